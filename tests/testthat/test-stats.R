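# Reporting layer: percent change, ANOVA, Sidak, stars, report assembly.

test_that("percent change reproduces the printed worked examples", {
  expect_equal(report_round(percent_change(1.72, 2.43)), 41)
  expect_equal(report_round(percent_change(823.0, 773.3), 1), -6.0)
  expect_equal(percent_change(5, 5), 0)
  expect_warning(pc <- percent_change(0, 1), "baseline is 0")
  expect_true(is.na(pc))
  # unit invariance: same percent in um^2 or nm^2
  expect_equal(percent_change(1.72, 2.43), percent_change(1.72e6, 2.43e6))
})

test_that("report rounding is half away from zero", {
  expect_equal(report_round(0.5), 1)
  expect_equal(report_round(-0.5), -1)
  expect_equal(report_round(2.5), 3)
  expect_equal(report_round(-6.04, 1), -6.0)
  expect_equal(report_round(41.279), 41)
})

test_that("one-way ANOVA matches the sum-of-squares oracle to 1e-10", {
  ss_oracle <- function(groups) {
    values <- unlist(groups)
    gm <- mean(values)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    df1 <- length(groups) - 1
    df2 <- length(values) - length(groups)
    f <- (ssb / df1) / (ssw / df2)
    list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
  }
  set.seed(8)
  for (i in 1:10) {
    groups <- lapply(seq_len(sample(2:5, 1)),
                     function(.) rnorm(sample(5:30, 1), sd = 2))
    got <- anova_oneway(groups)
    want <- ss_oracle(groups)
    expect_equal(got$f, want$f, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("ANOVA edge cases: identical groups and F = t^2", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  r <- anova_oneway(list(rep(1, 5), rep(1, 6)))
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  set.seed(3)
  a <- rnorm(12)
  b <- rnorm(15, 0.4)
  f <- anova_oneway(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(f$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f$p, tt$p.value, tolerance = 1e-12)
  expect_error(anova_oneway(list(1, c(1, 2))), "at least 2")
})

test_that("Sidak adjustment: identity, closed form, Bonferroni bound", {
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701, tolerance = 1e-12)
  grid <- expand.grid(p = seq(0, 1, by = 0.01), m = 1:8)
  sid <- sidak_adjust(grid$p, grid$m)
  expect_true(all(sid <= grid$m * grid$p + 1e-12))
  expect_true(all(sid >= grid$p - 1e-12))
  # monotone in m
  for (p in c(0.001, 0.04, 0.2))
    expect_true(all(diff(sidak_adjust(p, 1:6)) >= 0))
  expect_error(sidak_adjust(0.5, 0), "at least 1")
})

test_that("star codes use strict inequality bins", {
  expect_equal(star_code(0.2), "n.s.")
  expect_equal(star_code(0.05), "n.s.")
  expect_equal(star_code(0.049), "*")
  expect_equal(star_code(0.0005), "***")
  expect_equal(star_code(1e-6), "****")
  expect_equal(star_code(0.009), "**")
})

test_that("reports carry baseline contrasts with the right Sidak family", {
  set.seed(10)
  samples <- rbind(
    data.frame(condition = "A", timepoint_h = 0, metric = "area",
               value = rnorm(30, 10)),
    data.frame(condition = "A", timepoint_h = 24, metric = "area",
               value = rnorm(30, 11)))
  rep1 <- build_report(samples)
  raw <- anova_oneway(list(samples$value[samples$timepoint_h == 0],
                           samples$value[samples$timepoint_h == 24]))$p
  # single non-baseline timepoint: m = 1, Sidak is the identity
  expect_equal(rep1$p_adj[rep1$timepoint_h == 24], raw, tolerance = 1e-9)
  expect_true(is.na(rep1$p_adj[rep1$timepoint_h == 0]))
  ci <- rep1[rep1$timepoint_h == 0, ]
  expect_true(ci$ci95_low < ci$mean && ci$mean < ci$ci95_high)

  s3 <- rbind(samples,
              data.frame(condition = "A", timepoint_h = 48, metric = "area",
                         value = rnorm(30, 12)))
  rep3 <- build_report(s3)
  raw24 <- anova_oneway(list(s3$value[s3$timepoint_h == 0],
                             s3$value[s3$timepoint_h == 24]))$p
  expect_equal(rep3$p_adj[rep3$timepoint_h == 24],
               sidak_adjust(raw24, 2), tolerance = 1e-9)
  expect_error(build_report(s3[s3$timepoint_h != 0, ]), "baseline")
})

test_that("a printed-scale nucleolar shift is detected with correct size", {
  # baseline mean 1.72 (SD 1.32) -> 2.43 (SD 1.79), n = 400 per group,
  # lognormal object areas; the reported percent change centres on +41 and
  # the Sidak-adjusted contrast is significant in nearly all runs
  runs <- 25
  pcts <- numeric(runs)
  sig <- logical(runs)
  for (i in seq_len(runs)) {
    set.seed(1000 + i)
    draw <- function(m, s, n) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
    }
    samples <- rbind(
      data.frame(condition = "G12D", timepoint_h = 0, metric = "nucleolin",
                 value = draw(1.72, 1.32, 400)),
      data.frame(condition = "G12D", timepoint_h = 24, metric = "nucleolin",
                 value = draw(2.43, 1.79, 400)))
    r <- build_report(samples)
    pcts[i] <- r$pct_change_vs_0h[r$timepoint_h == 24]
    sig[i] <- r$p_adj[r$timepoint_h == 24] < 0.05
  }
  expect_lt(abs(mean(pcts) - 41), 5)
  expect_gte(mean(sig), 0.9)
})
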