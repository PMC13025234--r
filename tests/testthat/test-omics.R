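# DE filtering, panel construction, NTRS and sign concordance.

test_that("the DE filter applies strict FDR and inclusive log2FC bounds", {
  df <- data.frame(gene_id = c("a", "b", "c", "d"), condition = "x",
                   log2fc = c(0.75, 2.0, -0.74, -0.8),
                   fdr = c(0.04, 0.05, 0.01, 0.049),
                   go_category = "nucleolus")
  kept <- filter_de(df)
  expect_setequal(kept$gene_id, c("a", "d"))  # fdr 0.05 dropped, |0.74| dropped
  dfn <- rbind(df, data.frame(gene_id = "e", condition = "x", log2fc = NaN,
                              fdr = 0.01, go_category = "nucleolus"))
  expect_warning(keptn <- filter_de(dfn), "non-finite")
  expect_false("e" %in% keptn$gene_id)
})

test_that("filtering equals a brute-force scan on random tables", {
  for (seed in 1:5) {
    tab <- random_de_table(1000, seed)
    kept <- filter_de(tab)
    brute <- tab[is.finite(tab$log2fc) & tab$fdr < 0.05 &
                   abs(tab$log2fc) >= 0.75, ]
    expect_equal(kept$gene_id, brute$gene_id)
  }
})

test_that("threshold relaxation never shrinks the kept set", {
  tab <- random_de_table(500, 42)
  k1 <- filter_de(tab, fdr_max = 0.05, min_abs_lfc = 0.75)
  k2 <- filter_de(tab, fdr_max = 0.10, min_abs_lfc = 0.75)
  k3 <- filter_de(tab, fdr_max = 0.05, min_abs_lfc = 0.50)
  expect_true(all(k1$gene_id %in% k2$gene_id))
  expect_true(all(k1$gene_id %in% k3$gene_id))
})

test_that("panel construction subsets categories stably", {
  tab <- random_de_table(400, 7)
  panel <- build_panel(tab)
  expect_true(all(panel$go_category != "other"))
  expect_equal(nrow(panel), sum(tab$go_category != "other"))
  # union identity over single-category panels
  single <- lapply(c("chromatin_remodeling", "nuclear_membrane", "nucleolus"),
                   function(cat) build_panel(tab, cat))
  expect_equal(nrow(panel), sum(vapply(single, nrow, 0L)))
  all_other <- tab[tab$go_category == "other", ]
  expect_equal(nrow(build_panel(all_other)), 0)
})

test_that("NTRS means match hand arithmetic and flag empty directions", {
  p <- data.frame(gene_id = c("u1", "u2", "d1"), condition = "x",
                  log2fc = c(1, 3, -2), fdr = 0.01, go_category = "nucleolus")
  r <- compute_ntrs(p)
  expect_equal(r$ntrs_pos, 2)
  expect_equal(r$ntrs_neg, -2)
  expect_equal(c(r$n_pos, r$n_neg), c(2L, 1L))

  # the six printed values of the attenuated variant's nuclear genes
  six <- data.frame(gene_id = c("SOX9", "NOS1AP", "CCD86", "HDAC5", "ABTB1",
                                "SATB1"),
                    condition = "G12R",
                    log2fc = c(0.85, 0.84, 0.30, 0.16, 0.03, -0.05),
                    fdr = 0.01, go_category = "chromatin_remodeling")
  rs <- compute_ntrs(six)
  expect_equal(rs$ntrs_pos, 0.436, tolerance = 1e-12)
  expect_equal(rs$ntrs_neg, -0.05, tolerance = 1e-12)

  neg <- data.frame(gene_id = c("a", "b"), condition = "x",
                    log2fc = c(-1, -2), fdr = 0.01, go_category = "nucleolus")
  rn <- compute_ntrs(neg)
  expect_true(is.na(rn$ntrs_pos))
  expect_equal(rn$n_pos, 0L)
  # zero log2fc contributes to neither direction
  z <- rbind(neg, data.frame(gene_id = "z", condition = "x", log2fc = 0,
                             fdr = 0.01, go_category = "nucleolus"))
  rz <- compute_ntrs(z)
  expect_equal(rz$n_pos + rz$n_neg, 2L)
})

test_that("NTRS equals the brute-force mean and ignores record order", {
  for (seed in 1:20) {
    tab <- random_de_table(200, seed + 100)
    r <- compute_ntrs(tab)
    pos <- tab$log2fc[tab$log2fc > 0]
    neg <- tab$log2fc[tab$log2fc < 0]
    expect_equal(r$ntrs_pos, mean(pos))
    expect_equal(r$ntrs_neg, mean(neg))
    shuf <- tab[sample(nrow(tab)), ]
    expect_equal(compute_ntrs(shuf)$ntrs_pos, r$ntrs_pos)
  }
})

test_that("sign concordance is +1 on itself, -1 on a flipped copy", {
  p <- random_de_table(100, 9)
  p <- p[p$log2fc != 0, ]
  flipped <- p
  flipped$log2fc <- -p$log2fc
  expect_equal(sign_concordance(p, p), 1)
  expect_equal(sign_concordance(p, flipped), -1)
  q <- p
  q$gene_id <- paste0("other_", q$gene_id)
  expect_warning(res <- sign_concordance(p, q), "no shared")
  expect_true(is.na(res))
})

test_that("injected effect magnitudes are recovered through the NTRS", {
  # inject +/-0.85 effects; conditional on the |log2fc| >= 0.75 filter the
  # expected positive NTRS is the truncated-normal mean
  eff_mean <- 0.85
  eff_sd <- 0.3
  spec <- de_sim_spec(
    n_genes = 6000,
    category_fractions = c(chromatin_remodeling = 0.1, nuclear_membrane = 0.1,
                           nucleolus = 0.1, other = 0.7),
    effects = list(A = list(mean = eff_mean, sd = eff_sd,
                            frac_affected = 0.6)),
    null_sd = 0.25)
  tab <- generate_de_table(spec, "A", seed = 13)
  r <- compute_ntrs(build_panel(filter_de(tab)))
  # E[X | X >= 0.75], X ~ N(mean, sd): truncated-normal oracle
  alpha <- (0.75 - eff_mean) / eff_sd
  trunc_mean <- eff_mean + eff_sd * dnorm(alpha) / (1 - pnorm(alpha))
  se <- eff_sd / sqrt(r$n_pos)
  expect_lt(abs(r$ntrs_pos - trunc_mean), 3 * se)
  expect_lt(abs(-r$ntrs_neg - trunc_mean), 3 * eff_sd / sqrt(r$n_neg))
})
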