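# Condition-level reporting: percent change versus the 0-h baseline,
# mean +/- SD and t-based 95% CI, one-way ANOVA, Sidak-adjusted baseline
# contrasts and significance star coding.

#' Percent change of a value relative to a baseline
#'
#' `(value - baseline) / baseline * 100`, signed. A zero baseline is
#' undefined and returns `NA` with a warning.
#'
#' @param baseline,value mean values (vectorized over `value`).
#' @return Signed percent change.
#' @examples
#' percent_change(1.72, 2.43)   # +41.28: reported as "41%"
#' percent_change(823.0, 773.3) # -6.04: reported as "-6.0%"
#' @export
percent_change <- function(baseline, value) {
  if (any(baseline == 0)) {
    warning("undefined percent change: baseline is 0")
    return(ifelse(baseline == 0, NA_real_, (value - baseline) / baseline * 100))
  }
  (value - baseline) / baseline * 100
}

#' Round half away from zero for reporting
#'
#' Reporting helper matching the convention used for printed percentages
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded values.
#' @export
report_round <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classical one-way ANOVA across groups
#'
#' Equal-variance one-way analysis of variance. With two groups the F
#' statistic equals the square of the pooled t statistic.
#'
#' @param groups list of numeric vectors (one per group), each of length at
#'   least 2.
#' @return A list with `f`, `p`, `df1`, `df2`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, 0L)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), n))
  if (stats::var(values) == 0) {
    # identical data in every group: no between-group signal
    return(list(f = 0, p = 1, df1 = length(groups) - 1L,
                df2 = sum(n) - length(groups)))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(fit$statistic), p = unname(fit$p.value),
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to \[0, 1\]. Identity at `m = 1`;
#' everywhere at most the Bonferroni adjustment `m * p`.
#'
#' @param p raw p value(s) in \[0, 1\].
#' @param m number of comparisons in the family (>= 1).
#' @return Adjusted p value(s).
#' @export
sidak_adjust <- function(p, m) {
  if (any(m < 1)) stop("m must be at least 1")
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Significance star code
#'
#' Strict-inequality bins: `****` below 1e-4, `***` below 1e-3, `**` below
#' 0.01, `*` below 0.05, otherwise `n.s.` (so `p = 0.05` is `n.s.`).
#'
#' @param p_adj adjusted p value(s) in \[0, 1\].
#' @return Character vector of star codes.
#' @export
star_code <- function(p_adj) {
  stopifnot(all(is.na(p_adj) | (p_adj >= 0 & p_adj <= 1)))
  ifelse(is.na(p_adj), NA_character_,
         ifelse(p_adj < 1e-4, "****",
                ifelse(p_adj < 1e-3, "***",
                       ifelse(p_adj < 0.01, "**",
                              ifelse(p_adj < 0.05, "*", "n.s.")))))
}

#' Build a condition-level report with baseline contrasts
#'
#' For every condition and metric, each time point is summarized as mean, SD
#' and t-distribution 95% CI; non-baseline time points are additionally
#' compared with the 0-h baseline (pooled two-group comparison), Sidak
#' adjusted with `m` equal to the number of non-baseline time points in that
#' family, star coded, and annotated with the percent change of the mean
#' versus baseline.
#'
#' @param samples data frame with columns `condition`, `timepoint_h`,
#'   `metric`, `value` (one row per measured object).
#' @param baseline_h baseline time point (default 0); required per
#'   condition/metric, otherwise an error names the missing combination.
#' @return A data frame with one row per condition, metric and time point:
#'   `condition`, `timepoint_h`, `metric`, `n`, `mean`, `sd`, `ci95_low`,
#'   `ci95_high`, `pct_change_vs_0h`, `p_adj`, `stars`.
#' @export
build_report <- function(samples, baseline_h = 0) {
  req <- c("condition", "timepoint_h", "metric", "value")
  if (!all(req %in% names(samples)))
    stop("samples must have columns ", paste(req, collapse = ", "))
  out <- list()
  for (cond in unique(samples$condition)) {
    for (met in unique(samples$metric[samples$condition == cond])) {
      sub <- samples[samples$condition == cond & samples$metric == met, ]
      tps <- sort(unique(sub$timepoint_h))
      if (!baseline_h %in% tps)
        stop(sprintf("missing %g-h baseline for condition '%s', metric '%s'",
                     baseline_h, cond, met))
      base_vals <- sub$value[sub$timepoint_h == baseline_h]
      m <- sum(tps != baseline_h)
      for (tp in tps) {
        v <- sub$value[sub$timepoint_h == tp]
        n <- length(v)
        mu <- mean(v)
        s <- sd(v)
        ci <- if (n >= 2) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
        if (tp == baseline_h) {
          p_adj <- NA_real_
          pct <- 0
        } else {
          raw <- anova_oneway(list(base_vals, v))$p
          p_adj <- sidak_adjust(raw, m)
          pct <- percent_change(mean(base_vals), mu)
        }
        out[[length(out) + 1L]] <- data.frame(
          condition = cond, timepoint_h = tp, metric = met, n = n,
          mean = mu, sd = s, ci95_low = mu - ci, ci95_high = mu + ci,
          pct_change_vs_0h = pct, p_adj = p_adj,
          stars = ifelse(is.na(p_adj), NA_character_, star_code(p_adj)))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
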