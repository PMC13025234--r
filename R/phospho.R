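# Antibody phospho-array quantification chain: duplicate-spot summarization,
# per-array global-median normalization, phospho/total signal ratio, plus/
# minus doxycycline fold change and threshold classification. No p-values are
# computed anywhere in this chain: sites are classified purely by the fold
# change thresholds.

#' Summarize replicate spots of one antibody
#'
#' One antibody on one array is quantified as the mean of its replicate spot
#' median intensities; with duplicate spotting this is simply the mean of the
#' two spot values.
#'
#' @param signals numeric vector of spot signals (one array, one antibody).
#' @return The summarized signal (numeric scalar).
#' @export
summarize_spots <- function(signals) {
  if (!length(signals)) stop("missing data: no replicate spots for antibody")
  stopifnot(is.numeric(signals), all(signals >= 0))
  mean(signals)
}

#' Normalize one array to its global median signal
#'
#' Divides every summarized antibody signal on an array by the array-wide
#' median, so the post-normalization median is exactly 1. The median of an
#' even count is the mean of the central pair.
#'
#' @param signals numeric vector of summarized signals for one array.
#' @return Normalized signals.
#' @export
normalize_global <- function(signals) {
  stopifnot(is.numeric(signals), length(signals) >= 1)
  med <- median(signals)
  if (!is.finite(med) || med <= 0)
    stop("normalization error: array median is not positive")
  signals / med
}

#' Phospho/total signal ratio
#'
#' @param phospho_signal,total_signal normalized signals of a phospho
#'   antibody and its paired total-protein antibody. Non-positive total
#'   signals yield `NA` with a warning (undefined site, excluded downstream).
#' @return The ratio (vectorized).
#' @export
phospho_ratio <- function(phospho_signal, total_signal) {
  bad <- !is.finite(total_signal) | total_signal <= 0
  if (any(bad))
    warning(sprintf("%d site(s) with non-positive total signal; ratio undefined", sum(bad)))
  ifelse(bad, NA_real_, phospho_signal / total_signal)
}

#' Classify a site from its plus/minus doxycycline ratios
#'
#' `log2fc = log2(plus / minus)`; the call is `"up"` when log2FC is at least
#' `threshold`, `"down"` when at most `-threshold` (both boundaries
#' inclusive), otherwise `"unchanged"`. Non-positive ratios yield an
#' undefined (`NA`) site.
#'
#' @param plus_ratio,minus_ratio phospho/total ratios in the induced (+doxy)
#'   and control (-doxy) state (vectorized).
#' @param threshold log2 fold-change threshold (default 1).
#' @return A data frame with columns `log2fc` and `call`.
#' @examples
#' call_site(2, 1)    # log2fc exactly 1 -> "up" (inclusive boundary)
#' call_site(1, 1)    # unchanged
#' @export
call_site <- function(plus_ratio, minus_ratio, threshold = 1) {
  stopifnot(threshold > 0)
  bad <- !is.finite(plus_ratio) | !is.finite(minus_ratio) |
    plus_ratio <= 0 | minus_ratio <= 0
  if (any(bad)) warning(sprintf("%d site(s) with non-positive ratio; call undefined", sum(bad)))
  lfc <- ifelse(bad, NA_real_, log2(plus_ratio / minus_ratio))
  call <- ifelse(is.na(lfc), NA_character_,
                 ifelse(lfc >= threshold, "up",
                        ifelse(lfc <= -threshold, "down", "unchanged")))
  data.frame(log2fc = lfc, call = call)
}

#' Run the full phospho-array scoring chain on a spot table
#'
#' Per array (one condition, doxycycline state and biological replicate):
#' spots are summarized per antibody and normalized to the array's global
#' median. Normalized antibody signals are then averaged over biological
#' replicates, the phospho/total ratio is formed per site and state, and the
#' plus-vs-minus doxycycline log2 fold change is classified at the threshold.
#' Because the ratio of two same-array signals cancels the normalization
#' constant, the chain is invariant to global array scaling.
#'
#' @param records spot table as produced by [generate_phospho_array()].
#' @param threshold log2 fold-change call threshold (default 1).
#' @return A data frame with one row per site and condition: `target`,
#'   `site`, `condition`, `log2fc`, `call`.
#' @export
score_phospho <- function(records, threshold = 1) {
  req <- c("antibody_id", "target", "is_phospho", "site", "condition",
           "doxy", "replicate", "signal")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  norm <- normalize_spot_table(records)
  # average normalized signals over biological replicates
  avg <- stats::aggregate(norm_signal ~ antibody_id + target + is_phospho +
                            site + condition + doxy,
                          data = norm, FUN = mean, na.action = stats::na.pass)
  ph <- avg[avg$is_phospho, ]
  tot <- avg[!avg$is_phospho, c("target", "condition", "doxy", "norm_signal")]
  names(tot)[names(tot) == "norm_signal"] <- "total_signal"
  m <- merge(ph, tot, by = c("target", "condition", "doxy"))
  m$ratio <- phospho_ratio(m$norm_signal, m$total_signal)
  plus <- m[m$doxy == "plus", c("target", "site", "condition", "ratio")]
  minus <- m[m$doxy == "minus", c("target", "site", "condition", "ratio")]
  names(plus)[4] <- "plus_ratio"
  names(minus)[4] <- "minus_ratio"
  res <- merge(plus, minus, by = c("target", "site", "condition"))
  cc <- call_site(res$plus_ratio, res$minus_ratio, threshold)
  out <- data.frame(target = res$target, site = res$site,
                    condition = res$condition, log2fc = cc$log2fc,
                    call = cc$call)
  out <- out[order(out$condition, out$target, out$site), ]
  rownames(out) <- NULL
  out
}

# summarize spots and median-normalize per array (condition x doxy x replicate)
normalize_spot_table <- function(records) {
  # total-protein antibodies carry no site; aggregate() would drop NA levels
  records$site <- ifelse(is.na(records$site), "", records$site)
  summ <- stats::aggregate(signal ~ antibody_id + target + is_phospho + site +
                             condition + doxy + replicate,
                           data = records, FUN = summarize_spots,
                           na.action = stats::na.pass)
  key <- interaction(summ$condition, summ$doxy, summ$replicate, drop = TRUE)
  summ$norm_signal <- NA_real_
  for (k in levels(key)) {
    sel <- key == k
    summ$norm_signal[sel] <- normalize_global(summ$signal[sel])
  }
  summ
}

#' Fold-change calls for total-protein abundance
#'
#' The abundance layer has no ratio step: fold change is computed directly on
#' the replicate-averaged, median-normalized total-protein signals
#' (+doxy versus -doxy), classified at the same threshold rule as
#' [call_site()].
#'
#' @inheritParams score_phospho
#' @return A data frame with one row per protein and condition: `target`,
#'   `condition`, `log2fc`, `call`.
#' @export
score_abundance <- function(records, threshold = 1) {
  norm <- normalize_spot_table(records[!records$is_phospho, ])
  avg <- stats::aggregate(norm_signal ~ target + condition + doxy,
                          data = norm, FUN = mean)
  plus <- avg[avg$doxy == "plus", c("target", "condition", "norm_signal")]
  minus <- avg[avg$doxy == "minus", c("target", "condition", "norm_signal")]
  res <- merge(plus, minus, by = c("target", "condition"),
               suffixes = c("_plus", "_minus"))
  cc <- call_site(res$norm_signal_plus, res$norm_signal_minus, threshold)
  out <- data.frame(target = res$target, condition = res$condition,
                    log2fc = cc$log2fc, call = cc$call)
  out[order(out$condition, out$target), ]
}
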