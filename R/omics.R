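# Transcriptomic scoring: threshold filtering of differential-expression
# records, nuclear gene-panel construction by Gene Ontology cellular
# component, and the Nuclear Transcriptional Remodeling Score (NTRS).

#' Filter differential-expression records at the study thresholds
#'
#' Keeps records with FDR strictly below `fdr_max` and absolute log2 fold
#' change of at least `min_abs_lfc`. Records with non-finite log2FC are
#' rejected with a warning.
#'
#' @param records data frame with columns `gene_id`, `condition`, `log2fc`,
#'   `fdr`, `go_category`.
#' @param fdr_max FDR threshold (default 0.05, exclusive).
#' @param min_abs_lfc minimum absolute log2FC (default 0.75, inclusive).
#' @return The filtered data frame.
#' @examples
#' df <- data.frame(gene_id = c("a", "b"), condition = "x",
#'                  log2fc = c(0.8, 2), fdr = c(0.04, 0.05),
#'                  go_category = "nucleolus")
#' filter_de(df)  # keeps only "a": FDR 0.05 is not below the threshold
#' @export
filter_de <- function(records, fdr_max = 0.05, min_abs_lfc = 0.75) {
  stopifnot(fdr_max > 0, min_abs_lfc > 0)
  check_de_cols(records)
  bad <- !is.finite(records$log2fc)
  if (any(bad)) {
    warning(sprintf("rejected %d record(s) with non-finite log2fc", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  records[records$fdr < fdr_max & abs(records$log2fc) >= min_abs_lfc, ,
          drop = FALSE]
}

check_de_cols <- function(records) {
  req <- c("gene_id", "condition", "log2fc", "fdr", "go_category")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  invisible(records)
}

#' Build the nuclear gene panel from filtered records
#'
#' Subsets records to the requested Gene Ontology cellular-component
#' categories (by default the three nuclear categories) and orders rows by
#' gene id within condition for stable downstream output.
#'
#' @param records filtered DE records (see [filter_de()]).
#' @param categories character set of categories to keep.
#' @return A data frame of class `nuclear_panel`.
#' @export
build_panel <- function(records,
                        categories = c("chromatin_remodeling",
                                       "nuclear_membrane", "nucleolus")) {
  stopifnot(length(categories) >= 1)
  check_de_cols(records)
  out <- records[records$go_category %in% categories, , drop = FALSE]
  out <- out[order(out$condition, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nuclear_panel", "data.frame")
  out
}

#' Nuclear Transcriptional Remodeling Score
#'
#' The NTRS of a panel is the unweighted arithmetic mean of log2 fold
#' changes, computed separately over genes with positive and with negative
#' values; genes with log2FC exactly 0 contribute to neither direction. An
#' empty direction is reported as `NA` (explicitly undefined, never 0).
#'
#' @param panel a panel data frame (see [build_panel()]); may contain several
#'   conditions.
#' @return A data frame with one row per condition: `condition`, `ntrs_pos`,
#'   `n_pos`, `ntrs_neg`, `n_neg`.
#' @examples
#' p <- data.frame(gene_id = letters[1:3], condition = "x",
#'                 log2fc = c(1, 3, -2), fdr = 0.01, go_category = "nucleolus")
#' compute_ntrs(p)  # ntrs_pos 2, ntrs_neg -2
#' @export
compute_ntrs <- function(panel) {
  check_de_cols(panel)
  conds <- unique(panel$condition)
  out <- lapply(conds, function(cond) {
    x <- panel$log2fc[panel$condition == cond]
    pos <- x[x > 0]
    neg <- x[x < 0]
    data.frame(condition = cond,
               ntrs_pos = if (length(pos)) mean(pos) else NA_real_,
               n_pos = length(pos),
               ntrs_neg = if (length(neg)) mean(neg) else NA_real_,
               n_neg = length(neg))
  })
  out <- do.call(rbind, out)
  if (!nrow(out))
    out <- data.frame(condition = character(0), ntrs_pos = numeric(0),
                      n_pos = integer(0), ntrs_neg = numeric(0),
                      n_neg = integer(0))
  out
}

#' Sign concordance of two condition panels
#'
#' Over genes present with nonzero log2FC in both panels, computes
#' `(matching-sign pairs - opposite-sign pairs) / shared genes`, in
#' \[-1, 1\]. `+1` for identical regulation directions, `-1` for a fully
#' inverted program. Returns `NA` with a warning when no genes are shared.
#'
#' @param panel_a,panel_b single-condition panel data frames.
#' @return A single numeric concordance value.
#' @export
sign_concordance <- function(panel_a, panel_b) {
  check_de_cols(panel_a)
  check_de_cols(panel_b)
  a <- panel_a[panel_a$log2fc != 0, c("gene_id", "log2fc")]
  b <- panel_b[panel_b$log2fc != 0, c("gene_id", "log2fc")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    warning("no shared nonzero genes between panels; concordance undefined")
    return(NA_real_)
  }
  s <- sign(m$log2fc_a) * sign(m$log2fc_b)
  sum(s) / nrow(m)
}
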