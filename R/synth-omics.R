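# Seeded generators for differential-expression tables and antibody
# phospho-array spot tables with known injected effects.

#' Differential-expression simulation specification
#'
#' Genes are assigned a Gene Ontology cellular-component category by
#' `category_fractions`; a fixed subset of the nuclear-annotated genes
#' (categories other than `"other"`) is responsive, with a per-gene base
#' direction shared across conditions so that cross-condition sign
#' concordance is meaningful. Per-condition effects set the mean/sd of the
#' responsive genes' log2 fold change; an `invert` flag flips every sign to
#' emulate a dominant-negative, inversely regulated condition. FDR values for
#' affected genes are uniform below the 0.05 threshold with probability
#' `fdr_hit_prob` (only the threshold crossing matters downstream); null
#' genes draw FDR uniform on (0, 1) and log2FC from a central normal.
#'
#' @param n_genes number of genes.
#' @param category_fractions named fractions over
#'   `chromatin_remodeling`, `nuclear_membrane`, `nucleolus`, `other`;
#'   must sum to 1.
#' @param effects named list (by condition) of lists with `mean`, `sd`,
#'   `frac_affected`, optional `invert` flag.
#' @param null_sd sd of null-gene log2FC.
#' @param fdr_hit_prob probability an affected gene's FDR lands below 0.05.
#' @return An object of class `de_sim_spec`.
#' @export
de_sim_spec <- function(n_genes = 2000,
                        category_fractions = c(chromatin_remodeling = 0.01,
                                               nuclear_membrane = 0.01,
                                               nucleolus = 0.01,
                                               other = 0.97),
                        effects = list(),
                        null_sd = 0.3,
                        fdr_hit_prob = 0.95) {
  stopifnot(n_genes >= 1, null_sd >= 0,
            fdr_hit_prob >= 0, fdr_hit_prob <= 1)
  cats <- c("chromatin_remodeling", "nuclear_membrane", "nucleolus", "other")
  if (!setequal(names(category_fractions), cats) ||
      abs(sum(category_fractions) - 1) > 1e-8)
    stop("config error: category_fractions must cover the four categories and sum to 1")
  for (e in effects)
    stopifnot(is.numeric(e$mean), e$sd >= 0,
              e$frac_affected >= 0, e$frac_affected <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 category_fractions = category_fractions[cats],
                 effects = effects, null_sd = null_sd,
                 fdr_hit_prob = fdr_hit_prob),
            class = "de_sim_spec")
}

#' Generate a synthetic differential-expression gene table
#'
#' @param spec a [de_sim_spec()].
#' @param conditions character vector of condition names; every condition
#'   named in `spec$effects` must be listed here.
#' @param seed integer seed; identical `(spec, conditions, seed)` gives an
#'   identical table.
#' @return A data frame with columns `gene_id`, `condition`, `log2fc`,
#'   `fdr`, `go_category` (one row per gene and condition).
#' @examples
#' spec <- de_sim_spec(n_genes = 100,
#'                     effects = list(A = list(mean = 1, sd = 0.2, frac_affected = 0.5)))
#' head(generate_de_table(spec, c("A", "B"), seed = 1))
#' @export
generate_de_table <- function(spec, conditions, seed) {
  stopifnot(inherits(spec, "de_sim_spec"), length(conditions) >= 1)
  unknown <- setdiff(names(spec$effects), conditions)
  if (length(unknown))
    stop("config error: effect model names unknown condition(s): ",
         paste(unknown, collapse = ", "))
  set.seed(stage_seed(seed, "de_table"))
  n <- spec$n_genes
  gene_id <- sprintf("gene_%05d", seq_len(n))
  counts <- floor(spec$category_fractions * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[order(spec$category_fractions * n - counts,
                            decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(spec$category_fractions * n - counts,
                   decreasing = TRUE)[seq_len(rem)]] + 1
  go <- sample(rep(names(counts), counts))
  base_dir <- sample(c(-1, 1), n, replace = TRUE)
  nuclear <- go != "other"
  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    eff <- spec$effects[[cond]]
    affected <- rep(FALSE, n)
    lfc <- rnorm(n, 0, spec$null_sd)
    fdr <- runif(n)
    if (!is.null(eff) && eff$frac_affected > 0) {
      affected <- nuclear & (runif(n) < eff$frac_affected)
      sgn <- base_dir * (if (isTRUE(eff$invert)) -1 else 1)
      na <- sum(affected)
      lfc[affected] <- sgn[affected] * abs(rnorm(na, eff$mean, eff$sd))
      hit <- runif(na) < spec$fdr_hit_prob
      fdr[affected] <- ifelse(hit, runif(na, 0, 0.05), runif(na, 0.05, 1))
    }
    out[[ci]] <- data.frame(gene_id = gene_id, condition = cond,
                            log2fc = lfc, fdr = fdr, go_category = go)
  }
  do.call(rbind, out)
}

#' Phospho-array simulation specification
#'
#' Emulates an antibody array in which every phosphorylation site has a
#' phospho-specific antibody paired with the total-protein antibody of its
#' target, each antibody is spotted in duplicate, and conditions are profiled
#' in paired minus/plus doxycycline states across biological replicates.
#'
#' @param n_sites number of phosphorylation sites (default 584).
#' @param n_proteins number of target proteins (default 452); sites are
#'   distributed over proteins round-robin.
#' @param n_replicates biological replicates per condition (default 3).
#' @param n_spots technical spots per antibody and array (default 2,
#'   duplicate spotting).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of baseline
#'   antibody signal.
#' @param spot_sdlog technical spot noise (sd of log signal).
#' @param replicate_sdlog biological replicate noise (sd of log signal).
#' @param effects named list (by condition) of lists with `frac` (fraction
#'   of sites affected), `lfc_mean`, `lfc_sd`: the induced +doxy change of
#'   the phospho signal, sign random per site.
#' @param antibody_table optional custom antibody table (columns
#'   `antibody_id`, `target`, `is_phospho`, `site`); every phospho antibody
#'   must have a total-protein antibody for the same target, otherwise a
#'   config error is raised.
#' @return An object of class `phospho_sim_spec`.
#' @export
phospho_sim_spec <- function(n_sites = 584, n_proteins = 452,
                             n_replicates = 3, n_spots = 2,
                             baseline_meanlog = log(1000),
                             baseline_sdlog = 0.8,
                             spot_sdlog = 0.05, replicate_sdlog = 0.08,
                             effects = list(), antibody_table = NULL) {
  stopifnot(n_sites >= 1, n_proteins >= 1, n_replicates >= 1, n_spots >= 1,
            spot_sdlog >= 0, replicate_sdlog >= 0)
  for (e in effects)
    stopifnot(e$frac >= 0, e$frac <= 1, is.numeric(e$lfc_mean), e$lfc_sd >= 0)
  if (!is.null(antibody_table)) {
    req <- c("antibody_id", "target", "is_phospho", "site")
    if (!all(req %in% names(antibody_table)))
      stop("config error: antibody_table must have columns ",
           paste(req, collapse = ", "))
    ph <- antibody_table[antibody_table$is_phospho, ]
    tot <- antibody_table[!antibody_table$is_phospho, ]
    unpaired <- setdiff(ph$target, tot$target)
    if (length(unpaired))
      stop("config error: phospho antibody without paired total-protein antibody: ",
           paste(unpaired, collapse = ", "))
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 n_spots = as.integer(n_spots),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 spot_sdlog = spot_sdlog, replicate_sdlog = replicate_sdlog,
                 effects = effects, antibody_table = antibody_table),
            class = "phospho_sim_spec")
}

default_antibody_table <- function(spec) {
  prot <- sprintf("prot_%04d", seq_len(spec$n_proteins))
  site_prot <- prot[((seq_len(spec$n_sites) - 1) %% spec$n_proteins) + 1]
  site <- sprintf("%s_S%d", site_prot,
                  100 + (seq_len(spec$n_sites) - 1) %/% spec$n_proteins)
  rbind(
    data.frame(antibody_id = paste0("pAb_", site), target = site_prot,
               is_phospho = TRUE, site = site),
    data.frame(antibody_id = paste0("tAb_", prot), target = prot,
               is_phospho = FALSE, site = NA_character_))
}

#' Generate a synthetic phospho-array spot table
#'
#' @param spec a [phospho_sim_spec()].
#' @param conditions character vector of condition names.
#' @param seed integer seed.
#' @return A data frame of spot records with columns `antibody_id`, `target`,
#'   `is_phospho`, `site`, `condition`, `doxy` (`"minus"`/`"plus"`),
#'   `replicate`, `signal`.
#' @export
generate_phospho_array <- function(spec, conditions, seed) {
  stopifnot(inherits(spec, "phospho_sim_spec"), length(conditions) >= 1)
  unknown <- setdiff(names(spec$effects), conditions)
  if (length(unknown))
    stop("config error: effect model names unknown condition(s): ",
         paste(unknown, collapse = ", "))
  set.seed(stage_seed(seed, "phospho_array"))
  ab <- spec$antibody_table %||% default_antibody_table(spec)
  n_ab <- nrow(ab)
  base <- rlnorm(n_ab, spec$baseline_meanlog, spec$baseline_sdlog)
  rows <- list()
  injected <- list()
  for (cond in conditions) {
    eff <- spec$effects[[cond]]
    site_lfc <- rep(0, n_ab)
    if (!is.null(eff) && eff$frac > 0) {
      ph_idx <- which(ab$is_phospho)
      hit <- ph_idx[runif(length(ph_idx)) < eff$frac]
      site_lfc[hit] <- sample(c(-1, 1), length(hit), replace = TRUE) *
        abs(rnorm(length(hit), eff$lfc_mean, eff$lfc_sd))
      if (length(hit))
        injected[[length(injected) + 1L]] <- data.frame(
          condition = cond, site = ab$site[hit], target = ab$target[hit],
          injected_lfc = site_lfc[hit])
    }
    for (rep_i in seq_len(spec$n_replicates)) {
      for (doxy in c("minus", "plus")) {
        lvl <- base * exp(rnorm(n_ab, 0, spec$replicate_sdlog))
        if (doxy == "plus") lvl <- lvl * 2^site_lfc
        for (sp_i in seq_len(spec$n_spots)) {
          sig <- lvl * exp(rnorm(n_ab, 0, spec$spot_sdlog))
          rows[[length(rows) + 1L]] <- data.frame(
            antibody_id = ab$antibody_id, target = ab$target,
            is_phospho = ab$is_phospho, site = ab$site,
            condition = cond, doxy = doxy, replicate = rep_i, signal = sig)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # simulation ground truth: which sites carry an injected effect
  attr(out, "injected") <- if (length(injected)) do.call(rbind, injected) else
    data.frame(condition = character(0), site = character(0),
               target = character(0), injected_lfc = numeric(0))
  out
}
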