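# End-to-end orchestration: simulate -> segment -> measure -> score ->
# report, driven by a YAML configuration. All randomness flows from one
# master seed; every stage derives a named substream, so identical
# (config, seed) reproduces byte-identical outputs (manifests carry no
# timestamps; wall-clock logging goes to run.log only).

config_error <- function(...) {
  stop(errorCondition(paste0("config error: ", ...),
                      class = c("nucmorph_config_error", "error")))
}

#' Read and validate a pipeline run configuration
#'
#' @param path path to a YAML configuration file (see the packaged demo at
#'   `system.file("extdata", "demo-config.yaml", package = "nucmorph")`).
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("no such config file: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' Validate an in-memory run configuration
#'
#' @param config configuration list (same structure as the YAML file).
#' @return The configuration, classed `run_config`.
#' @export
validate_run_config <- function(config) {
  missing <- setdiff(c("seed", "outdir"), names(config))
  if (!is.null(config$imaging)) {
    im <- config$imaging
    if (is.null(im$cohorts)) missing <- c(missing, "imaging.cohorts")
    mode <- im$mode %||% "2d"
    if (!mode %in% c("2d", "3d", "both"))
      config_error("imaging.mode must be one of 2d, 3d, both")
    if (mode %in% c("2d", "both") && is.null(im$geometry2d))
      missing <- c(missing, "imaging.geometry2d")
    if (mode %in% c("3d", "both") && is.null(im$geometry3d))
      missing <- c(missing, "imaging.geometry3d")
    keys <- vapply(im$cohorts, function(co)
      paste(co$condition %||% "?", co$timepoint_h %||% "?"), "")
    if (anyDuplicated(keys))
      config_error("duplicate (condition, timepoint) cohort keys: ",
                   paste(keys[duplicated(keys)], collapse = "; "))
    for (co in im$cohorts) {
      ck <- setdiff(c("condition", "timepoint_h", "n_cells", "nucleus"),
                    names(co))
      if (length(ck))
        config_error("cohort missing key(s): ", paste(ck, collapse = ", "))
    }
  }
  if (!is.null(config$omics) && is.null(config$omics$conditions))
    missing <- c(missing, "omics.conditions")
  if (length(missing))
    config_error("missing key(s): ", paste(missing, collapse = ", "))
  class(config) <- c("run_config", "list")
  config
}

cohort_specs <- function(co) {
  nuc <- co$nucleus
  spec <- nuclear_phenotype_spec(
    n_cells = co$n_cells,
    mean_size = nuc$mean_size,
    size_cv = nuc$size_cv %||% 0.2,
    irregularity_amplitude = nuc$irregularity_amplitude %||% 0.08,
    irregularity_harmonics = nuc$irregularity_harmonics %||% 4,
    target_shape = nuc$target_shape %||% NA_real_)
  comps <- lapply(co$compartments %||% list(), function(cc)
    compartment_spec(cc$marker, cc$count_mean, cc$size_mean,
                     cc$size_sigma %||% 0.4, cc$nesting))
  list(spec = spec, compartments = comps)
}

config_geometry <- function(g) image_geometry(unlist(g$shape),
                                              unlist(g$spacing_um))

config_noise <- function(nz) {
  if (is.null(nz)) return(noise_spec())
  noise_spec(background = nz$background %||% 0.05,
             psf_sigma = nz$psf_sigma %||% 0.1,
             gaussian_sigma = nz$gaussian_sigma %||% 0.01,
             photon_scale = nz$photon_scale %||% 0)
}

config_seg_params <- function(sg, channel, threshold = NULL) {
  ms <- sg$min_size
  if (is.list(ms)) ms <- ms[[channel]] %||% 0
  segmentation_params(
    smoothing_sigma = sg$smoothing_sigma %||% 0.1,
    threshold = threshold %||% (sg$threshold %||% "otsu"),
    min_size = ms %||% 0,
    fill_holes = sg$fill_holes %||% TRUE,
    exclude_border = sg$exclude_border %||% TRUE)
}

run_log <- function(outdir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

image_cohort_seed <- function(seed, mode, cond, tp, i)
  stage_seed(seed, sprintf("img_%s_%s_%s_%d", mode, cond, tp, i))

# generate every image of one cohort (list of synthetic_image)
cohort_images <- function(co, geom, noise, seed, mode) {
  n_images <- co$n_images %||% 1L
  per <- ceiling(co$n_cells / n_images)
  counts <- pmax(0L, pmin(per, co$n_cells - (seq_len(n_images) - 1L) * per))
  cs <- cohort_specs(co)
  lapply(which(counts > 0L), function(i) {
    sp <- cs$spec
    sp$n_cells <- counts[i]
    generate_image(sp, cs$compartments, noise, geom,
                   image_cohort_seed(seed, mode, co$condition,
                                     co$timepoint_h, i))
  })
}

#' Run the imaging arm of the pipeline
#'
#' For every cohort (condition x time point) the configured synthetic images
#' are generated, each channel is segmented (optionally with thresholds
#' frozen on the 0-h baseline images and applied uniformly to all cohorts),
#' objects are measured in physical units and assigned to parent nuclei, and
#' the per-object tables are aggregated into a condition report with percent
#' change versus baseline and Sidak-adjusted contrasts.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @param seed optional master seed overriding `config$seed`.
#' @param outdir optional output directory overriding `config$outdir`.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_imaging <- function(config, seed = NULL, outdir = NULL) {
  config <- validate_run_config(unclass(config))
  if (is.null(config$imaging)) config_error("config has no imaging section")
  seed <- seed %||% config$seed
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  im <- config$imaging
  mode <- im$mode %||% "2d"
  modes <- if (mode == "both") c("2d", "3d") else mode
  noise <- config_noise(im$noise)
  files <- character(0)
  for (md in modes) {
    run_log(outdir, sprintf("imaging stage (%s): %d cohort(s)", md,
                            length(im$cohorts)))
    geom <- config_geometry(if (md == "2d") im$geometry2d else im$geometry3d)
    seg <- im$segmentation %||% list()
    # only channels with configured content are segmented: thresholding a
    # channel that contains nothing but background is meaningless
    used_channels <- unique(c("nucleus", unlist(lapply(im$cohorts, function(co)
      vapply(co$compartments %||% list(), function(cc) cc$marker, "")))))
    # uniform-threshold contract: freeze per-channel thresholds on baseline
    thresholds <- list()
    if (isTRUE(seg$freeze_baseline)) {
      base_co <- Filter(function(co) (co$timepoint_h %||% 0) == 0, im$cohorts)
      pools <- list()
      for (co in base_co) {
        for (img in cohort_images(co, geom, noise, seed, md)) {
          for (ch in intersect(names(img$channels), used_channels))
            pools[[ch]] <- c(pools[[ch]], list(img$channels[[ch]]))
        }
      }
      thresholds <- lapply(pools, estimate_threshold)
      run_log(outdir, paste("frozen baseline thresholds:",
                            paste(sprintf("%s=%.4f", names(thresholds),
                                          unlist(thresholds)),
                                  collapse = " ")))
    }
    rows <- list()
    for (co in im$cohorts) {
      imgs <- cohort_images(co, geom, noise, seed, md)
      for (ii in seq_along(imgs)) {
        img <- imgs[[ii]]
        image_id <- sprintf("%s_%sh_%s_%02d", co$condition, co$timepoint_h,
                            md, ii)
        segs <- list()
        for (ch in intersect(names(img$channels), used_channels)) {
          prm <- config_seg_params(seg, ch, thresholds[[ch]])
          segs[[ch]] <- if (md == "2d") {
            segment_2d(img$channels[[ch]], geom, prm)
          } else {
            segment_3d(img$channels[[ch]], geom, prm)
          }
        }
        nuc <- segs$nucleus
        for (ch in names(segs)) {
          mm <- if (md == "2d") measure_2d(segs[[ch]]) else measure_3d(segs[[ch]])
          if (!nrow(mm)) next
          mm$parent_label <- NA_integer_
          if (ch != "nucleus") {
            asg <- assign_compartments(nuc, segs[[ch]])
            mm$parent_label[asg$assignment$child_label] <-
              asg$assignment$parent_label
          }
          mm <- cbind(data.frame(image_id = image_id, channel = ch,
                                 condition = co$condition,
                                 timepoint_h = co$timepoint_h), mm)
          rows[[length(rows) + 1L]] <- mm
        }
      }
    }
    objects <- do.call(rbind, rows)
    obj_file <- file.path(outdir, sprintf("objects_%s.csv", md))
    write.csv(objects, obj_file, row.names = FALSE)
    files <- c(files, obj_file)
    size_col <- if (md == "2d") "area_um2" else "volume_um3"
    shape_col <- if (md == "2d") "circularity" else "sphericity"
    long <- rbind(
      data.frame(condition = objects$condition,
                 timepoint_h = objects$timepoint_h,
                 metric = paste(objects$channel, size_col, sep = "_"),
                 value = objects[[size_col]]),
      data.frame(condition = objects$condition,
                 timepoint_h = objects$timepoint_h,
                 metric = paste(objects$channel, shape_col, sep = "_"),
                 value = objects[[shape_col]]))
    long <- long[is.finite(long$value), ]
    report <- build_report(long)
    rep_file <- file.path(outdir, sprintf("report_%s.csv", md))
    write.csv(report, rep_file, row.names = FALSE)
    files <- c(files, rep_file)
    if (identical(config$report$format %||% "csv", "json")) {
      jf <- file.path(outdir, sprintf("report_%s.json", md))
      jsonlite::write_json(report, jf, dataframe = "rows", digits = NA)
      files <- c(files, jf)
    }
    run_log(outdir, sprintf("imaging stage (%s) done: %d objects", md,
                            nrow(objects)))
  }
  write_manifest(config, seed, outdir, "imaging", files)
}

#' Run the omics arm of the pipeline
#'
#' Generates the configured differential-expression and phospho-array
#' tables, applies the FDR/log2FC filter, builds the nuclear panel, computes
#' the per-condition NTRS and the sign concordance of every condition
#' against the reference, and scores the phospho chain.
#'
#' @inheritParams run_imaging
#' @return Invisibly, the run manifest.
#' @export
run_omics <- function(config, seed = NULL, outdir = NULL) {
  config <- validate_run_config(unclass(config))
  if (is.null(config$omics)) config_error("config has no omics section")
  seed <- seed %||% config$seed
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  om <- config$omics
  conditions <- unlist(om$conditions)
  files <- character(0)
  if (!is.null(om$de)) {
    run_log(outdir, "omics stage: differential expression")
    de <- om$de
    spec <- de_sim_spec(
      n_genes = de$n_genes %||% 2000,
      effects = lapply(de$effects %||% list(), function(e)
        list(mean = e$mean, sd = e$sd, frac_affected = e$frac_affected,
             invert = e$invert %||% FALSE)),
      null_sd = de$null_sd %||% 0.3,
      fdr_hit_prob = de$fdr_hit_prob %||% 0.95)
    tab <- generate_de_table(spec, conditions, stage_seed(seed, "omics_de"))
    de_file <- file.path(outdir, "de_table.csv")
    write.csv(tab, de_file, row.names = FALSE)
    panel <- build_panel(filter_de(tab))
    ntrs <- compute_ntrs(panel)
    ntrs_file <- file.path(outdir, "ntrs_report.csv")
    write.csv(ntrs, ntrs_file, row.names = FALSE)
    conc_file <- file.path(outdir, "concordance.csv")
    ref <- om$reference_condition %||% conditions[1]
    refp <- panel[panel$condition == ref, ]
    conc <- do.call(rbind, lapply(setdiff(conditions, ref), function(cond) {
      other <- panel[panel$condition == cond, ]
      val <- if (nrow(other) && nrow(refp)) {
        tryCatch(sign_concordance(refp, other), warning = function(w) NA_real_)
      } else NA_real_
      data.frame(reference = ref, condition = cond, concordance = val)
    }))
    write.csv(conc, conc_file, row.names = FALSE)
    files <- c(files, de_file, ntrs_file, conc_file)
  }
  if (!is.null(om$phospho)) {
    run_log(outdir, "omics stage: phospho array")
    phc <- om$phospho
    spec <- phospho_sim_spec(
      n_sites = phc$n_sites %||% 584,
      n_proteins = phc$n_proteins %||% 452,
      n_replicates = phc$n_replicates %||% 3,
      effects = lapply(phc$effects %||% list(), function(e)
        list(frac = e$frac, lfc_mean = e$lfc_mean, lfc_sd = e$lfc_sd %||% 0.2)))
    arr <- generate_phospho_array(spec, conditions,
                                  stage_seed(seed, "omics_phospho"))
    calls <- score_phospho(arr, threshold = om$threshold %||% 1)
    calls_file <- file.path(outdir, "phospho_calls.csv")
    write.csv(calls, calls_file, row.names = FALSE)
    files <- c(files, calls_file)
  }
  write_manifest(config, seed, outdir, "omics", files)
}

write_manifest <- function(config, seed, outdir, stage, files) {
  mf <- file.path(outdir, sprintf("manifest_%s.json", stage))
  manifest <- list(
    stage = stage,
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    package_version = as.character(utils::packageVersion("nucmorph")),
    files = basename(files),
    complete = TRUE)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
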