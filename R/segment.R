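# Threshold segmentation of nuclear / compartment channels.
#
# The contract mirrors uniform-threshold quantification pipelines: a single
# parameter set, optionally with thresholds frozen on baseline (0-h) images,
# applied unchanged across all cohorts and time points.

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in micrometres.
#' @param threshold `"otsu"` for Otsu's method per channel, or a numeric
#'   fixed threshold on the normalized \[0, 1\] intensity scale (use
#'   [estimate_threshold()] to freeze a baseline-derived value).
#' @param min_size minimum object size kept, in um^2 (2D) or um^3 (3D).
#' @param fill_holes fill interior holes of objects.
#' @param exclude_border drop objects touching the lateral (x/y) image border.
#' @param exclude_z_border drop 3D objects touching the first or last z-plane
#'   (incomplete volumes bias volumetric statistics).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 0.1, threshold = "otsu",
                                min_size = 0, fill_holes = TRUE,
                                exclude_border = FALSE,
                                exclude_z_border = TRUE) {
  stopifnot(smoothing_sigma >= 0, min_size >= 0)
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, "otsu")
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  }
  structure(list(smoothing_sigma = smoothing_sigma, threshold = threshold,
                 min_size = min_size, fill_holes = isTRUE(fill_holes),
                 exclude_border = isTRUE(exclude_border),
                 exclude_z_border = isTRUE(exclude_z_border)),
            class = "segmentation_params")
}

norm_intensity <- function(channel) {
  x <- as.numeric(channel)
  if (max(x) > 1) x <- x / 65535
  dim(x) <- dim(channel)
  x
}

#' Estimate a frozen Otsu threshold from baseline images
#'
#' Pools the intensities of one or more channels (typically all baseline
#' images of one marker) and returns the Otsu threshold of the pooled
#' histogram on the normalized \[0, 1\] scale. Passing the result as the
#' `threshold` of [segmentation_params()] applies one uniform threshold
#' across every cohort and time point.
#'
#' @param channels a single intensity array or a list of them.
#' @return Numeric threshold in \[0, 1\].
#' @export
estimate_threshold <- function(channels) {
  if (!is.list(channels)) channels <- list(channels)
  x <- unlist(lapply(channels, function(ch) as.numeric(norm_intensity(ch))))
  otsu_threshold(x)
}

# Otsu's threshold of an intensity vector in [0, 1]; EBImage's implementation
# is histogram-based, so flattening to a 2D Image is exact.
otsu_threshold <- function(x) {
  if (diff(range(x)) == 0) return(Inf)  # constant image: nothing segmentable
  n <- length(x)
  img <- EBImage::Image(x, dim = c(n, 1))
  EBImage::otsu(img, range = c(0, 1), levels = 1024)
}

segment_core <- function(channel, geometry, params) {
  x <- norm_intensity(channel)
  nd <- geometry$n_dims
  if (params$smoothing_sigma > 0) {
    sig <- params$smoothing_sigma / geometry$spacing
    x <- .gauss_blur(as.numeric(x), dim(x), sig)
    dim(x) <- dim(channel)
  }
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(as.numeric(x)) else params$threshold
  mask <- x > thr
  if (!any(mask)) {
    lab <- array(0L, dim = dim(channel))
    return(lab)
  }
  if (params$fill_holes) {
    if (nd == 2L) {
      mask <- EBImage::fillHull(mask * 1L) > 0
    } else {
      for (z in seq_len(dim(mask)[3]))
        mask[, , z] <- EBImage::fillHull(mask[, , z] * 1L) > 0
    }
  }
  lab <- .cc_label(as.logical(mask), dim(mask))
  vox <- prod(geometry$spacing)
  keep <- which(tabulate(lab[lab > 0L]) * vox >= params$min_size)
  if (params$exclude_border) {
    border <- border_labels(lab, axes = 1:2)
    keep <- setdiff(keep, border)
  }
  if (nd == 3L && params$exclude_z_border) {
    keep <- setdiff(keep, border_labels(lab, axes = 3L))
  }
  relabel(lab, keep)
}

border_labels <- function(lab, axes) {
  d <- dim(lab)
  out <- integer(0)
  idx <- function(...) unique(as.vector(lab[...]))
  for (ax in axes) {
    sl <- rep(list(quote(expr = )), length(d))
    for (side in c(1L, d[ax])) {
      sl[[ax]] <- side
      out <- c(out, unique(as.vector(do.call(`[`, c(list(lab), sl)))))
    }
    sl[[ax]] <- quote(expr = )
  }
  setdiff(unique(out), 0L)
}

relabel <- function(lab, keep) {
  map <- integer(max(lab, 1L))
  map[keep] <- seq_along(keep)
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  out
}

#' Segment a 2D channel into labeled nuclei or compartments
#'
#' Gaussian smoothing, global threshold (Otsu or fixed), optional hole
#' filling, 8-connected component labeling, minimum-size filtering and
#' optional border exclusion. Deterministic for fixed input. A
#' constant-intensity image yields zero objects.
#'
#' @param channel 2D intensity array (16-bit integers or \[0, 1\] floats).
#' @param geometry matching [image_geometry()].
#' @param params a [segmentation_params()].
#' @return An object of class `labeled_objects` with fields `label_mask`,
#'   `geometry`, `source_channel`.
#' @export
segment_2d <- function(channel, geometry, params = segmentation_params()) {
  assert_geometry(geometry, channel, n_dims = 2L)
  stopifnot(inherits(params, "segmentation_params"))
  lab <- segment_core(channel, geometry, params)
  structure(list(label_mask = lab, geometry = geometry,
                 source_channel = attr(channel, "marker") %||% NA_character_),
            class = "labeled_objects")
}

#' Segment a 3D stack into labeled volumetric objects
#'
#' As [segment_2d()] with 26-connected labeling; `min_size` is interpreted in
#' um^3, holes are filled per z-slice, and objects touching the first/last
#' z-plane are excluded by default (incomplete volumes).
#'
#' @inheritParams segment_2d
#' @return A `labeled_objects` object with a 3D `label_mask`.
#' @export
segment_3d <- function(channel, geometry, params = segmentation_params()) {
  if (length(dim(channel)) != 3L)
    stop("dimensionality error: segment_3d expects a 3D array")
  assert_geometry(geometry, channel, n_dims = 3L)
  stopifnot(inherits(params, "segmentation_params"))
  lab <- segment_core(channel, geometry, params)
  structure(list(label_mask = lab, geometry = geometry,
                 source_channel = attr(channel, "marker") %||% NA_character_),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %dD, %d object(s)\n", x$geometry$n_dims,
              max(x$label_mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
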