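#' Image geometry: array shape and physical voxel spacing
#'
#' Describes the raster a synthetic image is generated on, or a measured image
#' lives on. `spacing` is in micrometres per pixel/voxel, one entry per array
#' axis. The 3D default is anisotropic with coarser axial (z) sampling, as is
#' typical for spinning-disk confocal stacks.
#'
#' @param shape integer vector of pixels/voxels per axis (length 2 or 3, axis
#'   order x, y\[, z\]); every entry must be at least 16.
#' @param spacing numeric vector of physical sizes per axis in micrometres;
#'   all entries positive. Defaults to 0.1 um/px in x/y and 0.25 um in z.
#' @return An object of class `image_geometry`.
#' @examples
#' image_geometry(c(256, 256))
#' image_geometry(c(128, 128, 48), spacing = c(0.1, 0.1, 0.25))
#' @export
image_geometry <- function(shape, spacing = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) stop("geometry error: shape must have 2 or 3 axes")
  if (any(shape < 16L)) stop("geometry error: all shape entries must be >= 16")
  if (is.null(spacing)) spacing <- if (nd == 2L) c(0.1, 0.1) else c(0.1, 0.1, 0.25)
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("geometry error: spacing must be positive, one entry per axis")
  structure(list(n_dims = nd, shape = shape, spacing = spacing),
            class = "image_geometry")
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %dD %s px @ %s um\n", x$n_dims,
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

assert_geometry <- function(geometry, arr = NULL, n_dims = NULL) {
  if (!inherits(geometry, "image_geometry"))
    stop("geometry error: expected an image_geometry object")
  if (!is.null(n_dims) && geometry$n_dims != n_dims)
    stop(sprintf("dimensionality error: expected a %dD geometry", n_dims))
  if (!is.null(arr)) {
    d <- dim(arr)
    if (is.null(d)) d <- length(arr)
    if (length(d) != geometry$n_dims || !all(d == geometry$shape))
      stop("geometry error: array shape does not match geometry")
  }
  invisible(geometry)
}

# xy pixel size for 2D measurement; requires square pixels
xy_spacing <- function(geometry) {
  sp <- geometry$spacing[1:2]
  if (abs(sp[1] - sp[2]) > 1e-12 * sp[1])
    stop("geometry error: anisotropic in-plane pixels are not supported")
  sp[1]
}
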