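# Image and table I/O. Images travel as multi-page 16-bit TIFF (fixed
# channel order: nucleus stain, nucleolin, fibrillarin, SC-35; for stacks,
# all z planes of a channel are consecutive) with a JSON sidecar recording
# the physical voxel spacing, channel names and seed.

#' Write a synthetic image as multi-page TIFF plus JSON sidecar
#'
#' @param img a `synthetic_image` from [generate_image()].
#' @param path_prefix output path without extension; writes
#'   `<prefix>.tif` and `<prefix>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_synthetic_image <- function(img, path_prefix) {
  stopifnot(inherits(img, "synthetic_image"))
  geom <- img$geometry
  pages <- list()
  for (ch in names(img$channels)) {
    arr <- img$channels[[ch]] / 65535
    if (geom$n_dims == 2L) {
      pages[[length(pages) + 1L]] <- arr
    } else {
      for (z in seq_len(geom$shape[3]))
        pages[[length(pages) + 1L]] <- arr[, , z]
    }
  }
  tif <- paste0(path_prefix, ".tif")
  side <- paste0(path_prefix, ".json")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  jsonlite::write_json(
    list(n_dims = geom$n_dims, shape = geom$shape,
         spacing_um = geom$spacing, channel_names = names(img$channels),
         seed = img$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, side))
}

#' Read an image written by [write_synthetic_image()]
#'
#' @param path_prefix path without extension.
#' @return A list with `channels` (named 16-bit integer arrays) and
#'   `geometry`, plus the stored `seed`.
#' @export
read_image <- function(path_prefix) {
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path_prefix, ".tif"), all = TRUE)
  geom <- image_geometry(side$shape, side$spacing_um)
  nz <- if (geom$n_dims == 3L) geom$shape[3] else 1L
  channels <- list()
  for (i in seq_along(side$channel_names)) {
    if (geom$n_dims == 2L) {
      arr <- round(pages[[i]] * 65535)
    } else {
      arr <- array(0, dim = geom$shape)
      for (z in seq_len(nz)) arr[, , z] <- pages[[(i - 1L) * nz + z]]
      arr <- round(arr * 65535)
    }
    storage.mode(arr) <- "integer"
    channels[[side$channel_names[i]]] <- arr
  }
  list(channels = channels, geometry = geom, seed = side$seed)
}
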