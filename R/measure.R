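# Morphometry in physical units. Pixel units are never exposed.

#' Measure area, perimeter and circularity of labeled 2D objects
#'
#' Area is pixel count times pixel area. The perimeter is the length of the
#' 0.5-level marching-squares contour of the object mask smoothed with a
#' fixed Gaussian (sigma 1.5 px), which is accurate to well under 1% on
#' digitized discs of radius 20 px and above while keeping a digitized
#' square's circularity within 0.03 of the closed form pi/4. Circularity is
#' `min(1, 4*pi*A / P^2)`.
#'
#' @param objects a `labeled_objects` from [segment_2d()] (or any integer
#'   label mask wrapped in one).
#' @return A data frame with one row per label: `label`, `area_um2`,
#'   `perimeter_um`, `circularity`, `centroid_x_um`, `centroid_y_um`.
#' @examples
#' geom <- image_geometry(c(64, 64))
#' mask <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 32)^2 <= 20^2)
#' obj <- segment_2d(mask * 1.0, geom, segmentation_params(smoothing_sigma = 0))
#' measure_2d(obj)
#' @export
measure_2d <- function(objects) {
  stopifnot(inherits(objects, "labeled_objects"))
  geom <- objects$geometry
  assert_geometry(geom, objects$label_mask, n_dims = 2L)
  sp <- xy_spacing(geom)
  lab <- objects$label_mask
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  out <- vector("list", n)
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx) * sp^2
    per <- contour_perimeter(lab, l, idx) * sp
    out[[l]] <- data.frame(
      label = l, area_um2 = area, perimeter_um = per,
      circularity = min(1, 4 * pi * area / per^2),
      centroid_x_um = mean(idx[, 1] - 0.5) * sp,
      centroid_y_um = mean(idx[, 2] - 0.5) * sp)
  }
  do.call(rbind, out)
}

# marching-squares contour length (in pixel units) of one label, measured on
# the mask smoothed with a fixed sigma of 1.5 px
contour_perimeter <- function(lab, l, idx, smooth_sigma = 1.5) {
  pad <- 6L
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(dim(lab), apply(idx, 2, max) + pad)
  sub <- lab[lo[1]:hi[1], lo[2]:hi[2]] == l
  m <- matrix(0, nrow(sub) + 2 * pad, ncol(sub) + 2 * pad)
  m[pad + seq_len(nrow(sub)), pad + seq_len(ncol(sub))] <- sub
  if (smooth_sigma > 0) {
    m2 <- .gauss_blur(as.numeric(m), dim(m), c(smooth_sigma, smooth_sigma))
    dim(m2) <- dim(m)
    m <- m2
  }
  cl <- grDevices::contourLines(seq_len(nrow(m)), seq_len(ncol(m)), m,
                                levels = 0.5)
  sum(vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)), 0))
}

#' Measure volume, iso-surface area and sphericity of labeled 3D objects
#'
#' Volume is voxel count times voxel volume. Surface area comes from a
#' marching-tetrahedra iso-surface of the object mask (smoothed with a fixed
#' sigma of 0.8 voxels to suppress voxelization staircase bias) at the 0.5
#' level, with the physical voxel spacing applied. Sphericity is
#' `min(1, pi^(1/3) * (6 V)^(2/3) / SA)`. Single-voxel objects have a
#' degenerate mesh and are reported with `NA` surface and sphericity plus a
#' warning.
#'
#' @param objects a `labeled_objects` from [segment_3d()].
#' @return A data frame with one row per label: `label`, `volume_um3`,
#'   `surface_um2`, `sphericity`, `centroid_x_um`, `centroid_y_um`,
#'   `centroid_z_um`.
#' @export
measure_3d <- function(objects) {
  stopifnot(inherits(objects, "labeled_objects"))
  geom <- objects$geometry
  assert_geometry(geom, objects$label_mask, n_dims = 3L)
  sp <- geom$spacing
  voxvol <- prod(sp)
  lab <- objects$label_mask
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), volume_um3 = numeric(0),
                      surface_um2 = numeric(0), sphericity = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_z_um = numeric(0)))
  out <- vector("list", n)
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    vol <- nrow(idx) * voxvol
    cen <- (colMeans(idx) - 0.5) * sp
    if (nrow(idx) < 2L) {
      warning(sprintf("label %d has a degenerate (single-voxel) mesh; surface skipped", l))
      out[[l]] <- data.frame(label = l, volume_um3 = vol,
                             surface_um2 = NA_real_, sphericity = NA_real_,
                             centroid_x_um = cen[1], centroid_y_um = cen[2],
                             centroid_z_um = cen[3])
      next
    }
    sa <- label_surface_area(lab, l, idx, sp)
    out[[l]] <- data.frame(
      label = l, volume_um3 = vol, surface_um2 = sa,
      sphericity = min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / sa),
      centroid_x_um = cen[1], centroid_y_um = cen[2], centroid_z_um = cen[3])
  }
  do.call(rbind, out)
}

label_surface_area <- function(lab, l, idx, sp, smooth_sigma = 0.8) {
  pad <- 5L
  lo <- pmax(1L, apply(idx, 2, min) - pad)
  hi <- pmin(dim(lab), apply(idx, 2, max) + pad)
  sub <- (lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] == l) * 1.0
  d <- dim(sub)
  if (smooth_sigma > 0) {
    # isotropic *physical* smoothing scaled to the coarsest axis: staircase
    # steps on anisotropic grids extend laterally over max(sp)/sp voxels
    sig <- smooth_sigma * max(sp) / sp
    sub <- .gauss_blur(as.numeric(sub), d, sig)
  }
  .mt_surface_area(as.numeric(sub), d, sp, 0.5)
}

#' Assign compartment objects to parent objects
#'
#' Each child is assigned to the parent label holding the majority of its
#' pixels/voxels; children overlapping no parent by at least 50% are listed
#' as orphans. On an exact 50/50 split the lower parent label wins
#' (determinism).
#'
#' @param parents,children `labeled_objects` on the same geometry.
#' @return A list with `assignment` (data frame `child_label`,
#'   `parent_label`) and `orphans` (integer vector of child labels).
#' @export
assign_compartments <- function(parents, children) {
  stopifnot(inherits(parents, "labeled_objects"),
            inherits(children, "labeled_objects"))
  if (!identical(parents$geometry, children$geometry))
    stop("geometry error: parents and children must share a geometry")
  pl <- parents$label_mask
  cl <- children$label_mask
  n_child <- max(cl)
  assignment <- data.frame(child_label = integer(0), parent_label = integer(0))
  orphans <- integer(0)
  for (ch in seq_len(n_child)) {
    sel <- cl == ch
    total <- sum(sel)
    pv <- pl[sel]
    counts <- tabulate(pv[pv > 0L])
    if (!length(counts) || max(counts) / total < 0.5) {
      orphans <- c(orphans, ch)
      next
    }
    best <- which(counts == max(counts))[1]  # ties: lower label
    assignment <- rbind(assignment,
                        data.frame(child_label = ch, parent_label = best))
  }
  list(assignment = assignment, orphans = orphans)
}
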