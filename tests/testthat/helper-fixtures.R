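# Rasterized reference shapes and small reusable specs, built in code.

raster_disc <- function(r, pad = 6L, spacing = 0.1) {
  n <- 2L * (r + pad) + 1L
  cx <- r + pad + 1L
  mask <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
  list(mask = mask * 1.0, geometry = image_geometry(c(n, n), rep(spacing, 2)))
}

raster_square <- function(side, pad = 10L, spacing = 0.1) {
  n <- side + 2L * pad
  mask <- matrix(0, n, n)
  mask[pad + seq_len(side), pad + seq_len(side)] <- 1
  list(mask = mask, geometry = image_geometry(c(n, n), rep(spacing, 2)))
}

raster_ball_fix <- function(r_vox, spacing = c(0.1, 0.1, 0.1), pad = 6L) {
  r_um <- r_vox * spacing
  n <- 2L * (r_vox + pad) + 1L
  n <- rep(max(n), 3L)
  cx <- (n %/% 2L) + 1L
  ax <- lapply(1:3, function(d) ((seq_len(n[d]) - cx[d]) * spacing[d])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- array(d2 <= (r_vox * spacing[1])^2, dim = n)
  list(mask = mask * 1.0, geometry = image_geometry(n, spacing),
       r_um = r_vox * spacing[1])
}

raster_cube <- function(side_vox, spacing = 1, pad = 8L) {
  n <- rep(side_vox + 2L * pad, 3L)
  mask <- array(0, dim = n)
  mask[pad + seq_len(side_vox), pad + seq_len(side_vox),
       pad + seq_len(side_vox)] <- 1
  list(mask = mask, geometry = image_geometry(n, rep(spacing, 3)),
       side_um = side_vox * spacing)
}

raster_ellipsoid <- function(semi_um, spacing = c(0.1, 0.1, 0.1), pad = 6L) {
  n <- 2L * ceiling(semi_um / spacing) + 2L * pad + 1L
  cx <- (n %/% 2L) + 1L
  ax <- lapply(1:3, function(d) ((seq_len(n[d]) - cx[d]) * spacing[d] / semi_um[d])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- array(d2 <= 1, dim = n)
  list(mask = mask * 1.0, geometry = image_geometry(n, spacing))
}

# closed-form surface area of an axis-aligned ellipsoid with semi-axes
# a >= b = c (prolate spheroid)
prolate_surface <- function(a, c) {
  e <- sqrt(1 - (c / a)^2)
  2 * pi * c^2 * (1 + (a / c) * asin(e) / e)
}

as_labeled <- function(mask, geometry) {
  lab <- array(0L, dim = dim(mask))
  lab[mask > 0] <- 1L
  structure(list(label_mask = lab, geometry = geometry,
                 source_channel = NA_character_),
            class = "labeled_objects")
}

noiseless <- function() noise_spec(background = 0, psf_sigma = 0,
                                   gaussian_sigma = 0, photon_scale = 0)

random_de_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    condition = "cond",
    log2fc = rnorm(n, 0, 1.5),
    fdr = runif(n),
    go_category = sample(c("chromatin_remodeling", "nuclear_membrane",
                           "nucleolus", "other"), n, replace = TRUE))
}
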