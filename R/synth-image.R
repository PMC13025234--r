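# Seeded simulation of multi-channel nuclear images with exact ground truth.
#
# Nuclei are analytic star-shaped domains (see shapes.R); subnuclear
# compartments are discs/spheres placed with strict containment inside their
# parent (fibrillarin inside nucleolin, nucleolin and SC-35 speckles inside
# the nucleus). Ground-truth size and shape are computed from the analytic
# geometry, not from the raster, and reported per object alongside the label
# masks. Rendering follows analytic shape -> binary raster -> Gaussian PSF
# blur -> additive Gaussian + optional Poisson-scaled noise -> 16-bit
# quantization.

CHANNEL_ORDER <- c("nucleus", "nucleolin", "fibrillarin", "sc35")

#' Nuclear cohort phenotype specification
#'
#' Describes the per-cohort distribution of nuclear size and boundary
#' irregularity that the image generator draws from. If `target_shape` is
#' given, the boundary perturbation (2D) or axial flattening (3D) of every
#' nucleus is calibrated so its analytic circularity/sphericity equals the
#' target; otherwise `irregularity_amplitude` is applied as-is.
#'
#' @param n_cells number of nuclei to place in the field.
#' @param mean_size mean nuclear area (um^2, 2D) or volume (um^3, 3D).
#' @param size_cv coefficient of variation of the lognormal size distribution.
#' @param irregularity_amplitude boundary perturbation amplitude as a fraction
#'   of the radius, in \[0, 0.5\].
#' @param irregularity_harmonics number of angular (2D) or spherical-harmonic
#'   degree (3D) perturbation modes.
#' @param target_shape optional target circularity (2D) or sphericity (3D) in
#'   (0, 1\]; when set, each nucleus is calibrated to it exactly (analytically).
#' @return An object of class `nuclear_phenotype_spec`.
#' @export
nuclear_phenotype_spec <- function(n_cells, mean_size, size_cv = 0.2,
                                   irregularity_amplitude = 0.08,
                                   irregularity_harmonics = 4,
                                   target_shape = NA_real_) {
  stopifnot(n_cells >= 1, mean_size > 0, size_cv >= 0,
            irregularity_amplitude >= 0, irregularity_amplitude <= 0.5,
            irregularity_harmonics >= 1)
  if (!is.na(target_shape)) stopifnot(target_shape > 0, target_shape <= 1)
  structure(list(n_cells = as.integer(n_cells), mean_size = mean_size,
                 size_cv = size_cv,
                 irregularity_amplitude = irregularity_amplitude,
                 irregularity_harmonics = as.integer(irregularity_harmonics),
                 target_shape = target_shape),
            class = "nuclear_phenotype_spec")
}

#' Subnuclear compartment specification
#'
#' @param marker one of `"nucleolin"`, `"fibrillarin"`, `"sc35"`.
#' @param count_mean expected (Poisson) object count per nucleus.
#' @param size_mean mean object size in um^2 (2D) or um^3 (3D).
#' @param size_sigma lognormal sigma (sd of log size).
#' @param nesting parent marker name, or `NULL` to nest directly in the
#'   nucleus. Fibrillarin foci conventionally nest inside nucleolin domains.
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(marker, count_mean, size_mean, size_sigma = 0.4,
                             nesting = NULL) {
  marker <- match.arg(marker, c("nucleolin", "fibrillarin", "sc35"))
  stopifnot(count_mean >= 0, size_mean > 0, size_sigma >= 0)
  if (!is.null(nesting))
    nesting <- match.arg(nesting, c("nucleolin", "sc35"))
  structure(list(marker = marker, count_mean = count_mean,
                 size_mean = size_mean, size_sigma = size_sigma,
                 nesting = nesting),
            class = "compartment_spec")
}

#' Acquisition noise specification
#'
#' @param background background intensity offset (fraction of full scale).
#' @param psf_sigma Gaussian PSF sigma in micrometres.
#' @param gaussian_sigma additive Gaussian read-noise sd (fraction of full scale).
#' @param photon_scale photons per unit intensity for Poisson shot noise;
#'   0 disables shot noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background = 0.05, psf_sigma = 0.1,
                       gaussian_sigma = 0.01, photon_scale = 0) {
  stopifnot(background >= 0, psf_sigma >= 0, gaussian_sigma >= 0,
            photon_scale >= 0)
  structure(list(background = background, psf_sigma = psf_sigma,
                 gaussian_sigma = gaussian_sigma, photon_scale = photon_scale),
            class = "noise_spec")
}

lognormal_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# sample one nucleus shape; returns pattern, amplitude, flattening, scale and
# analytic truth metrics
sample_nucleus <- function(spec, n_dims) {
  lp <- lognormal_pars(spec$mean_size, spec$size_cv)
  size <- if (spec$size_cv > 0) rlnorm(1, lp$meanlog, lp$sdlog) else spec$mean_size
  if (n_dims == 2L) {
    pat <- fourier_pattern(spec$irregularity_harmonics)
    a <- if (!is.na(spec$target_shape)) {
      calibrate_amplitude_2d(pat, spec$target_shape)
    } else spec$irregularity_amplitude
    m1 <- shape2d_metrics(pat, a, R = 1)
    R <- sqrt(size / m1$area)
    m <- list(area = size, perimeter = m1$perimeter * R,
              circularity = m1$circularity)
    theta <- seq(0, 2 * pi, length.out = 257)[1:256]
    rb <- R * max(1 + a * fourier_eval(pat, theta))
    list(n_dims = 2L, pat = pat, amplitude = a, q = 1, R = R,
         bound_xy = rb, bound_z = NA_real_, metrics = m)
  } else {
    pat <- sh_pattern(spec$irregularity_harmonics)
    a <- spec$irregularity_amplitude
    ev <- shape3d_evaluator(pat, a)
    q <- if (!is.na(spec$target_shape)) {
      calibrate_flattening_3d(pat, a, spec$target_shape, evaluator = ev)
    } else 0.45
    m1 <- ev(q)
    R <- (size / m1$volume)^(1 / 3)
    m <- list(volume = size, surface = m1$surface * R^2,
              sphericity = m1$sphericity)
    pk <- 1 + a * 3  # conservative bound on the unit-RMS perturbation
    list(n_dims = 3L, pat = pat, amplitude = a, q = q, R = R,
         bound_xy = R * pk, bound_z = R * q * pk, metrics = m)
  }
}

# rejection-sampling placement of nucleus centres in the xy plane with an
# inter-nucleus margin of one (mean) object radius
place_nuclei <- function(bounds_xy, field_um, max_retries = 1000L,
                         max_restarts = 25L) {
  n <- length(bounds_xy)
  for (attempt in seq_len(max_restarts)) {
    cx <- numeric(n)
    cy <- numeric(n)
    failed <- FALSE
    for (i in seq_len(n)) {
      rb <- bounds_xy[i]
      lox <- rb + 0.02 * field_um[1]
      loy <- rb + 0.02 * field_um[2]
      hix <- field_um[1] - lox
      hiy <- field_um[2] - loy
      if (hix <= lox || hiy <= loy)
        stop("field too crowded: nucleus does not fit in the field")
      ok <- FALSE
      for (t in seq_len(max_retries %/% max_restarts + 1L)) {
        x <- runif(1, lox, hix)
        y <- runif(1, loy, hiy)
        if (i == 1L) { ok <- TRUE }
        else {
          dmin <- (bounds_xy[1:(i - 1)] + rb) * 1.5  # touching + 1 mean radius
          ok <- all(sqrt((cx[1:(i - 1)] - x)^2 + (cy[1:(i - 1)] - y)^2) >= dmin)
        }
        if (ok) { cx[i] <- x; cy[i] <- y; break }
      }
      if (!ok) { failed <- TRUE; break }
    }
    if (!failed) return(cbind(x = cx, y = cy))
  }
  stop("field too crowded: placement failed after bounded retries")
}

# voxelization helpers: each returns the linear indices (into the full
# array) of raster cells whose centre lies inside the analytic object

bbox_axes <- function(geometry, center, bound) {
  sp <- geometry$spacing
  nd <- geometry$n_dims
  bound <- rep(bound, length.out = nd)
  lo <- pmax(1L, floor((center - bound) / sp[seq_len(nd)]) + 1L)
  hi <- pmin(geometry$shape, ceiling((center + bound) / sp[seq_len(nd)]) + 1L)
  if (any(hi < lo)) return(NULL)
  list(lo = lo, hi = hi,
       ax = lapply(seq_len(nd), function(d)
         ((lo[d]:hi[d]) - 0.5) * sp[d] - center[d]))
}

linear_index <- function(geometry, bb, which_in) {
  n1 <- bb$hi[1] - bb$lo[1] + 1L
  n2 <- bb$hi[2] - bb$lo[2] + 1L
  if (geometry$n_dims == 2L) {
    i <- (which_in - 1L) %% n1
    j <- (which_in - 1L) %/% n1
    (bb$lo[1] + i) + (bb$lo[2] + j - 1L) * geometry$shape[1]
  } else {
    i <- (which_in - 1L) %% n1
    rest <- (which_in - 1L) %/% n1
    j <- rest %% n2
    k <- rest %/% n2
    (bb$lo[1] + i) + (bb$lo[2] + j - 1L) * geometry$shape[1] +
      (bb$lo[3] + k - 1L) * geometry$shape[1] * geometry$shape[2]
  }
}

raster_ball <- function(geometry, center, r_obj) {
  bb <- bbox_axes(geometry, center, r_obj)
  if (is.null(bb)) return(integer(0))
  d2 <- Reduce(function(a, b) outer(a, b, `+`),
               lapply(bb$ax, function(v) v^2))
  linear_index(geometry, bb, which(d2 <= r_obj^2))
}

raster_shape2d <- function(geometry, center, nu) {
  bb <- bbox_axes(geometry, center, nu$bound_xy)
  if (is.null(bb)) return(integer(0))
  n1 <- length(bb$ax[[1]])
  n2 <- length(bb$ax[[2]])
  X <- matrix(bb$ax[[1]], n1, n2)
  Y <- matrix(bb$ax[[2]], n1, n2, byrow = TRUE)
  rad <- sqrt(X^2 + Y^2)
  rshape <- nu$R * (1 + nu$amplitude * fourier_eval(nu$pat, atan2(Y, X)))
  linear_index(geometry, bb, which(rad <= rshape))
}

raster_shape3d <- function(geometry, center, nu) {
  bb <- bbox_axes(geometry, center, c(nu$bound_xy, nu$bound_xy, nu$bound_z))
  if (is.null(bb)) return(integer(0))
  n1 <- length(bb$ax[[1]]); n2 <- length(bb$ax[[2]]); n3 <- length(bb$ax[[3]])
  X <- array(bb$ax[[1]], c(n1, n2, n3))
  Y <- array(rep(bb$ax[[2]], each = n1), c(n1, n2, n3))
  Z <- array(rep(bb$ax[[3]], each = n1 * n2), c(n1, n2, n3))
  rad <- sqrt(X^2 + Y^2 + Z^2)
  cth <- pmin(1, pmax(-1, ifelse(rad > 0, Z / rad, 1)))
  base <- nu$R / sqrt(1 - cth^2 + cth^2 / nu$q^2)
  band <- nu$amplitude * 3  # conservative bound on the unit-RMS perturbation
  inside <- rad <= base * (1 - band)
  shell <- which(!inside & rad <= base * (1 + band))
  if (length(shell)) {
    theta <- acos(cth[shell])
    phi <- atan2(Y[shell], X[shell])
    rs <- nu$R * shape3d_radius(nu$pat, nu$amplitude, nu$q, theta, phi)
    inside[shell] <- rad[shell] <= rs
  }
  linear_index(geometry, bb, which(inside))
}

# place a disc/sphere compartment fully inside a star-shaped parent; the
# candidate is accepted only if a dense ring of its boundary points lies
# radially inside the parent with one-voxel margin
place_in_parent <- function(parent_center, parent_radius_fn, r_obj, margin,
                            siblings, n_dims, max_retries = 200L) {
  # 2D radius functions take the planar angle as their first argument
  prad <- function(theta, phi) {
    if (n_dims == 2L) parent_radius_fn(phi, NULL) else parent_radius_fn(theta, phi)
  }
  for (t in seq_len(max_retries)) {
    dir_phi <- runif(1, 0, 2 * pi)
    dir_th <- if (n_dims == 3L) acos(runif(1, -1, 1)) else pi / 2
    u <- runif(1)^(1 / n_dims)
    pr <- prad(dir_th, dir_phi)
    d <- u * max(0, pr - r_obj - margin)
    off <- d * c(sin(dir_th) * cos(dir_phi), sin(dir_th) * sin(dir_phi),
                 cos(dir_th))[seq_len(n_dims)]
    cand <- parent_center + off
    # containment check on a dense deterministic sample of the compartment
    # boundary (the parent boundary is band-limited, so this cannot miss a
    # violating sector)
    if (n_dims == 2L) {
      k <- 96L
      bph <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
      bth <- rep(pi / 2, k)
    } else {
      k <- 256L
      i_fib <- seq_len(k) - 0.5
      bph <- (2 * pi * i_fib * (sqrt(5) - 1) / 2) %% (2 * pi)
      bth <- acos(1 - 2 * i_fib / k)
    }
    bpts <- matrix(cand - parent_center, k, n_dims, byrow = TRUE) +
      r_obj * cbind(sin(bth) * cos(bph), sin(bth) * sin(bph),
                    cos(bth))[, seq_len(n_dims), drop = FALSE]
    brad <- sqrt(rowSums(bpts^2))
    bphi <- atan2(bpts[, 2], bpts[, 1])
    btheta <- if (n_dims == 3L) {
      acos(pmin(1, pmax(-1, ifelse(brad > 0, bpts[, 3] / brad, 1))))
    } else rep(pi / 2, k)
    if (any(brad + margin > prad(btheta, bphi))) next
    if (length(siblings)) {
      ok <- TRUE
      for (s in siblings) {
        if (sqrt(sum((s$center - cand)^2)) < s$r + r_obj) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    return(cand)
  }
  NULL
}

#' Generate a synthetic multi-channel nuclear image with ground truth
#'
#' Places `spec$n_cells` analytically defined nuclei in the field without
#' overlap, nests compartment objects inside them per `compartments`, renders
#' every channel at 16 bits with the requested noise model, and returns label
#' masks plus a ground-truth metric table computed from the analytic
#' generator geometry (not from the raster). Identical `(spec, seed)` yields
#' bit-identical output.
#'
#' @param spec a [nuclear_phenotype_spec()].
#' @param compartments list of [compartment_spec()] objects.
#' @param noise a [noise_spec()].
#' @param geometry an [image_geometry()] (2D or 3D).
#' @param seed integer seed.
#' @return An object of class `synthetic_image`: list with `geometry`,
#'   `channels` (named 16-bit integer arrays), `truth_masks` (named label
#'   arrays), `truth_metrics` (data frame), `seed`.
#' @examples
#' geom <- image_geometry(c(96, 96))
#' img <- generate_image(nuclear_phenotype_spec(1, mean_size = 20),
#'                       geometry = geom, seed = 1)
#' img$truth_metrics
#' @export
generate_image <- function(spec, compartments = list(), noise = noise_spec(),
                           geometry, seed) {
  stopifnot(inherits(spec, "nuclear_phenotype_spec"),
            inherits(noise, "noise_spec"))
  assert_geometry(geometry)
  for (cs in compartments) stopifnot(inherits(cs, "compartment_spec"))
  nd <- geometry$n_dims
  set.seed(stage_seed(seed, "image"))

  nuclei <- lapply(seq_len(spec$n_cells), function(i) sample_nucleus(spec, nd))
  field_um <- geometry$shape[1:2] * geometry$spacing[1:2]
  centers_xy <- place_nuclei(vapply(nuclei, `[[`, 0, "bound_xy"), field_um)
  zmid <- if (nd == 3L) geometry$shape[3] * geometry$spacing[3] / 2 else NULL
  if (nd == 3L) {
    zb <- vapply(nuclei, `[[`, 0, "bound_z")
    if (any(zb + 2 * geometry$spacing[3] > zmid))
      stop("field too crowded: nucleus does not fit in the axial extent")
  }

  zero <- array(0L, dim = geometry$shape)
  masks <- list(nucleus = zero, nucleolin = zero, fibrillarin = zero,
                sc35 = zero)
  metrics <- list()
  nuc_objects <- list()

  make_rfun <- function(nu) {
    force(nu)
    if (nd == 2L) {
      function(theta, phi) nu$R * (1 + nu$amplitude * fourier_eval(nu$pat, theta))
    } else {
      function(theta, phi) nu$R * shape3d_radius(nu$pat, nu$amplitude, nu$q, theta, phi)
    }
  }
  for (i in seq_along(nuclei)) {
    nu <- nuclei[[i]]
    center <- c(centers_xy[i, ], zmid)[seq_len(nd)]
    rfun <- make_rfun(nu)
    idx <- if (nd == 2L) raster_shape2d(geometry, center, nu) else
      raster_shape3d(geometry, center, nu)
    masks$nucleus[idx] <- i
    row <- c(list(channel = "nucleus", label = i), nu$metrics,
             as.list(stats::setNames(center, c("x", "y", "z")[seq_len(nd)])))
    metrics[[length(metrics) + 1L]] <- row
    nuc_objects[[i]] <- list(center = center, rfun = rfun)
  }

  # compartments: parents before children
  ord <- order(vapply(compartments, function(cs) !is.null(cs$nesting), TRUE))
  placed <- list(nucleolin = list(), fibrillarin = list(), sc35 = list())
  margin <- 1.5 * max(geometry$spacing)
  for (cs in compartments[ord]) {
    lp <- lognormal_pars(cs$size_mean, NULL)
    sdlog <- cs$size_sigma
    meanlog <- log(cs$size_mean) - sdlog^2 / 2
    for (i in seq_along(nuc_objects)) {
      n_obj <- rpois(1, cs$count_mean)
      if (n_obj == 0) next
      parents <- if (is.null(cs$nesting)) {
        list(nuc_objects[[i]])
      } else {
        Filter(function(p) p$nucleus == i, placed[[cs$nesting]])
      }
      if (!length(parents)) next
      for (j in seq_len(n_obj)) {
        size <- rlnorm(1, meanlog, sdlog)
        r_obj <- if (nd == 2L) sqrt(size / pi) else (3 * size / (4 * pi))^(1 / 3)
        par <- parents[[sample.int(length(parents), 1)]]
        prf <- if (!is.null(par$rfun)) {
          par$rfun
        } else {
          function(theta, phi) par$r  # disc/sphere parent
        }
        sibs <- Filter(function(s) s$nucleus == i, placed[[cs$marker]])
        cand <- place_in_parent(par$center, prf, r_obj, margin, sibs, nd)
        if (is.null(cand)) next
        lab <- length(placed[[cs$marker]]) + 1L
        masks[[cs$marker]][raster_ball(geometry, cand, r_obj)] <- lab
        placed[[cs$marker]][[lab]] <- list(center = cand, r = r_obj,
                                           nucleus = i)
        sz <- if (nd == 2L) {
          list(area = pi * r_obj^2, perimeter = 2 * pi * r_obj,
               circularity = 1)
        } else {
          list(volume = 4 / 3 * pi * r_obj^3, surface = 4 * pi * r_obj^2,
               sphericity = 1)
        }
        metrics[[length(metrics) + 1L]] <-
          c(list(channel = cs$marker, label = lab), sz,
            as.list(stats::setNames(cand, c("x", "y", "z")[seq_len(nd)])))
      }
    }
  }

  truth <- do.call(rbind, lapply(metrics, function(m) as.data.frame(m)))
  if (nd == 2L) {
    names(truth)[names(truth) == "area"] <- "area_um2"
    names(truth)[names(truth) == "perimeter"] <- "perimeter_um"
  } else {
    names(truth)[names(truth) == "volume"] <- "volume_um3"
    names(truth)[names(truth) == "surface"] <- "surface_um2"
  }

  channels <- lapply(CHANNEL_ORDER, function(ch) {
    render_channel(masks[[ch]], geometry, noise)
  })
  names(channels) <- CHANNEL_ORDER

  structure(list(geometry = geometry, channels = channels,
                 truth_masks = masks, truth_metrics = truth, seed = seed),
            class = "synthetic_image")
}

render_channel <- function(mask, geometry, noise) {
  has_fg <- any(mask > 0L)
  img <- 0.7 * (mask > 0L) + noise$background
  if (noise$psf_sigma > 0 && has_fg) {
    sig <- noise$psf_sigma / geometry$spacing
    img <- .gauss_blur(as.numeric(img), dim(mask), sig)
  }
  if (noise$photon_scale > 0) {
    img <- rpois(length(img), pmax(img, 0) * noise$photon_scale) /
      noise$photon_scale
  }
  if (noise$gaussian_sigma > 0) {
    img <- img + rnorm(length(img), 0, noise$gaussian_sigma)
  }
  out <- as.integer(round(pmin(pmax(img, 0), 1) * 65535))
  dim(out) <- dim(mask)
  out
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image> %dD, %d channel(s), %d truth objects, seed %s\n",
              x$geometry$n_dims, length(x$channels), nrow(x$truth_metrics),
              format(x$seed)))
  invisible(x)
}
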