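# Analytic shape models behind the synthetic nuclei.
#
# 2D nuclei are star-shaped domains r(theta) = R * (1 + a * f(theta)) where f
# is a truncated Fourier series over harmonics k = 2 .. 1+H with random
# coefficients normalized to unit root-mean-square. 3D nuclei are oblate
# ellipsoids (adherent-cell nuclei are flattened along the optical axis) with
# the same kind of band-limited perturbation built from real spherical
# harmonics (degrees 2 .. 1+H). Area/perimeter (2D) and volume/surface (3D)
# are computed from the analytic radial function by quadrature, never from
# the raster; that is what the generator reports as ground truth.

# ---- 2D Fourier boundary ----------------------------------------------------

fourier_pattern <- function(n_harmonics) {
  stopifnot(n_harmonics >= 1)
  k <- seq(2L, 1L + n_harmonics)
  coef <- rnorm(length(k))
  coef <- coef / sqrt(sum(coef^2) / 2)  # RMS of sum over theta = 1
  list(k = k, coef = coef, phase = runif(length(k), 0, 2 * pi))
}

fourier_eval <- function(pat, theta, deriv = FALSE) {
  out <- numeric(length(theta))
  for (i in seq_along(pat$k)) {
    k <- pat$k[i]
    out <- out + if (deriv) {
      -pat$coef[i] * k * sin(k * theta + pat$phase[i])
    } else {
      pat$coef[i] * cos(k * theta + pat$phase[i])
    }
  }
  out
}

# Analytic area, perimeter, circularity of r(theta) = R (1 + a f(theta)).
# The integrand is band-limited, so the trapezoid rule on a uniform grid
# converges spectrally; n = 2048 is far below 1e-6 error for the harmonic
# counts used here.
shape2d_metrics <- function(pat, amplitude, R = 1, n = 2048L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  dth <- 2 * pi / n
  r <- R * (1 + amplitude * fourier_eval(pat, theta))
  rp <- R * amplitude * fourier_eval(pat, theta, deriv = TRUE)
  if (any(r <= 0)) return(list(area = NA_real_, perimeter = NA_real_, circularity = NA_real_))
  area <- 0.5 * sum(r^2) * dth
  per <- sum(sqrt(r^2 + rp^2)) * dth
  list(area = area, perimeter = per,
       circularity = min(1, 4 * pi * area / per^2))
}

# Smallest amplitude whose analytic circularity hits `target`; the circularity
# of this family decreases monotonically in the amplitude. Returns the cap
# when the target is below what the pattern can reach at `amax`.
calibrate_amplitude_2d <- function(pat, target, amax = 0.5) {
  stopifnot(target > 0, target <= 1)
  f <- function(a) {
    m <- shape2d_metrics(pat, a)
    if (is.na(m$circularity)) return(-1) # radius went negative: too irregular
    m$circularity - target
  }
  if (f(amax) >= 0) return(amax)
  uniroot(f, c(0, amax), tol = 1e-5)$root
}

# ---- 3D oblate ellipsoid + spherical-harmonic boundary ----------------------

sh_pattern <- function(n_harmonics) {
  stopifnot(n_harmonics >= 1)
  terms <- list()
  for (l in seq(2L, 1L + n_harmonics)) {
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m)) *
        (if (m > 0) sqrt(2) else 1)
      terms[[length(terms) + 1L]] <- list(l = l, m = m, kind = "c", nrm = nrm)
      if (m > 0)
        terms[[length(terms) + 1L]] <- list(l = l, m = m, kind = "s", nrm = nrm)
    }
  }
  coef <- rnorm(length(terms))
  coef <- coef / sqrt(sum(coef^2))
  list(terms = terms, coef = coef)
}

# Associated Legendre functions P_l^m(x) (Condon-Shortley phase) for all
# l = 0..lmax, m = 0..l, by the standard upward recurrence, vectorized in x.
# Returned as a list indexed by l+1 of matrices with m+1 rows.
assoc_legendre_all <- function(lmax, x) {
  n <- length(x)
  s <- sqrt(pmax(0, 1 - x^2))
  out <- lapply(0:lmax, function(l) matrix(0, l + 1L, n))
  for (m in 0:lmax) {
    pmm <- if (m == 0) rep(1, n) else
      (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * s^m
    out[[m + 1L]][m + 1L, ] <- pmm
    if (m < lmax) {
      pm1 <- x * (2 * m + 1) * pmm
      out[[m + 2L]][m + 1L, ] <- pm1
      if (m + 2L <= lmax) {
        for (l in (m + 2L):lmax) {
          p <- ((2 * l - 1) * x * pm1 - (l + m - 1) * pmm) / (l - m)
          out[[l + 1L]][m + 1L, ] <- p
          pmm <- pm1
          pm1 <- p
        }
      }
    }
  }
  out
}

# Orthonormal-basis expansion scaled so the RMS of the field over the sphere
# is 1.
sh_eval <- function(pat, theta, phi) {
  x <- cos(theta)
  out <- numeric(length(theta))
  lmax <- max(vapply(pat$terms, function(t) t$l, 0))
  leg <- assoc_legendre_all(lmax, x)
  for (i in seq_along(pat$terms)) {
    tm <- pat$terms[[i]]
    P <- leg[[tm$l + 1L]][tm$m + 1L, ]
    ang <- if (tm$kind == "c") cos(tm$m * phi) else sin(tm$m * phi)
    out <- out + pat$coef[i] * tm$nrm * P * ang
  }
  out * sqrt(4 * pi)
}

# Radial function of the oblate ellipsoid with in-plane semi-axis 1 and axial
# semi-axis q (z along theta = 0), modulated by the perturbation field.
shape3d_radius <- function(pat, amplitude, q, theta, phi) {
  base <- 1 / sqrt(sin(theta)^2 + cos(theta)^2 / q^2)
  pert <- if (amplitude > 0) 1 + amplitude * sh_eval(pat, theta, phi) else 1
  base * pert
}

# cached Gauss-Legendre nodes (quadrature grids are reused constantly)
gl_cache <- new.env(parent = emptyenv())
gauss_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]]))
    gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  gl_cache[[key]]
}

# Closure evaluating analytic volume/surface/sphericity of
# r = R * base_oblate(q, theta) * (1 + a f(theta, phi)) for varying q and R.
# The perturbation field and its angular derivatives do not depend on q, so
# they are evaluated once on the quadrature grid; each subsequent call is a
# handful of vectorized array operations. Quadrature: Gauss-Legendre in
# cos(theta), trapezoid in phi (spectrally accurate for band-limited f).
shape3d_evaluator <- function(pat, amplitude, nth = 64L, nph = 128L) {
  gl <- gauss_nodes(nth)
  th <- acos(gl$x)
  ph <- seq(0, 2 * pi, length.out = nph + 1L)[seq_len(nph)]
  dph <- 2 * pi / nph
  TH <- rep(th, times = nph)
  PH <- rep(ph, each = nth)
  wt <- rep(gl$w, times = nph)
  sinth <- sin(TH)
  costh <- cos(TH)
  if (amplitude > 0) {
    h <- 1e-5
    FF <- sh_eval(pat, TH, PH)
    Fth <- (sh_eval(pat, TH + h, PH) - sh_eval(pat, TH - h, PH)) / (2 * h)
    Fph <- (sh_eval(pat, TH, PH + h) - sh_eval(pat, TH, PH - h)) / (2 * h)
  } else {
    FF <- Fth <- Fph <- numeric(length(TH))
  }
  function(q, R = 1) {
    base <- 1 / sqrt(sinth^2 + costh^2 / q^2)
    dbase <- -sinth * costh * (1 - 1 / q^2) * base^3
    pert <- 1 + amplitude * FF
    r <- R * base * pert
    if (any(r <= 0))
      return(list(volume = NA_real_, surface = NA_real_,
                  sphericity = NA_real_))
    rth <- R * (dbase * pert + base * amplitude * Fth)
    rph <- R * base * amplitude * Fph
    vol <- sum((r^3 / 3) * wt) * dph
    dS_over_sin <- r * sqrt(r^2 + rth^2 + (rph / sinth)^2)
    surf <- sum(dS_over_sin * wt) * dph
    list(volume = vol, surface = surf,
         sphericity = min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / surf))
  }
}

# direct evaluation (one-off use and tests)
shape3d_metrics <- function(pat, amplitude, q, R = 1, nth = 64L, nph = 128L) {
  shape3d_evaluator(pat, amplitude, nth, nph)(q, R)
}

# Closed-form sphericity of an oblate spheroid with axis ratio q = c/a < 1.
oblate_sphericity <- function(q) {
  if (q >= 1) return(1)
  e <- sqrt(1 - q^2)
  sa <- 2 * pi * (1 + q^2 / e * atanh(e))
  vol <- 4 / 3 * pi * q
  pi^(1 / 3) * (6 * vol)^(2 / 3) / sa
}

# Axial flattening q whose analytic sphericity (at the given perturbation
# amplitude) hits `target`. Sphericity is monotone in q on (qmin, 1).
calibrate_flattening_3d <- function(pat, amplitude, target, qmin = 0.12,
                                    evaluator = NULL) {
  stopifnot(target > 0, target <= 1)
  ev <- if (is.null(evaluator)) shape3d_evaluator(pat, amplitude) else evaluator
  f <- function(q) ev(q)$sphericity - target
  top <- f(0.999)
  if (top <= 0) return(0.999)   # perturbation alone already at/below target
  if (f(qmin) >= 0) return(qmin)
  uniroot(f, c(qmin, 0.999), tol = 1e-4)$root
}
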