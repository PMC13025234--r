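# 2D segmentation and morphometry against closed forms and generator truth.

test_that("blank and constant images segment to zero objects", {
  geom <- image_geometry(c(64, 64))
  blank <- matrix(0, 64, 64)
  expect_equal(max(segment_2d(blank, geom)$label_mask), 0)
  const <- matrix(0.4, 64, 64)
  expect_equal(max(segment_2d(const, geom,
                              segmentation_params(smoothing_sigma = 0))$label_mask), 0)
  expect_error(segment_2d(matrix(0, 32, 32), geom), "geometry error")
})

test_that("disc and square morphometry match closed forms", {
  d <- raster_disc(50)
  m <- measure_2d(segment_2d(d$mask, d$geometry,
                             segmentation_params(smoothing_sigma = 0)))
  expect_equal(nrow(m), 1)
  expect_equal(m$area_um2, pi * 5^2, tolerance = 0.01)   # r = 5 um
  expect_equal(m$circularity, 1, tolerance = 0.02)
  expect_equal(m$centroid_x_um, 5.65, tolerance = 0.02)  # centre of 113 px grid

  s <- raster_square(100)
  ms <- measure_2d(segment_2d(s$mask, s$geometry,
                              segmentation_params(smoothing_sigma = 0)))
  expect_equal(ms$area_um2, 100, tolerance = 1e-6)       # 10 x 10 um exactly
  expect_equal(ms$circularity, pi / 4, tolerance = 0.03)
})

test_that("circularity is scale invariant; area scales with pixel size", {
  d1 <- raster_disc(50, spacing = 0.1)
  d2 <- raster_disc(50, spacing = 0.2)
  m1 <- measure_2d(segment_2d(d1$mask, d1$geometry,
                              segmentation_params(smoothing_sigma = 0)))
  m2 <- measure_2d(segment_2d(d2$mask, d2$geometry,
                              segmentation_params(smoothing_sigma = 0)))
  expect_equal(m2$area_um2 / m1$area_um2, 4, tolerance = 1e-6)
  expect_lt(abs(m1$circularity - m2$circularity), 0.01)
})

test_that("segmentation recovers generated nuclei with Jaccard > 0.9", {
  geom <- image_geometry(c(1024, 1024))
  spec <- nuclear_phenotype_spec(12, mean_size = 80, target_shape = 0.85)
  img <- generate_image(spec, geometry = geom, seed = 21)
  obj <- segment_2d(img$channels$nucleus, geom,
                    segmentation_params(min_size = 10))
  expect_equal(max(obj$label_mask), 12)
  truth <- img$truth_masks$nucleus
  for (tl in 1:12) {
    sel <- truth == tl
    seg_lab <- as.integer(names(which.max(table(obj$label_mask[sel]))))
    expect_gt(seg_lab, 0)
    inter <- sum(sel & obj$label_mask == seg_lab)
    uni <- sum(sel | obj$label_mask == seg_lab)
    expect_gt(inter / uni, 0.9)
  }
})

test_that("border exclusion removes exactly the edge-touching object", {
  geom <- image_geometry(c(200, 200))
  mask <- matrix(0, 200, 200)
  mk_disc <- function(cx, cy, r) outer(1:200, 1:200, function(i, j)
    (i - cx)^2 + (j - cy)^2 <= r^2)
  mask[mk_disc(60, 60, 25)] <- 1
  mask[mk_disc(140, 140, 25)] <- 1
  mask[mk_disc(190, 60, 25)] <- 1  # touches the x border
  p0 <- segmentation_params(smoothing_sigma = 0, exclude_border = FALSE)
  p1 <- segmentation_params(smoothing_sigma = 0, exclude_border = TRUE)
  expect_equal(max(segment_2d(mask, geom, p0)$label_mask), 3)
  expect_equal(max(segment_2d(mask, geom, p1)$label_mask), 2)
})

test_that("hole filling and min-size filtering behave as configured", {
  geom <- image_geometry(c(128, 128))
  mask <- matrix(0, 128, 128)
  mask[30:90, 30:90] <- 1
  mask[55:65, 55:65] <- 0           # hole
  mask[5:6, 5:6] <- 1               # 4-px speck = 0.04 um^2
  pf <- segmentation_params(smoothing_sigma = 0, fill_holes = TRUE,
                            min_size = 1)
  m <- measure_2d(segment_2d(mask, geom, pf))
  expect_equal(nrow(m), 1)
  expect_equal(m$area_um2, 61^2 * 0.01, tolerance = 1e-6)  # hole filled
  pn <- segmentation_params(smoothing_sigma = 0, fill_holes = FALSE,
                            min_size = 0)
  mn <- measure_2d(segment_2d(mask, geom, pn))
  expect_equal(nrow(mn), 2)
  expect_lt(max(mn$area_um2), 61^2 * 0.01)  # hole kept open
})

test_that("measured circularity tracks generator truth on perturbed nuclei", {
  spec <- nuclear_phenotype_spec(1, mean_size = 100, target_shape = 0.84)
  co <- simulate_cohort_2d(30, spec, noise = noiseless(), seed = 9)
  expect_gte(nrow(co), 28)
  expect_lt(abs(mean(co$circularity) - mean(co$truth_circularity)), 0.02)
})

test_that("stronger boundary perturbation lowers measured circularity", {
  circ_at <- function(a) {
    spec <- nuclear_phenotype_spec(1, mean_size = 100, size_cv = 0.1,
                                   irregularity_amplitude = a)
    mean(simulate_cohort_2d(20, spec, noise = noiseless(), seed = 31)$circularity)
  }
  m <- vapply(c(0, 0.08, 0.16), circ_at, 0)
  expect_true(all(diff(m) < 0))
})

test_that("compartment assignment follows majority overlap with tie-breaking", {
  geom <- image_geometry(c(64, 64))
  parents <- array(0L, c(64, 64))
  parents[5:30, 5:60] <- 1L
  parents[31:60, 5:60] <- 2L
  children <- array(0L, c(64, 64))
  children[10:14, 10:14] <- 1L     # fully inside parent 1
  children[62:63, 62:63] <- 2L     # background -> orphan
  children[29:32, 20:23] <- 3L     # exact 50/50 split -> lower parent label
  po <- as_labeled(parents, geom); po$label_mask <- parents
  co <- as_labeled(children, geom); co$label_mask <- children
  res <- assign_compartments(po, co)
  expect_equal(res$assignment$parent_label[res$assignment$child_label == 1], 1)
  expect_equal(res$orphans, 2L)
  expect_equal(res$assignment$parent_label[res$assignment$child_label == 3], 1)
  expect_error(assign_compartments(po, as_labeled(children,
    image_geometry(c(64, 64), c(0.2, 0.2)))), "geometry error")
})

test_that("generated compartments are never orphans", {
  geom <- image_geometry(c(384, 384))
  img <- generate_image(nuclear_phenotype_spec(2, mean_size = 60,
                                               target_shape = 0.85),
                        list(compartment_spec("nucleolin", 3, 1.7)),
                        noise = noiseless(), geometry = geom, seed = 12)
  nuc <- segment_2d(img$channels$nucleus, geom,
                    segmentation_params(smoothing_sigma = 0, min_size = 5))
  nol <- segment_2d(img$channels$nucleolin, geom,
                    segmentation_params(smoothing_sigma = 0, min_size = 0.05))
  res <- assign_compartments(nuc, nol)
  expect_length(res$orphans, 0)
  expect_equal(nrow(res$assignment), max(nol$label_mask))
})
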