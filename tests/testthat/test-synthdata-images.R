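# Image generator: determinism, noiseless identity, containment,
# distribution recovery, crowding errors.

demo_comps <- function() list(
  compartment_spec("nucleolin", 3, 1.7, 0.4),
  compartment_spec("fibrillarin", 2, 0.3, 0.35, nesting = "nucleolin"),
  compartment_spec("sc35", 6, 0.8, 0.4))

test_that("identical (spec, seed) gives bit-identical images and truth", {
  geom <- image_geometry(c(256, 256))
  spec <- nuclear_phenotype_spec(2, mean_size = 60, target_shape = 0.85)
  a <- generate_image(spec, demo_comps(), geometry = geom, seed = 42)
  b <- generate_image(spec, demo_comps(), geometry = geom, seed = 42)
  expect_identical(a$channels, b$channels)
  expect_identical(a$truth_masks, b$truth_masks)
  expect_identical(a$truth_metrics, b$truth_metrics)
  d <- generate_image(spec, demo_comps(), geometry = geom, seed = 43)
  expect_false(identical(a$channels, d$channels))
})

test_that("noiseless unperturbed nuclei render exactly as their masks", {
  geom <- image_geometry(c(128, 128))
  spec <- nuclear_phenotype_spec(1, mean_size = 40, size_cv = 0,
                                 irregularity_amplitude = 0)
  img <- generate_image(spec, noise = noiseless(), geometry = geom, seed = 7)
  expect_identical(img$channels$nucleus > 0, img$truth_masks$nucleus > 0)
  expect_equal(img$truth_metrics$circularity, 1, tolerance = 1e-6)
})

test_that("sampled truth areas recover the specified mean size", {
  # 200 nuclei, lognormal around 160 um^2 with CV 0.2: Monte-Carlo mean
  # within 3 standard errors
  spec <- nuclear_phenotype_spec(20, mean_size = 160, size_cv = 0.2)
  geom <- image_geometry(c(1800, 1800))
  areas <- unlist(lapply(1:10, function(i) {
    generate_image(spec, noise = noiseless(), geometry = geom,
                   seed = 100 + i)$truth_metrics$area_um2
  }))
  expect_gte(length(areas), 200)
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - 160), 3 * se)
})

test_that("sampled 3D truth volumes recover the specified mean size", {
  spec <- nuclear_phenotype_spec(1, mean_size = 50, size_cv = 0.2,
                                 irregularity_amplitude = 0.06)
  geom <- image_geometry(c(64, 64, 32), c(0.15, 0.15, 0.3))
  vols <- vapply(1:200, function(i) {
    generate_image(spec, noise = noiseless(), geometry = geom,
                   seed = 500 + i)$truth_metrics$volume_um3
  }, 0)
  se <- sd(vols) / sqrt(length(vols))
  expect_lt(abs(mean(vols) - 50), 3 * se)
})

test_that("every compartment lies inside its parent mask", {
  geom <- image_geometry(c(384, 384))
  spec <- nuclear_phenotype_spec(2, mean_size = 60, target_shape = 0.85)
  for (seed in 1:4) {
    img <- generate_image(spec, demo_comps(), geometry = geom, seed = seed)
    m <- img$truth_masks
    expect_true(all(m$nucleus[m$nucleolin > 0] > 0))
    expect_true(all(m$nucleolin[m$fibrillarin > 0] > 0))
    expect_true(all(m$nucleus[m$sc35 > 0] > 0))
    # every truth row references an existing label in its mask
    for (ch in unique(img$truth_metrics$channel)) {
      labs <- img$truth_metrics$label[img$truth_metrics$channel == ch]
      expect_true(all(labs %in% m[[ch]]))
    }
  }
  g3 <- image_geometry(c(160, 160, 44), c(0.15, 0.15, 0.3))
  i3 <- generate_image(nuclear_phenotype_spec(1, mean_size = 300,
                                              target_shape = 0.75),
                       demo_comps(), geometry = g3, seed = 2)
  m3 <- i3$truth_masks
  expect_true(all(m3$nucleus[m3$nucleolin > 0] > 0))
  expect_true(all(m3$nucleolin[m3$fibrillarin > 0] > 0))
  expect_true(all(m3$nucleus[m3$sc35 > 0] > 0))
})

test_that("overfull fields raise an explicit crowding error", {
  geom <- image_geometry(c(64, 64))
  expect_error(
    generate_image(nuclear_phenotype_spec(8, mean_size = 40), geometry = geom,
                   seed = 1),
    "field too crowded")
  expect_error(
    generate_image(nuclear_phenotype_spec(1, mean_size = 4000),
                   geometry = geom, seed = 1),
    "field too crowded")
})

test_that("invalid geometry and spec parameters are rejected", {
  expect_error(image_geometry(c(8, 8)), "geometry error")
  expect_error(image_geometry(c(64, 64), c(0.1, -0.1)), "geometry error")
  expect_error(nuclear_phenotype_spec(1, mean_size = -5))
  expect_error(nuclear_phenotype_spec(1, 50, irregularity_amplitude = 0.7))
  expect_error(compartment_spec("nucleolin", -1, 1))
})

test_that("TIFF round trip preserves channels and spacing", {
  geom <- image_geometry(c(96, 96, 20), c(0.1, 0.1, 0.25))
  img <- generate_image(nuclear_phenotype_spec(1, mean_size = 30,
                                               size_cv = 0),
                        geometry = geom, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "img")
  write_synthetic_image(img, prefix)
  back <- read_image(prefix)
  expect_identical(back$channels$nucleus, img$channels$nucleus)
  expect_equal(back$geometry$spacing, geom$spacing)
  expect_identical(names(back$channels), names(img$channels))
})
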