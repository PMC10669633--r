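test_that("a noise-free scan has the closed-form band geometry and intensities", {
  spec <- synthetic_spec(size = 496, vessel_count = 0)
  sc <- generate_bscan(spec)
  rows <- floor(0.75 * 496 + 0.5) - floor(0.55 * 496 + 0.5)
  expect_identical(sc$true_CA, as.integer(496 * rows))
  expect_identical(sc$true_CA, as.integer(sum(sc$choroid_mask)))
  expect_true(all(sc$image[sc$choroid_mask] == 60L))
  expect_equal(sc$true_COID, 60)
})

test_that("generation is bitwise reproducible from the seed", {
  spec <- synthetic_spec(size = 96, speckle_looks = 4, artifact_amplitude = 10,
                         tilt_px = 5, seed = 123)
  a <- generate_bscan(spec)
  b <- generate_bscan(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$choroid_mask, b$choroid_mask)
})

test_that("multiplicative speckle has unit mean over the choroid band", {
  spec <- synthetic_spec(size = 256, vessel_count = 0, speckle_looks = 4,
                         seed = 5)
  sc <- generate_bscan(spec)
  n <- sum(sc$choroid_mask)
  expect_gt(n, 10000)
  se <- (60 / sqrt(4)) / sqrt(n)  # sd of the masked mean
  expect_lt(abs(mean(sc$image[sc$choroid_mask]) - 60), 3 * se + 0.5)
})

test_that("ground-truth mask and metrics agree with compute_metrics", {
  spec <- synthetic_spec(size = 128, vessel_count = 6,
                         vessel_radius_range = c(2, 5), seed = 9)
  sc <- generate_bscan(spec)
  m <- compute_metrics(sc$image, sc$choroid_mask)
  expect_identical(m$CA, sc$true_CA)
  expect_equal(m$COID, sc$true_COID, tolerance = 1e-12)
  expect_equal(m$CD, sc$true_CA / sc$true_COID, tolerance = 1e-12)
})

test_that("tilt shears the band without changing its area", {
  s0 <- synthetic_spec(size = 128, vessel_count = 0, seed = 2)
  st <- synthetic_spec(size = 128, vessel_count = 0, tilt_px = 6, seed = 2)
  a <- generate_bscan(s0); b <- generate_bscan(st)
  expect_identical(a$true_CA, b$true_CA)
  # last column shifted down by tilt_px relative to the first
  expect_equal(which(b$choroid_mask[, 128])[1] - which(b$choroid_mask[, 1])[1],
               6)
  expect_error(generate_bscan(synthetic_spec(size = 128, tilt_px = 100)),
               "out of frame")
})

test_that("cohort deltas order the group means control > MS > PD on true CA", {
  co <- simulate_cohort(5, base_spec = synthetic_spec(size = 128,
                                                      vessel_count = 0),
                        seed = 1)
  m <- tapply(co$table$true_CA, co$table$group, mean)
  expect_true(m["control"] > m["MS"] && m["MS"] > m["PD"])
  mc <- tapply(co$table$true_COID, co$table$group, mean)
  expect_true(mc["control"] < mc["MS"] && mc["MS"] < mc["PD"])
  expect_equal(nrow(co$table), 15L)
  expect_identical(co$table$true_CA,
                   vapply(co$scans, function(s) s$true_CA, integer(1),
                          USE.NAMES = FALSE))
})

test_that("identical group specs differ only by jitter (null cohort)", {
  nulldeltas <- list(control = list(), MS = list(), PD = list())
  co <- simulate_cohort(6, nulldeltas,
                        synthetic_spec(size = 128, vessel_count = 0),
                        seed = 4)
  spread <- diff(range(tapply(co$table$true_CA, co$table$group, mean)))
  within_sd <- mean(tapply(co$table$true_CA, co$table$group, sd))
  expect_lt(spread, 3 * within_sd)  # no systematic group effect
  # reproducibility of the whole cohort
  co2 <- simulate_cohort(6, nulldeltas,
                         synthetic_spec(size = 128, vessel_count = 0),
                         seed = 4)
  expect_identical(co$table, co2$table)
})

test_that("spec validation rejects degenerate layer definitions", {
  expect_error(synthetic_spec(size = 32), ">= 64")
  expect_error(synthetic_spec(layer_fractions = c(0.5, 0.4, 0.6, 0.8)),
               "increasing")
  expect_error(synthetic_spec(speckle_looks = 0.5), "speckle_looks")
  expect_error(simulate_cohort(1), ">= 2")
})
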