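test_that("constant image with K = 4 splits into near-equal spatial quarters", {
  sp <- slic_segment(matrix(100L, 100, 100), superpixel_params(4, 10, 10))
  expect_equal(sp$K, 4L)
  sizes <- tabulate(sp$labels, 4)
  expect_true(all(abs(sizes - 2500) <= 0.05 * 2500))
})

test_that("K = 1 yields a single label covering the image", {
  img <- rand_gray(40, 40, seed = 71)
  sp <- slic_segment(img, superpixel_params(1, 5, 10))
  expect_equal(sp$K, 1L)
  expect_true(all(sp$labels == 1L))
})

test_that("superpixels do not straddle a strong horizontal intensity edge", {
  img <- rbind(matrix(30L, 32, 64), matrix(220L, 32, 64))
  sp <- slic_segment(img, superpixel_params(8, 10, 10))
  band <- (row(img) > 32) + 1L
  spans <- table(sp$labels, band) > 0
  expect_true(all(rowSums(spans) == 1))  # 100% band purity
})

test_that("labels always partition the image and runs are deterministic", {
  for (s in 1:5) {
    img <- rand_gray(48, 48, seed = 500 + s)
    sp <- slic_segment(img, superpixel_params(20, 5, 10))
    expect_true(all(sp$labels >= 1L & sp$labels <= sp$K))
    expect_equal(sum(tabulate(sp$labels, sp$K)), length(img))
    expect_lte(sp$K, 20L)
    sp2 <- slic_segment(img, superpixel_params(20, 5, 10))
    expect_identical(sp$labels, sp2$labels)
  }
  expect_error(slic_segment(rand_gray(4, 4, 1), superpixel_params(100)),
               "pixel count")
})

test_that("windowed assignment agrees with the unwindowed brute-force oracle", {
  # K <= 2 with aspect ratio in [9/8, 2]: the 2S x 2S search windows tile
  # the whole frame, so the windowed and global assignments must coincide
  cases <- list(c(16, 16, 1), c(24, 16, 2), c(32, 20, 2), c(28, 16, 2))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    img <- rand_gray(cs[1], cs[2], seed = 600 + i, sd = 30)
    got <- slic_segment(img, superpixel_params(cs[3], 100, 10))$labels
    want <- slic_bruteforce(img, cs[3], 10)
    expect_identical(got, want)
  }
  # K up to 4 with strong compactness: assignments stay local, so the
  # window restriction is inactive
  cases4 <- list(c(24, 24, 4), c(32, 32, 4), c(20, 28, 3))
  for (i in seq_along(cases4)) {
    cs <- cases4[[i]]
    img <- rand_gray(cs[1], cs[2], seed = 620 + i, sd = 10)
    got <- slic_segment(img, superpixel_params(cs[3], 100, 40))$labels
    want <- slic_bruteforce(img, cs[3], 40)
    expect_identical(got, want)
  }
})

test_that("mean boundary length does not increase with compactness", {
  img <- rand_gray(64, 64, seed = 42)
  blen <- sapply(c(1, 10, 40), function(m) {
    sp <- slic_segment(img, superpixel_params(16, 10, m))
    sum(choroidsps:::label_boundaries(sp$labels)) / sp$K
  })
  expect_true(all(diff(blen) <= 0))
})

test_that("enforce_connectivity leaves a connected map unchanged up to renumbering", {
  img <- matrix(100L, 60, 60)
  sp <- slic_segment(img, superpixel_params(4, 10, 10))
  sp2 <- enforce_connectivity(sp)
  expect_equal(sp2$K, sp$K)
  # same partition: labels are a bijection of the originals
  expect_equal(length(unique(paste(sp$labels, sp2$labels))), sp$K)
})

test_that("an orphan pixel is absorbed into its surrounding label", {
  labels <- matrix(1L, 20, 20)
  labels[, 11:20] <- 2L
  labels[10, 15] <- 1L  # orphan of label 1 inside label 2
  sp <- structure(list(labels = labels, K = 2L, S = sqrt(200),
                       centroids = data.frame(label = 1:2, row = c(10, 10),
                                              col = c(5, 15),
                                              mean_intensity = c(0, 0),
                                              size = c(201L, 199L))),
                  class = "superpixel_map")
  out <- enforce_connectivity(sp)
  expect_equal(out$K, 2L)
  expect_true(all(out$labels[, 11:20] == out$labels[10, 15]))
})

test_that("every label is 4-connected after enforcement on noisy fixtures", {
  for (s in 1:3) {
    img <- rand_gray(64, 64, seed = 700 + s, sd = 60)
    sp <- enforce_connectivity(slic_segment(img, superpixel_params(25, 5, 5)),
                               img = img)
    comp <- choroidsps:::cpp_components(sp$labels)
    for (k in seq_len(sp$K))
      expect_length(unique(comp[sp$labels == k]), 1L)
    expect_equal(sum(tabulate(sp$labels, sp$K)), length(img))
  }
})

test_that("overlay draws exactly the boundary pixels plus the frame", {
  img <- rand_gray(40, 40, seed = 81)
  sp <- slic_segment(img, superpixel_params(6, 5, 10))
  ov <- overlay_labels(img, sp, numbers = FALSE)
  drawn <- ov[, , 1] == 255L & ov[, , 2] == 255L & ov[, , 3] == 0L
  want <- choroidsps:::label_boundaries(sp$labels)
  want[c(1, nrow(want)), ] <- TRUE
  want[, c(1, ncol(want))] <- TRUE
  # a drawn pixel may be overwritten only where img was already (255,255,0)-like
  expect_identical(drawn, want)

  sp1 <- slic_segment(img, superpixel_params(1, 2, 10))
  ov1 <- overlay_labels(img, sp1, numbers = FALSE)
  drawn1 <- ov1[, , 1] == 255L & ov1[, , 2] == 255L & ov1[, , 3] == 0L
  inner <- drawn1[2:39, 2:39]
  expect_false(any(inner))  # only the frame

  expect_identical(overlay_labels(img, sp), overlay_labels(img, sp))
  expect_error(overlay_labels(rand_gray(10, 10, 1), sp), "shapes")
})
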