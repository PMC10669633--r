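make_sp <- function(img, K = 8, iters = 5, m = 10) {
  enforce_connectivity(slic_segment(img, superpixel_params(K, iters, m)),
                       img = img)
}

test_that("selecting superpixels unions their pixels without double counting", {
  img <- rand_gray(40, 40, seed = 91)
  sp <- make_sp(img)
  all_mask <- select_superpixels(sp, seq_len(sp$K))
  expect_true(all(all_mask))

  expect_gte(sp$K, 2L)
  one <- select_superpixels(sp, 2L)
  expect_equal(sum(one), sum(sp$labels == 2L))

  dup <- select_superpixels(sp, c(1L, 2L, 1L))
  expect_identical(dup, select_superpixels(sp, c(1L, 2L)))
  expect_equal(sum(dup), sum(sp$labels %in% c(1L, 2L)))

  expect_error(select_superpixels(sp, integer(0)), "no superpixels")
  expect_error(select_superpixels(sp, sp$K + 1L), paste0("1..", sp$K))
})

test_that("band criteria select exactly the matching layer", {
  img <- rbind(matrix(30L, 20, 60), matrix(200L, 20, 60), matrix(60L, 20, 60))
  sp <- make_sp(img, K = 12)
  ids <- auto_select_band(sp, img, band_criteria(c(50, 70), c(1, nrow(img))))
  expect_true(length(ids) > 0)
  mask <- select_superpixels(sp, ids)
  expect_true(all(img[mask] == 60L))
  expect_equal(sum(mask), sum(img == 60L))

  all_ids <- auto_select_band(sp, img,
                              band_criteria(c(0, 255), c(1, nrow(img))))
  expect_identical(all_ids, seq_len(sp$K))

  expect_warning(
    none <- auto_select_band(sp, img, band_criteria(c(80, 80), c(1, 60))),
    "no superpixel")
  expect_length(none, 0)
})

test_that("depth criteria follow a per-column anchor profile", {
  img <- rbind(matrix(30L, 20, 60), matrix(200L, 5, 60), matrix(60L, 35, 60))
  sp <- make_sp(img, K = 12)
  anchor <- detect_bright_band(img)
  expect_true(all(anchor >= 21 & anchor <= 25))  # inside the bright band
  ids <- auto_select_band(sp, img,
                          band_criteria(c(0, 255), c(5, 40), anchor = "brightest"))
  mask <- select_superpixels(sp, ids)
  expect_true(all(img[mask] == 60L))  # only the band below the anchor
})

test_that("region properties match closed forms", {
  mask <- matrix(FALSE, 30, 30)
  mask[6:15, 4:23] <- TRUE  # 10 x 20 rectangle
  rp <- region_properties(mask)
  expect_equal(rp$area, 200L)
  expect_equal(unname(rp$centroid), c(10.5, 13.5))
  expect_equal(unname(rp$bounding_box), c(6, 4, 10, 20))
  expect_equal(rp$n_components, 1L)

  two <- matrix(FALSE, 10, 10)
  two[2, 2] <- TRUE; two[8, 9] <- TRUE
  expect_equal(region_properties(two)$n_components, 2L)

  rnd <- rand_mask(25, 25, seed = 11)
  expect_equal(region_properties(rnd)$area, sum(rnd))  # popcount oracle

  expect_error(region_properties(matrix(FALSE, 3, 3)), "empty")
})

test_that("boundary extraction matches closed forms and the neighbor-scan oracle", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  b <- extract_boundary(single)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]), 1L)
  expect_equal(c(b[[1]]$row, b[[1]]$col), c(3, 3))

  for (wh in list(c(2, 2), c(4, 7), c(6, 3))) {
    rect <- matrix(FALSE, 12, 12)
    rect[3:(2 + wh[1]), 4:(3 + wh[2])] <- TRUE
    ct <- extract_boundary(rect)[[1]]
    expect_equal(nrow(ct), 2 * wh[1] + 2 * wh[2] - 4)
    expect_true(all(rect[cbind(ct$row, ct$col)]))  # contour within mask
  }

  for (s in 1:5) {
    blob <- blob_mask(20, 20, seed = 800 + s)
    ct <- extract_boundary(blob)
    pts <- do.call(rbind, ct)
    got <- matrix(FALSE, 20, 20)
    got[cbind(pts$row, pts$col)] <- TRUE
    expect_identical(got, boundary4_oracle(blob))
  }
})

test_that("filling the outer contour reproduces the component without holes", {
  for (s in 1:3) {
    blob <- blob_mask(18, 18, seed = 900 + s)
    ct <- extract_boundary(blob)[[1]]
    contour <- matrix(FALSE, 18, 18)
    contour[cbind(ct$row, ct$col)] <- TRUE
    expect_identical(fill_holes(contour), fill_holes(blob))
  }
})
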