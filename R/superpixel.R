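# Grayscale SLIC superpixel clustering. Fully deterministic: grid seeding,
# fixed scan order, ties broken by lowest center index, no randomness.

#' Superpixel clustering parameters
#'
#' @param n_superpixels requested number of superpixels K (default 400,
#'   which gives superpixels roughly 50 px across on a 992 x 992 scan).
#' @param iterations assignment/update rounds (default 10).
#' @param compactness shape-regularity weight m trading intensity
#'   similarity against spatial regularity (default 10).
#' @return a `superpixel_params` list.
#' @export
superpixel_params <- function(n_superpixels = 400L,
                              iterations = 10L,
                              compactness = 10.0) {
  k <- as.integer(n_superpixels)
  it <- as.integer(iterations)
  if (is.na(k) || k < 1L) stop("n_superpixels must be >= 1", call. = FALSE)
  if (is.na(it) || it < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (!is.numeric(compactness) || compactness <= 0)
    stop("compactness must be > 0", call. = FALSE)
  structure(list(n_superpixels = k, iterations = it,
                 compactness = as.numeric(compactness)),
            class = "superpixel_params")
}

new_superpixel_map <- function(labels, img, S) {
  K <- max(labels)
  f <- factor(labels, levels = seq_len(K))
  rows <- row(labels); cols <- col(labels)
  centroids <- data.frame(
    label = seq_len(K),
    row = as.numeric(tapply(rows, f, mean)),
    col = as.numeric(tapply(cols, f, mean)),
    mean_intensity = as.numeric(tapply(img + 0.0, f, mean)),
    size = as.integer(tabulate(labels, nbins = K))
  )
  structure(list(labels = labels, K = K, centroids = centroids, S = S),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("superpixel map: %d x %d px, K = %d (grid interval S = %.1f)\n",
              nrow(x$labels), ncol(x$labels), x$K, x$S))
  invisible(x)
}

#' Partition a gray image into SLIC superpixels
#'
#' Deterministic grayscale SLIC: K cluster centers are seeded on a regular
#' grid with interval `S = sqrt(N / K)`, each seed is moved to the
#' lowest-gradient position in its 3 x 3 neighborhood, and for
#' `iterations` rounds every pixel within a 2S x 2S window of a center is
#' assigned to the center minimizing
#' `D = sqrt(dI^2 + (dxy / S)^2 * m^2)`
#' (`dI` = intensity difference to the center mean, `dxy` = Euclidean
#' pixel distance, `m` = compactness), after which centers are recomputed
#' as cluster means. Ties in `D` go to the lowest center index. Labels are
#' renumbered 1..K.
#'
#' @param img gray image matrix.
#' @param params a [superpixel_params()] object.
#' @return a `superpixel_map`: list with `labels` (integer matrix), `K`,
#'   `centroids` (data frame: label, row, col, mean_intensity, size) and
#'   the grid interval `S`.
#' @seealso [enforce_connectivity()], [overlay_labels()]
#' @export
slic_segment <- function(img, params = superpixel_params()) {
  stopifnot_gray(img)
  stopifnot(inherits(params, "superpixel_params"))
  if (params$n_superpixels > length(img))
    stop("n_superpixels exceeds the pixel count", call. = FALSE)
  labels <- cpp_slic(img + 0.0, params$n_superpixels,
                     params$iterations, params$compactness)
  new_superpixel_map(labels, img, sqrt(length(img) / params$n_superpixels))
}

#' Enforce 4-connectivity of superpixels
#'
#' Merges every connected component smaller than `S^2 / 4` pixels into its
#' largest 4-adjacent neighbor label and renumbers labels consecutively
#' from 1, so that each final label is one 4-connected region.
#'
#' @param sp a `superpixel_map`.
#' @param img optional gray image used to refresh centroid intensities;
#'   defaults to reconstructing them from the stored centroids' source.
#' @return a `superpixel_map` with 4-connected labels.
#' @export
enforce_connectivity <- function(sp, img = NULL) {
  stopifnot(inherits(sp, "superpixel_map"))
  labels <- cpp_enforce_connectivity(sp$labels, sp$S^2 / 4)
  if (is.null(img)) {
    # centroid intensities refreshed from a label-mean reconstruction
    img <- matrix(sp$centroids$mean_intensity[sp$labels],
                  nrow(sp$labels), ncol(sp$labels))
    img <- quantize8(img)
  }
  new_superpixel_map(labels, img, sp$S)
}

#' Superpixel boundary pixels
#'
#' @param labels integer label matrix.
#' @return logical matrix: `TRUE` where a pixel has a 4-neighbor with a
#'   different label.
#' @keywords internal
label_boundaries <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  b <- matrix(FALSE, h, w)
  b[-h, ] <- b[-h, ] | labels[-h, ] != labels[-1, ]
  b[-1, ] <- b[-1, ] | labels[-1, ] != labels[-h, ]
  b[, -w] <- b[, -w] | labels[, -w] != labels[, -1]
  b[, -1] <- b[, -1] | labels[, -1] != labels[, -w]
  b
}

# 3 x 5 bitmaps for digits 0-9, used to stamp label numbers on overlays
digit_glyphs <- local({
  rows <- c(
    "111101101101111",  # 0
    "010110010010111",  # 1
    "111001111100111",  # 2
    "111001111001111",  # 3
    "101101111001001",  # 4
    "111100111001111",  # 5
    "111100111101111",  # 6
    "111001001001001",  # 7
    "111101111101111",  # 8
    "111101111001111"   # 9
  )
  lapply(rows, function(s)
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5, 3, byrow = TRUE))
})

stamp_number <- function(canvas, n, row, col, value) {
  digits <- strsplit(as.character(n), "")[[1]]
  width <- 4L * length(digits) - 1L
  r0 <- round(row) - 2L
  c0 <- round(col) - width %/% 2L
  for (d in seq_along(digits)) {
    g <- digit_glyphs[[as.integer(digits[d]) + 1L]]
    rr <- r0 + 0:4; cc <- c0 + (d - 1L) * 4L + 0:2
    ok_r <- rr >= 1L & rr <= dim(canvas)[1]
    ok_c <- cc >= 1L & cc <= dim(canvas)[2]
    for (ch in 1:3)
      canvas[rr[ok_r], cc[ok_c], ch][g[ok_r, ok_c]] <- value[ch]
  }
  canvas
}

#' Render a numbered superpixel overlay
#'
#' Draws superpixel boundaries (yellow) and the label number at each
#' centroid (red) on top of the source image; the overlay supports the
#' supervised label selection step and has no effect on any metric.
#'
#' @param img gray image matrix.
#' @param sp a `superpixel_map` with matching shape.
#' @param numbers stamp label numbers at centroids? Default `TRUE`.
#' @return height x width x 3 integer array (RGB, 0..255).
#' @export
overlay_labels <- function(img, sp, numbers = TRUE) {
  stopifnot_gray(img)
  stopifnot(inherits(sp, "superpixel_map"))
  if (!all(dim(img) == dim(sp$labels)))
    stop("image and superpixel map shapes differ", call. = FALSE)
  rgb <- array(as.integer(img), c(dim(img), 3L))
  b <- label_boundaries(sp$labels)
  b[c(1L, nrow(b)), ] <- TRUE  # image frame always drawn
  b[, c(1L, ncol(b))] <- TRUE
  rgb[, , 1][b] <- 255L
  rgb[, , 2][b] <- 255L
  rgb[, , 3][b] <- 0L
  if (numbers)
    for (i in seq_len(sp$K))
      rgb <- stamp_number(rgb, i, sp$centroids$row[i], sp$centroids$col[i],
                          c(255L, 0L, 0L))
  rgb
}
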