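# Image loading, 8-bit grayscale conversion and square cropping.
# The working representation of a B-scan ("gray image") is an integer matrix
# with values in 0..255; rows are depth, columns lateral position.

#' Round half away from zero and clip to the 8-bit range
#'
#' All quantization to 8 bits in the pipeline uses half-away-from-zero
#' rounding (values here are non-negative, so `floor(x + 0.5)`) for
#' cross-platform determinism, unlike base [round()] which rounds half to
#' even.
#'
#' @param x numeric vector/matrix of non-negative values.
#' @return integer values clipped to `[0, 255]`, same shape as `x`.
#' @keywords internal
quantize8 <- function(x) {
  q <- floor(x + 0.5)
  q[q < 0] <- 0
  q[q > 255] <- 255
  storage.mode(q) <- "integer"
  q
}

stopifnot_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix (gray image)", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must contain gray levels in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

#' Load a TIFF or PNG image as an 8-bit raster
#'
#' Reads a B-scan exported as TIFF or PNG. 16-bit samples are rescaled to
#' 8 bits by integer division by 257 (so 65535 maps to 255). An alpha
#' channel, if present, is dropped with a warning.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return for grayscale input an integer matrix (height x width); for RGB
#'   input an integer array (height x width x 3). Values in 0..255.
#' @seealso [to_gray8()], [crop_square()]
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      tif = ,
      tiff = tiff::readTIFF(path, as.is = TRUE),
      png = {
        v <- png::readPNG(path)
        v8 <- v * 255
        if (max(abs(v8 - round(v8))) < 1e-6) round(v8) else round(v * 65535)
      },
      stop("unsupported image format '", ext, "' for: ", path, call. = FALSE)
    ),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  nch <- dim(px)[3]
  if (nch %in% c(2L, 4L)) {
    warning("alpha channel dropped for: ", path)
    px <- px[, , seq_len(nch - 1L), drop = FALSE]
    nch <- dim(px)[3]
  }
  if (max(px) > 255) px <- px %/% 257  # 16-bit -> 8-bit
  storage.mode(px) <- "integer"
  if (dim(px)[3] == 1L) px[, , 1L] else px
}

#' Convert a raster to an 8-bit gray image
#'
#' Single-channel input passes through unchanged. RGB input is mapped with
#' the ITU-R BT.601 luma weights `0.2989 R + 0.5870 G + 0.1140 B`, rounded
#' half away from zero. OCT devices typically export pseudo-grayscale RGB,
#' for which any luma weighting is exact on `r = g = b` pixels.
#'
#' @param img matrix (grayscale) or height x width x 3 array (RGB),
#'   values 0..255.
#' @return integer matrix of gray levels 0..255.
#' @examples
#' rgb <- array(0L, c(2, 2, 3)); rgb[1, 1, ] <- c(255L, 0L, 0L)
#' to_gray8(rgb)[1, 1]  # 76
#' @export
to_gray8 <- function(img) {
  if (is.matrix(img)) {
    stopifnot_gray(img)
    storage.mode(img) <- "integer"
    return(img)
  }
  if (!is.array(img) || length(dim(img)) != 3L || !dim(img)[3] %in% c(1L, 3L))
    stop("unsupported image: expected 1 or 3 channels", call. = FALSE)
  if (dim(img)[3] == 1L) return(to_gray8(img[, , 1L]))
  y <- 0.2989 * img[, , 1L] + 0.5870 * img[, , 2L] + 0.1140 * img[, , 3L]
  quantize8(y)
}

#' Crop a B-scan to a square working frame
#'
#' Removes `width - height` columns so the output is `height x height`:
#' `floor((width - height) / 2)` from the left and the remainder from the
#' right. HD-line scans are fovea-centered, so the symmetric crop keeps the
#' fovea centered. A 1024 x 992 export becomes 992 x 992.
#'
#' @param img gray image matrix with `width >= height`.
#' @return square integer matrix of side `height`.
#' @export
crop_square <- function(img) {
  stopifnot_gray(img)
  h <- nrow(img); w <- ncol(img)
  if (w < h)
    stop("image is taller than wide (", h, " x ", w, "); B-scans are ",
         "expected wider than tall - inspect orientation and transpose ",
         "explicitly if appropriate", call. = FALSE)
  if (w == h) return(img)
  left <- (w - h) %/% 2L
  img[, (left + 1L):(left + h), drop = FALSE]
}

#' Write an 8-bit gray image to PNG or TIFF
#'
#' @param img gray image matrix (0..255).
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_gray <- function(img, path) {
  stopifnot_gray(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(img / 255, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write a superpixel label raster as a 16-bit TIFF
#'
#' @param labels integer matrix of labels (0..65535).
#' @param path output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
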