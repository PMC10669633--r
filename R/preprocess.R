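# Denoising and contrast enhancement applied before superpixelation:
# Gaussian low-pass (speckle) -> spectral median filter (periodic artifacts)
# -> global histogram equalization. The pipeline contract is 8-bit in,
# 8-bit out at every stage, re-quantized half away from zero.

#' Preprocessing parameters
#'
#' @param gaussian_sigma Gaussian low-pass standard deviation in pixels
#'   (`>= 0`; `0` disables smoothing). Default 1.
#' @param spectral_median_window odd window (pixels) of the median filter
#'   applied to the log-magnitude spectrum. Default 3.
#' @param equalize apply global histogram equalization? Default `TRUE`.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(gaussian_sigma = 1.0,
                              spectral_median_window = 3L,
                              equalize = TRUE) {
  if (!is.numeric(gaussian_sigma) || gaussian_sigma < 0)
    stop("gaussian_sigma must be >= 0", call. = FALSE)
  w <- as.integer(spectral_median_window)
  if (w < 3L || w %% 2L == 0L)
    stop("spectral_median_window must be odd and >= 3", call. = FALSE)
  structure(list(gaussian_sigma = gaussian_sigma,
                 spectral_median_window = w,
                 equalize = isTRUE(equalize)),
            class = "preprocess_params")
}

#' Gaussian low-pass filter
#'
#' Spatial convolution with a normalized discrete Gaussian of radius
#' `ceil(3 * sigma)`, reflective boundary handling. `sigma = 0` is the
#' identity. Used to suppress speckle before superpixel clustering.
#'
#' @param img gray image matrix.
#' @param sigma kernel standard deviation in pixels (`>= 0`).
#' @return 8-bit gray image matrix.
#' @export
gaussian_lowpass <- function(img, sigma = 1.0) {
  stopifnot_gray(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single value >= 0", call. = FALSE)
  if (sigma == 0) {
    storage.mode(img) <- "integer"
    return(img)
  }
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  quantize8(cpp_sepconv(img + 0.0, k))
}

fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  x[c((h2 + 1L):h, seq_len(h2)), c((w2 + 1L):w, seq_len(w2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  h2 <- h - h %/% 2L; w2 <- w - w %/% 2L
  x[c((h2 + 1L):h, seq_len(h2)), c((w2 + 1L):w, seq_len(w2)), drop = FALSE]
}

#' Frequency-domain median filter
#'
#' Suppresses periodic (power-line type) artifacts, which appear as
#' isolated peaks in the 2-D spectrum: the image is Fourier transformed,
#' a `window x window` median filter is applied to the centered
#' log-magnitude spectrum, the DC bin is held fixed, and the image is
#' reconstructed from the filtered magnitude and the original phase.
#' Smooth spectral content passes essentially unchanged; isolated peaks
#' are replaced by their local median.
#'
#' @param img gray image matrix.
#' @param window odd median window (`>= 3`, smaller than the image side).
#' @param quantize clip to `[0, 255]` and re-quantize to 8 bits
#'   (default `TRUE`); `FALSE` returns the raw real part, useful for
#'   checking exact DC preservation.
#' @return 8-bit gray image matrix (or a double matrix if
#'   `quantize = FALSE`).
#' @export
spectral_median_filter <- function(img, window = 3L, quantize = TRUE) {
  stopifnot_gray(img)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (window >= min(dim(img)))
    stop("window must be smaller than the image side", call. = FALSE)
  eps <- 1e-12
  fw <- stats::fft(img + 0.0)
  mag <- Mod(fw)
  lmag <- fftshift2(log(mag + eps))
  lmag <- cpp_median_filter(lmag, window)
  mag2 <- exp(ifftshift2(lmag)) - eps
  mag2[mag2 < 0] <- 0
  mag2[1L, 1L] <- mag[1L, 1L]  # DC pinned: mean gray level preserved
  phase <- Arg(fw)
  cm <- matrix(complex(modulus = mag2, argument = phase),
               nrow(img), ncol(img))
  rec <- stats::fft(cm, inverse = TRUE)
  re <- matrix(Re(rec) / length(img), nrow(img), ncol(img))
  if (quantize) quantize8(pmin(pmax(re, 0), 255)) else re
}

#' Global histogram equalization
#'
#' Applies the cumulative-distribution mapping
#' `T(v) = round(255 * (cdf(v) - cdf_min) / (N - cdf_min))`, which is
#' monotone non-decreasing in `v`, flattening the gray-level histogram as
#' far as the discrete levels allow. A constant image is returned
#' unchanged.
#'
#' @param img gray image matrix.
#' @return 8-bit gray image matrix.
#' @export
equalize_histogram <- function(img) {
  stopifnot_gray(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  n <- length(img)
  if (n == cdf_min) {  # constant image
    storage.mode(img) <- "integer"
    return(img)
  }
  lut <- quantize8(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
}

#' Run the full preprocessing chain
#'
#' Gaussian low-pass, then spectral median filter, then (optionally)
#' histogram equalization, in that order. Deterministic: identical input
#' and parameters give a bitwise-identical result.
#'
#' @param img gray image matrix.
#' @param params a [preprocess_params()] object.
#' @return 8-bit gray image matrix.
#' @export
preprocess_bscan <- function(img, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  out <- gaussian_lowpass(img, params$gaussian_sigma)
  out <- spectral_median_filter(out, params$spectral_median_window)
  if (params$equalize) out <- equalize_histogram(out)
  out
}
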