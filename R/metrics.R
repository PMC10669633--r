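# The three per-eye choroid metrics:
#   CA   - choroidal area, the pixel count of the segmented region (px^2)
#   COID - choroidal optical image density, the mean 8-bit gray level of
#          the segmented region (kept at float precision; printed at 2 dp)
#   CD   - choroidal density, the ratio CA / COID (dimensionless)

check_mask <- function(mask, img = NULL) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!is.null(img) && !all(dim(img) == dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  invisible(mask)
}

#' Choroidal area (CA)
#'
#' The total area of the segmented choroidal region of interest: the
#' number of `TRUE` pixels, in px^2.
#'
#' @param mask logical choroid mask.
#' @return integer pixel count.
#' @export
choroid_area <- function(mask) {
  check_mask(mask)
  as.integer(sum(mask))
}

#' Choroidal optical image density (COID)
#'
#' The mean pixel gray level over the segmented region, computed in
#' floating point (no 8-bit re-rounding).
#'
#' @param img gray image matrix.
#' @param mask logical choroid mask of the same shape.
#' @return mean gray level in `[0, 255]`.
#' @export
choroid_optical_image_density <- function(img, mask) {
  stopifnot_gray(img)
  check_mask(mask, img)
  mean(img[mask])
}

#' Choroidal density (CD)
#'
#' The ratio between the choroidal area and the choroidal optical image
#' density, `CD = CA / COID`.
#'
#' @param CA choroidal area in px^2.
#' @param COID choroidal optical image density (mean gray level, `> 0`).
#' @return dimensionless density.
#' @examples
#' choroid_density(154940, 51.22)  # 3024.99 for the healthy worked example
#' @export
choroid_density <- function(CA, COID) {
  if (!is.numeric(CA) || !is.numeric(COID))
    stop("CA and COID must be numeric", call. = FALSE)
  if (COID <= 0)
    stop("undefined density for zero-intensity region", call. = FALSE)
  CA / COID
}

#' Compute the (CA, COID, CD) triple for a segmented eye
#'
#' CD is recomputed from the unrounded CA and COID, so the identity
#' `CD * COID = CA` holds to floating-point precision.
#'
#' @param img gray image matrix.
#' @param mask logical choroid mask of the same shape.
#' @return a `choroid_metrics` list with elements `CA`, `COID`, `CD`.
#' @export
compute_metrics <- function(img, mask) {
  CA <- choroid_area(mask)
  COID <- choroid_optical_image_density(img, mask)
  structure(list(CA = CA, COID = COID, CD = choroid_density(CA, COID)),
            class = "choroid_metrics")
}

#' @export
print.choroid_metrics <- function(x, ...) {
  cat(sprintf("CA = %d px^2, COID = %.2f, CD = %.2f\n", x$CA, x$COID, x$CD))
  invisible(x)
}
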