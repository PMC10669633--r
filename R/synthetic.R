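# Seeded synthetic OCT B-scan generator. Emulates the layered retinal
# cross-section seen in a macular B-scan: dark vitreous, brighter
# neuroretina, bright RPE band, textured darker choroid with hypo-
# reflective vessel lumina, sclera below; multiplicative gamma speckle
# (unit mean, the standard coherent-imaging model); an optional additive
# horizontal-frequency sinusoid emulating power-line artifacts; and an
# optional linear retinal tilt (column-wise vertical shear).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic B-scan
#'
#' Defaults describe a 496 x 496 scan whose choroid band spans depths
#' 0.55 H to 0.75 H with base gray level 60, below a bright RPE band
#' (210) and above the sclera (90).
#'
#' @param size square side in pixels (`>= 64`).
#' @param layer_fractions strictly increasing interface depths in (0, 1):
#'   vitreous/retina, retina/RPE, RPE/choroid, choroid/sclera.
#' @param layer_intensities gray levels of the five bands (vitreous,
#'   retina, RPE, choroid, sclera).
#' @param vessel_count number of dark elliptical vessel lumina placed in
#'   the choroid band.
#' @param vessel_radius_range `(min, max)` vessel semi-axis in pixels.
#' @param vessel_intensity vessel lumen gray level.
#' @param speckle_looks number of looks L of the multiplicative gamma
#'   speckle (`g ~ Gamma(L, rate = L)`, unit mean); `Inf` disables
#'   speckle.
#' @param artifact_amplitude amplitude (gray levels) of the additive
#'   horizontal-frequency sinusoid; 0 disables it.
#' @param artifact_period period of the sinusoid in pixels.
#' @param tilt_px maximum vertical shear (pixels) across the width; the
#'   shear grows linearly from 0 at the left edge.
#' @param seed integer seed controlling vessels and speckle.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(size = 496L,
                           layer_fractions = c(vitreous_retina = 0.30,
                                               retina_rpe = 0.50,
                                               rpe_choroid = 0.55,
                                               choroid_sclera = 0.75),
                           layer_intensities = c(vitreous = 10, retina = 120,
                                                 rpe = 210, choroid = 60,
                                                 sclera = 90),
                           vessel_count = 12L,
                           vessel_radius_range = c(4, 14),
                           vessel_intensity = 30,
                           speckle_looks = Inf,
                           artifact_amplitude = 0,
                           artifact_period = 32,
                           tilt_px = 0,
                           seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("size must be >= 64", call. = FALSE)
  lf <- as.numeric(layer_fractions)
  if (length(lf) != 4L || any(diff(lf) <= 0) || lf[1] <= 0 || lf[4] >= 1)
    stop("layer_fractions must be 4 strictly increasing values in (0, 1)",
         call. = FALSE)
  li <- as.numeric(layer_intensities)
  if (length(li) != 5L || any(li < 0 | li > 255))
    stop("layer_intensities must be 5 gray levels in [0, 255]", call. = FALSE)
  if (speckle_looks < 1) stop("speckle_looks must be >= 1", call. = FALSE)
  if (tilt_px < 0) stop("tilt_px must be >= 0", call. = FALSE)
  structure(list(size = size, layer_fractions = lf,
                 layer_intensities = li,
                 vessel_count = as.integer(vessel_count),
                 vessel_radius_range = as.numeric(vessel_radius_range),
                 vessel_intensity = as.numeric(vessel_intensity),
                 speckle_looks = speckle_looks,
                 artifact_amplitude = as.numeric(artifact_amplitude),
                 artifact_period = as.numeric(artifact_period),
                 tilt_px = as.numeric(tilt_px),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic B-scan with ground truth
#'
#' Builds the noise-free layered image (bands, vessels, tilt), records
#' the exact choroid-band mask (vessels included — the choroidal region
#' of interest comprises stroma and vessel lumina) and its metrics, then
#' applies speckle and the periodic artifact and quantizes to 8 bits.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()] object.
#' @return a `synthetic_scan` list: `image` (8-bit gray matrix),
#'   `choroid_mask` (logical), `true_CA` (px^2), `true_COID` (mean
#'   noise-free gray of the masked band), and `spec`.
#' @export
generate_bscan <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$size; W <- spec$size
  iface <- floor(spec$layer_fractions * H + 0.5)  # interface rows (0-based counts)
  if (iface[4] + ceiling(spec$tilt_px) > H)
    stop("tilt would push the choroid band out of frame", call. = FALSE)
  band_of_row <- findInterval(seq_len(H) - 0.5, iface) + 1L
  clean <- matrix(spec$layer_intensities[band_of_row], H, W)
  mask <- matrix(band_of_row == 4L, H, W)

  with_seed(spec$seed, {
    if (spec$vessel_count > 0L) {
      r_lo <- iface[3] + 1L; r_hi <- iface[4]  # choroid rows (1-based)
      for (i in seq_len(spec$vessel_count)) {
        a <- runif(1, spec$vessel_radius_range[1], spec$vessel_radius_range[2])
        b <- runif(1, spec$vessel_radius_range[1], spec$vessel_radius_range[2])
        cr <- runif(1, r_lo, r_hi)
        cc <- runif(1, 1, W)
        rr <- max(1L, floor(cr - b)):min(H, ceiling(cr + b))
        ccid <- max(1L, floor(cc - a)):min(W, ceiling(cc + a))
        ell <- outer(((rr - cr) / b)^2, ((ccid - cc) / a)^2, `+`) <= 1
        inband <- band_of_row[rr] == 4L
        ell[!inband, ] <- FALSE
        sub <- clean[rr, ccid, drop = FALSE]
        sub[ell] <- spec$vessel_intensity
        clean[rr, ccid] <- sub
      }
    }

    if (spec$tilt_px > 0) {
      shift <- floor(spec$tilt_px * (seq_len(W) - 1L) / (W - 1L) + 0.5)
      for (j in seq_len(W)) {
        s <- shift[j]
        if (s > 0L) {
          clean[, j] <- c(rep(spec$layer_intensities[1], s),
                          clean[seq_len(H - s), j])
          mask[, j] <- c(rep(FALSE, s), mask[seq_len(H - s), j])
        }
      }
    }

    true_CA <- sum(mask)
    true_COID <- mean(clean[mask])

    img <- clean
    if (is.finite(spec$speckle_looks)) {
      L <- spec$speckle_looks
      img <- img * matrix(rgamma(H * W, shape = L, rate = L), H, W)
    }
    if (spec$artifact_amplitude > 0) {
      art <- spec$artifact_amplitude *
        sin(2 * pi * (seq_len(W) - 1L) / spec$artifact_period)
      img <- img + matrix(art, H, W, byrow = TRUE)
    }
    structure(list(image = quantize8(img), choroid_mask = mask,
                   true_CA = as.integer(true_CA), true_COID = true_COID,
                   spec = spec),
              class = "synthetic_scan")
  })
}

#' @export
print.synthetic_scan <- function(x, ...) {
  cat(sprintf("synthetic B-scan %d x %d: true CA = %d px^2, true COID = %.2f\n",
              nrow(x$image), ncol(x$image), x$true_CA, x$true_COID))
  invisible(x)
}

apply_deltas <- function(spec, delta) {
  if (length(delta) == 0) return(spec)
  if (!is.null(delta$choroid_thickness_factor)) {
    f <- spec$layer_fractions
    f[4] <- f[3] + (f[4] - f[3]) * delta$choroid_thickness_factor
    spec$layer_fractions <- f
  }
  if (!is.null(delta$choroid_intensity_shift))
    spec$layer_intensities[4] <-
      min(255, max(0, spec$layer_intensities[4] + delta$choroid_intensity_shift))
  spec
}

#' Default disease-group effects for cohort simulation
#'
#' Encodes the direction of the group differences reported for choroid
#' metrics in neurodegeneration — a thinner choroid band (smaller CA) and
#' a higher mean gray level (higher COID) in disease, stronger in PD than
#' in MS. Magnitudes are configurable and not claimed to be clinically
#' calibrated.
#'
#' @return named list of per-group delta lists (`control`, `MS`, `PD`).
#' @export
cohort_group_deltas <- function() {
  list(control = list(),
       MS = list(choroid_thickness_factor = 0.90, choroid_intensity_shift = 7),
       PD = list(choroid_thickness_factor = 0.80, choroid_intensity_shift = 14))
}

#' Simulate a cohort of synthetic B-scans
#'
#' Applies each group's spec deltas to a base spec, adds per-subject
#' jitter (seeded) to the band depths and intensities, and generates one
#' scan per subject. Fully reproducible from `seed`.
#'
#' @param n_per_group subjects per group (`>= 2`).
#' @param group_deltas named list mapping group label to a delta list
#'   (`choroid_thickness_factor`, `choroid_intensity_shift`); an empty
#'   delta list leaves the base spec unchanged. Default
#'   [cohort_group_deltas()].
#' @param base_spec base [synthetic_spec()]; default has gamma speckle
#'   with L = 8 looks.
#' @param seed master seed.
#' @param depth_jitter_sd SD of the jitter added to each interface depth
#'   fraction (default 0.006).
#' @param intensity_jitter_sd SD of the jitter added to each band gray
#'   level (default 2).
#' @return list with `scans` (list of `synthetic_scan`), and `table`, a
#'   data frame (`eye_id`, `group`, `true_CA`, `true_COID`, `true_CD`).
#' @export
simulate_cohort <- function(n_per_group = 25L,
                            group_deltas = cohort_group_deltas(),
                            base_spec = synthetic_spec(speckle_looks = 8),
                            seed = 1L,
                            depth_jitter_sd = 0.006,
                            intensity_jitter_sd = 2) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  if (is.null(names(group_deltas)) || any(names(group_deltas) == ""))
    stop("group_deltas must be a named list", call. = FALSE)
  scans <- list()
  rows <- list()
  with_seed(seed, {
    for (g in names(group_deltas)) {
      gspec <- apply_deltas(base_spec, group_deltas[[g]])
      for (i in seq_len(n_per_group)) {
        s <- gspec
        repeat {
          f <- s$layer_fractions + rnorm(4, 0, depth_jitter_sd)
          if (all(diff(f) > 0) && f[1] > 0 && f[4] < 1) break
        }
        s$layer_fractions <- f
        s$layer_intensities <- pmin(255, pmax(
          0, s$layer_intensities + rnorm(5, 0, intensity_jitter_sd)))
        s$seed <- sample.int(.Machine$integer.max - 1L, 1L)
        scan <- generate_bscan(s)
        id <- sprintf("%s_%02d", g, i)
        scans[[id]] <- scan
        rows[[id]] <- data.frame(eye_id = id, group = g,
                                 true_CA = scan$true_CA,
                                 true_COID = scan$true_COID,
                                 true_CD = scan$true_CA / scan$true_COID)
      }
    }
  })
  list(scans = scans, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}
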