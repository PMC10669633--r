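# Grouping selected superpixels into a single choroidal region of
# interest, region properties and boundary extraction. Connectivity is
# 4-connectivity everywhere (components, boundaries, orphan merging).

#' Build a choroid mask from selected superpixel labels
#'
#' The mask is the union of the pixels of the chosen labels — the
#' supervised step in which an expert groups the numbered superpixels
#' covering the choroid into one segmented region. Duplicate ids are
#' ignored (set semantics).
#'
#' @param sp a `superpixel_map`.
#' @param chosen integer vector of label ids in `1..K`.
#' @return logical matrix (`TRUE` inside the choroidal region).
#' @seealso [auto_select_band()] for a criteria-driven selection.
#' @export
select_superpixels <- function(sp, chosen) {
  stopifnot(inherits(sp, "superpixel_map"))
  if (length(chosen) == 0)
    stop("no superpixels selected", call. = FALSE)
  chosen <- unique(as.integer(chosen))
  bad <- chosen[is.na(chosen) | chosen < 1L | chosen > sp$K]
  if (length(bad) > 0)
    stop("unknown superpixel id(s) ", paste(bad, collapse = ", "),
         "; valid labels are 1..", sp$K, call. = FALSE)
  matrix(sp$labels %in% chosen, nrow(sp$labels), ncol(sp$labels))
}

#' Band criteria for unsupervised superpixel selection
#'
#' A surrogate for the expert's interactive selection used in batch runs
#' and tests: superpixels qualify by mean intensity and by centroid depth,
#' optionally measured relative to a per-column anchor row (typically the
#' bright retinal pigment epithelium band), which makes the selection
#' robust to retinal tilt.
#'
#' @param intensity_range numeric `(lo, hi)` gray levels, `lo <= hi`.
#' @param depth_range numeric `(row_lo, row_hi)` in pixels, `row_lo <=
#'   row_hi`; absolute rows, or offsets below the anchor when an anchor is
#'   used.
#' @param anchor `NULL` (absolute depths), the string `"brightest"`
#'   (anchor at the brightest row of each column, median-smoothed), or a
#'   numeric vector of anchor rows, one per image column.
#' @return a `band_criteria` list.
#' @export
band_criteria <- function(intensity_range, depth_range, anchor = NULL) {
  if (length(intensity_range) != 2 || intensity_range[1] > intensity_range[2])
    stop("intensity_range must be (lo, hi) with lo <= hi", call. = FALSE)
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2])
    stop("depth_range must be (row_lo, row_hi) with row_lo <= row_hi",
         call. = FALSE)
  if (!is.null(anchor) && !identical(anchor, "brightest") &&
      !is.numeric(anchor))
    stop("anchor must be NULL, \"brightest\", or a numeric row profile",
         call. = FALSE)
  structure(list(intensity_range = as.numeric(intensity_range),
                 depth_range = as.numeric(depth_range),
                 anchor = anchor),
            class = "band_criteria")
}

#' Per-column brightest-band row profile
#'
#' Returns, for each image column, the row of maximum intensity, smoothed
#' with a running median. In a B-scan this tracks the hyper-reflective
#' RPE band and serves as a depth anchor that follows retinal tilt.
#'
#' @param img gray image matrix.
#' @param k odd running-median window (default 31, clipped to the width).
#' @return numeric vector of anchor rows, one per column.
#' @export
detect_bright_band <- function(img, k = 31L) {
  stopifnot_gray(img)
  prof <- apply(img, 2, which.max)
  k <- min(as.integer(k), ncol(img))
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= 3L) prof <- stats::runmed(prof, k, endrule = "median")
  as.numeric(prof)
}

#' Select superpixel labels matching band criteria
#'
#' Returns every label whose mean image intensity lies within
#' `intensity_range` and whose centroid row lies within `depth_range`
#' (interpreted relative to the anchor row at the centroid's column when
#' an anchor is given). Deterministic; labels returned sorted ascending.
#'
#' @param sp a `superpixel_map`.
#' @param img gray image matrix the mean intensities are computed from.
#' @param criteria a [band_criteria()] object.
#' @return sorted integer vector of label ids (possibly empty, with a
#'   warning).
#' @export
auto_select_band <- function(sp, img, criteria) {
  stopifnot(inherits(sp, "superpixel_map"), inherits(criteria, "band_criteria"))
  stopifnot_gray(img)
  if (!all(dim(img) == dim(sp$labels)))
    stop("image and superpixel map shapes differ", call. = FALSE)
  f <- factor(sp$labels, levels = seq_len(sp$K))
  mean_int <- as.numeric(tapply(img + 0.0, f, mean))
  cen_row <- sp$centroids$row
  cen_col <- sp$centroids$col

  anchor <- criteria$anchor
  if (identical(anchor, "brightest")) anchor <- detect_bright_band(img)
  if (is.null(anchor)) {
    ref <- rep(0, sp$K)
  } else {
    if (length(anchor) != ncol(img))
      stop("anchor profile must have one row per image column", call. = FALSE)
    ref <- anchor[pmin(pmax(round(cen_col), 1L), ncol(img))]
  }
  depth <- cen_row - ref
  ok <- mean_int >= criteria$intensity_range[1] &
        mean_int <= criteria$intensity_range[2] &
        depth >= criteria$depth_range[1] &
        depth <= criteria$depth_range[2]
  ids <- sort(which(ok))
  if (length(ids) == 0)
    warning("no superpixel matches the band criteria")
  ids
}

#' Region properties of a choroid mask
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return list with `area` (pixel count), `centroid` `(row, col)` means
#'   of the true-pixel coordinates, `bounding_box` `(top, left, height,
#'   width)` (1-based, tight), and `n_components` (4-connected).
#' @export
region_properties <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  area <- sum(mask)
  if (area == 0) stop("empty mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  comp <- cpp_components(mask + 0L)
  list(
    area = as.integer(area),
    centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
    bounding_box = c(top = min(idx[, 1]), left = min(idx[, 2]),
                     height = max(idx[, 1]) - min(idx[, 1]) + 1L,
                     width = max(idx[, 2]) - min(idx[, 2]) + 1L),
    n_components = length(unique(comp[mask]))
  )
}

moore_offsets <- matrix(c(0L, -1L,   # W
                          -1L, -1L,  # NW
                          -1L, 0L,   # N
                          -1L, 1L,   # NE
                          0L, 1L,    # E
                          1L, 1L,    # SE
                          1L, 0L,    # S
                          1L, -1L),  # SW
                        ncol = 2, byrow = TRUE)

trace_component <- function(comp_mask) {
  idx <- which(comp_mask, arr.ind = TRUE)
  if (nrow(idx) == 1L)
    return(data.frame(order = 1L, row = idx[1, 1], col = idx[1, 2]))
  h <- nrow(comp_mask); w <- ncol(comp_mask)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && comp_mask[r, c]
  # start: minimum row, then minimum column (top-left-most boundary pixel)
  r0 <- min(idx[, 1])
  c0 <- min(idx[idx[, 1] == r0, 2])
  # backtrack enters from the west neighbour (outside by construction)
  path_r <- integer(0); path_c <- integer(0)
  cur <- c(r0, c0); back <- c(r0, c0 - 1L)
  start <- cur; start_back <- back
  maxit <- 8L * nrow(idx) + 8L
  for (it in seq_len(maxit)) {
    path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
    # index of backtrack in the clockwise Moore order around cur
    d0 <- which(moore_offsets[, 1] == back[1] - cur[1] &
                moore_offsets[, 2] == back[2] - cur[2])
    found <- FALSE
    for (s in 1:8) {
      j <- ((d0 - 1L + s - 1L) %% 8L) + 1L
      cand <- cur + moore_offsets[j, ]
      if (inside(cand[1], cand[2])) {
        prev_j <- ((d0 - 1L + s - 2L) %% 8L) + 1L
        back <- cur + moore_offsets[prev_j, ]
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel handled above; safety
    if (all(cur == start) && all(back == start_back)) break
  }
  # keep only pixels with a 4-neighbour outside the component, drop
  # consecutive duplicates and a repeated closing pixel
  keep <- vapply(seq_along(path_r), function(i) {
    r <- path_r[i]; c <- path_c[i]
    !inside(r - 1L, c) || !inside(r + 1L, c) ||
      !inside(r, c - 1L) || !inside(r, c + 1L)
  }, logical(1))
  pr <- path_r[keep]; pc <- path_c[keep]
  if (length(pr) > 1L) {
    dup <- c(FALSE, pr[-1] == pr[-length(pr)] & pc[-1] == pc[-length(pc)])
    pr <- pr[!dup]; pc <- pc[!dup]
    if (length(pr) > 1L && pr[1] == pr[length(pr)] && pc[1] == pc[length(pc)]) {
      pr <- pr[-length(pr)]; pc <- pc[-length(pc)]
    }
  }
  data.frame(order = seq_along(pr), row = pr, col = pc)
}

#' Extract ordered outer boundaries of a mask
#'
#' For each 4-connected component, returns its outer contour — the
#' component pixels with at least one 4-neighbor outside the component —
#' traced clockwise (Moore neighbor tracing) starting from the
#' top-left-most boundary pixel.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return list of data frames, one per component (ascending component
#'   id), with columns `order`, `row`, `col`.
#' @export
extract_boundary <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  comp <- cpp_components(mask + 0L)
  ids <- sort(unique(comp[mask]))
  lapply(ids, function(k) trace_component(comp == k & mask))
}
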