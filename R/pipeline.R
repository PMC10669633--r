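# End-to-end pipeline runners: process B-scans to a metrics table,
# generate synthetic cohorts to disk, and run the group statistics.
# Every output is accompanied by a JSON sidecar carrying the full
# configuration, package version and input checksums for provenance.

#' Default pipeline configuration
#'
#' Nested configuration for [run_process()]: preprocessing, superpixel
#' and selection parameters. `selection$mode` is `"band"` (criteria
#' driven, batch-capable) or `"interactive"` (labels supplied by the
#' caller per image via `select_labels`).
#'
#' @param preprocess a [preprocess_params()] object.
#' @param superpixel a [superpixel_params()] object.
#' @param selection list with `mode` and, for band mode, a
#'   [band_criteria()] object under `criteria`.
#' @param save_intermediates write per-stage PNGs next to the outputs?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_params(),
                            superpixel = superpixel_params(),
                            selection = list(
                              mode = "band",
                              criteria = band_criteria(c(40, 80), c(5, 150),
                                                       anchor = "brightest")),
                            save_intermediates = FALSE) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(superpixel, "superpixel_params"))
  if (!selection$mode %in% c("band", "interactive"))
    stop("selection mode must be 'band' or 'interactive'", call. = FALSE)
  if (selection$mode == "band" && !inherits(selection$criteria, "band_criteria"))
    stop("band mode requires selection$criteria", call. = FALSE)
  structure(list(preprocess = preprocess, superpixel = superpixel,
                 selection = selection,
                 save_intermediates = isTRUE(save_intermediates)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `preprocess` (`gaussian_sigma`,
#' `spectral_median_window`, `equalize`), `superpixel`
#' (`n_superpixels`, `iterations`, `compactness`), `selection` (`mode`,
#' `intensity_range`, `depth_range`, `anchor`), `save_intermediates`.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_params, y$preprocess %||% list())
  sp <- do.call(superpixel_params, y$superpixel %||% list())
  sel <- y$selection %||% list()
  if (is.null(sel$mode) || sel$mode == "band") {
    crit <- band_criteria(
      intensity_range = sel$intensity_range %||% c(40, 80),
      depth_range = sel$depth_range %||% c(5, 150),
      anchor = sel$anchor %||% "brightest")
    sel <- list(mode = "band", criteria = crit)
  } else {
    sel <- list(mode = sel$mode)
  }
  pipeline_config(preprocess = pp, superpixel = sp, selection = sel,
                  save_intermediates = isTRUE(y$save_intermediates))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment one B-scan and compute its metrics
#'
#' Runs the five-stage chain on a single image: 8-bit conversion, square
#' crop, preprocessing, SLIC superpixelation with connectivity
#' enforcement, superpixel selection (band criteria or explicit labels),
#' and the (CA, COID, CD) metrics. COID is measured on the cropped
#' grayscale image before contrast enhancement, so gray levels keep their
#' acquisition scale.
#'
#' @param img gray image matrix, RGB array, or a file path.
#' @param config a [pipeline_config()] object.
#' @param select_labels explicit label ids for interactive mode.
#' @return list with `metrics` (`choroid_metrics`), `mask`, `superpixels`
#'   (`superpixel_map`), `selected` label ids, `gray` (cropped input) and
#'   `preprocessed` images.
#' @export
process_bscan <- function(img, config = pipeline_config(),
                          select_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(img)) img <- load_image(img)
  gray <- crop_square(to_gray8(img))
  pre <- preprocess_bscan(gray, config$preprocess)
  sp <- enforce_connectivity(slic_segment(pre, config$superpixel), img = pre)
  selected <- if (config$selection$mode == "band") {
    auto_select_band(sp, gray, config$selection$criteria)
  } else {
    if (is.null(select_labels))
      stop("interactive mode requires select_labels", call. = FALSE)
    select_labels
  }
  mask <- select_superpixels(sp, selected)
  list(metrics = compute_metrics(gray, mask), mask = mask,
       superpixels = sp, selected = sort(unique(as.integer(selected))),
       gray = gray, preprocessed = pre)
}

write_sidecar <- function(path, config, extra = list()) {
  payload <- c(list(
    package = "choroidsps",
    version = as.character(utils::packageVersion("choroidsps")),
    config = unclass_recursive(config)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Process a batch of B-scan images to a metrics table
#'
#' Applies [process_bscan()] to each image, appending one metrics row per
#' image. Per-image failures are caught, reported, and skipped; the
#' returned object records them so callers can signal partial failure.
#'
#' @param images character vector of image paths, or a named list of
#'   in-memory images.
#' @param config a [pipeline_config()] object.
#' @param output_dir optional directory; when given, writes
#'   `metrics.csv`, a JSON sidecar per image (selection, checksums) and,
#'   if `config$save_intermediates`, per-stage PNGs.
#' @param groups optional group label per image (recycled into the CSV).
#' @return (invisibly) list with `metrics` (data frame: `eye_id`,
#'   `group`, `CA_px2`, `COID`, `CD`) and `failures` (named character
#'   vector of error messages).
#' @export
run_process <- function(images, config = pipeline_config(),
                        output_dir = NULL, groups = NULL) {
  if (is.character(images)) {
    ids <- tools::file_path_sans_ext(basename(images))
    paths <- images
  } else {
    ids <- names(images)
    if (is.null(ids)) ids <- sprintf("scan_%03d", seq_along(images))
    paths <- rep(NA_character_, length(images))
  }
  if (!is.null(groups)) groups <- rep_len(groups, length(images))
  if (!is.null(output_dir))
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); failures <- character(0)
  for (i in seq_along(images)) {
    res <- tryCatch(
      process_bscan(if (is.character(images)) images[[i]] else images[[i]],
                    config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[ids[i]] <- conditionMessage(res)
      message("skipping ", ids[i], ": ", conditionMessage(res))
      next
    }
    m <- res$metrics
    rows[[ids[i]]] <- data.frame(
      eye_id = ids[i],
      group = if (is.null(groups)) NA_character_ else groups[i],
      CA_px2 = m$CA, COID = m$COID, CD = m$CD)
    if (!is.null(output_dir)) {
      write_sidecar(
        file.path(output_dir, paste0(ids[i], ".json")), config,
        list(eye_id = ids[i],
             selected_labels = res$selected,
             input = if (is.na(paths[i])) NULL else paths[i],
             input_md5 = if (is.na(paths[i])) NULL else
               unname(tools::md5sum(paths[i])),
             metrics = unclass(m)))
      if (config$save_intermediates) {
        save_gray(res$preprocessed,
                  file.path(output_dir, paste0(ids[i], "_preprocessed.png")))
        save_gray(quantize8(res$mask * 255),
                  file.path(output_dir, paste0(ids[i], "_mask.png")))
      }
    }
  }
  metrics <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else data.frame(eye_id = character(0), group = character(0),
                             CA_px2 = integer(0), COID = numeric(0),
                             CD = numeric(0))
  if (!is.null(output_dir))
    write.csv(metrics, file.path(output_dir, "metrics.csv"),
              row.names = FALSE)
  invisible(list(metrics = metrics, failures = failures))
}

#' Generate synthetic scans to disk
#'
#' Writes `n` seeded synthetic B-scans as image/mask PNG pairs with a
#' ground-truth JSON per scan and a cohort manifest CSV.
#'
#' @param spec a [synthetic_spec()] (its seed is re-derived per scan).
#' @param n number of scans.
#' @param seed master seed.
#' @param output_dir destination directory (created if needed).
#' @return (invisibly) the manifest data frame (`scan_id`, `group`,
#'   `true_CA`, `true_COID`).
#' @export
run_synth <- function(spec = synthetic_spec(), n = 1L, seed = 1L,
                      output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(n)) {
      s <- spec
      s$seed <- sample.int(.Machine$integer.max - 1L, 1L)
      scan <- generate_bscan(s)
      id <- sprintf("scan_%03d", i)
      save_gray(scan$image, file.path(output_dir, paste0(id, ".png")))
      save_gray(quantize8(scan$choroid_mask * 255),
                file.path(output_dir, paste0(id, "_mask.png")))
      jsonlite::write_json(
        list(scan_id = id, true_CA = scan$true_CA,
             true_COID = scan$true_COID, seed = s$seed),
        file.path(output_dir, paste0(id, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
      rows[[id]] <- data.frame(scan_id = id, group = NA_character_,
                               true_CA = scan$true_CA,
                               true_COID = scan$true_COID)
    }
  })
  manifest <- do.call(rbind, c(rows, make.row.names = FALSE))
  write.csv(manifest, file.path(output_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Run the group statistics on a metrics table
#'
#' Produces the per-group summary (mean +/- SD of CA, COID, CD), the
#' one-way ANOVA per metric and the Welch-Bonferroni post hoc pairs.
#'
#' @param metrics a metrics data frame as written by [run_process()]
#'   (`eye_id`, `group`, `CA_px2`, `COID`, `CD`), or a path to such a
#'   CSV.
#' @param alpha significance level (default 0.05).
#' @param output_dir optional directory for `group_summary.csv`,
#'   `posthoc.csv` and a readable `stats_report.txt`.
#' @return (invisibly) list with `summary`, `anova` (per metric) and
#'   `posthoc` (per metric).
#' @export
run_stats <- function(metrics, alpha = 0.05, output_dir = NULL) {
  if (is.character(metrics)) metrics <- read.csv(metrics)
  names(metrics)[names(metrics) == "CA_px2"] <- "CA"
  if (!"group" %in% names(metrics) || length(unique(metrics$group)) < 2)
    stop("need >= 2 groups", call. = FALSE)
  mcols <- intersect(c("CA", "COID", "CD"), names(metrics))
  summ <- summarize_groups(metrics, mcols)
  anova <- lapply(setNames(mcols, mcols), function(m)
    one_way_anova(metrics[[m]], metrics$group))
  posthoc <- lapply(setNames(mcols, mcols), function(m)
    pairwise_posthoc(metrics[[m]], metrics$group, alpha))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wide <- do.call(rbind, lapply(split(summ, summ$group), function(d)
      data.frame(group = d$group[1], n = d$n[1],
                 setNames(as.list(sprintf("%.2f +/- %.2f", d$mean, d$sd)),
                          d$metric))))
    write.csv(wide, file.path(output_dir, "group_summary.csv"),
              row.names = FALSE)
    ph <- do.call(rbind, lapply(names(posthoc), function(m)
      cbind(metric = m, posthoc[[m]])))
    write.csv(ph, file.path(output_dir, "posthoc.csv"), row.names = FALSE)
    rpt <- file.path(output_dir, "stats_report.txt")
    con <- file(rpt, "w"); on.exit(close(con), add = TRUE)
    for (m in mcols) {
      a <- anova[[m]]
      writeLines(sprintf("%s: F(%d, %d) = %.3f, p = %.3f", m,
                         a$df_between, a$df_within, a$F, a$p), con)
      p <- posthoc[[m]]
      for (j in seq_len(nrow(p)))
        writeLines(sprintf("  %s vs %s: p_adj = %.3f%s", p$group1[j],
                           p$group2[j], p$p_adj[j],
                           ifelse(p$significant[j], " *", "")), con)
    }
  }
  invisible(list(summary = summ, anova = anova, posthoc = posthoc))
}
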