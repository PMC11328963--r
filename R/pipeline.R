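list_pngs <- function(dir) {
  f <- sort(list.files(dir, pattern = "\\.png$", full.names = FALSE))
  stats::setNames(file.path(dir, f), sub("\\.png$", "", f))
}

#' Match PNG basenames across two directories
#'
#' @param dir_a,dir_b Directories containing PNG files.
#' @return A list with `matched` (character vector of common basenames, in
#'   lexicographic order), `only_a`, `only_b`.
#' @export
match_basenames <- function(dir_a, dir_b) {
  a <- list_pngs(dir_a); b <- list_pngs(dir_b)
  list(matched = sort(intersect(names(a), names(b))),
       only_a = sort(setdiff(names(a), names(b))),
       only_b = sort(setdiff(names(b), names(a))))
}

check_matching <- function(mb, what_a, what_b, allow_partial) {
  if (length(mb$only_a) || length(mb$only_b)) {
    msg <- sprintf("basename mismatch: %d only in %s (%s), %d only in %s (%s)",
                   length(mb$only_a), what_a, paste(utils::head(mb$only_a, 5), collapse = ", "),
                   length(mb$only_b), what_b, paste(utils::head(mb$only_b, 5), collapse = ", "))
    if (allow_partial) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  invisible(mb$matched)
}

#' Run the corrective-metrics stage over a directory pair
#'
#' Pairs `predictions/` and `annotations/` PNGs by basename, scores them in
#' lexicographic order with [evaluate_sequence()], and writes the training
#' log, the rolling-mean series and a stopping report to `out_dir`.
#'
#' @param pred_dir Directory of prediction masks.
#' @param ann_dir Directory of corrective-annotation PNGs.
#' @param out_dir Output directory (created if missing); `NULL` writes no
#'   files.
#' @param rule A [stopping_rule()].
#' @param foreground_rule,threshold Passed to [read_mask()].
#' @param colour_tolerance Passed to [read_annotation()].
#' @param allow_partial Proceed on basename mismatches (with a warning)
#'   instead of aborting.
#' @return The `training_log` tibble, invisibly.
#' @export
run_metrics <- function(pred_dir, ann_dir, out_dir = NULL,
                        rule = stopping_rule(), foreground_rule = "any_nonzero",
                        threshold = 0, colour_tolerance = 30,
                        allow_partial = FALSE) {
  mb <- match_basenames(pred_dir, ann_dir)
  ids <- check_matching(mb, "predictions", "annotations", allow_partial)
  log <- if (length(ids)) {
    pairs <- tibble::tibble(
      image_id = ids,
      pred = purrr::map(file.path(pred_dir, paste0(ids, ".png")), read_mask,
                        foreground_rule = foreground_rule, threshold = threshold),
      ann = purrr::map(file.path(ann_dir, paste0(ids, ".png")), read_annotation,
                       colour_tolerance = colour_tolerance))
    evaluate_sequence(pairs)
  } else {
    structure(tibble::tibble(image_id = character(), index = integer(),
                             precision = numeric(), recall = numeric(),
                             dice = numeric(), accuracy = numeric(),
                             predicted_area_px = numeric(),
                             corrected_area_px = numeric(),
                             area_error_px = numeric(),
                             annotated_fraction = numeric()),
              class = c("training_log", class(tibble::tibble())))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_training_log(log, file.path(out_dir, "training_log.csv"))
    readr::write_csv(rolling_mean(log, rule$metric, rule$window_n),
                     file.path(out_dir, "rolling_mean.csv"))
    si <- if (nrow(log)) stopping_index(log, rule) else NA_integer_
    readr::write_csv(tibble::tibble(metric = rule$metric,
                                    window_n = rule$window_n,
                                    threshold = rule$threshold,
                                    stopping_index = si,
                                    reached = !is.na(si)),
                     file.path(out_dir, "stopping_report.csv"))
  }
  invisible(log)
}

#' Run the measurement stage over a mask directory
#'
#' Labels and measures every mask; when a scale source is configured, adds
#' cm² columns. In laser mode each frame is calibrated independently from
#' its laser mask (matched by basename); frames whose calibration is
#' excluded (not exactly two laser dots) keep their pixel measurements but
#' get `NA` cm² values and a `laser_excluded` anomaly flag.
#'
#' @param mask_dir Directory of segmentation masks.
#' @param out_dir Output directory for `region_table.csv` and
#'   `anomaly_flags.csv`; `NULL` writes no files.
#' @param scale A global [scale_factor()] (fixed-reference mode), or `NULL`.
#' @param laser_dir Directory of laser masks (laser mode), or `NULL`.
#' @param true_separation_cm,min_region_px Laser-calibration parameters.
#' @param connectivity Region connectivity (default 8).
#' @param foreground_rule,threshold Passed to [read_mask()].
#' @param allow_partial Proceed when laser basenames do not cover all masks.
#' @return A list with `regions` (combined region table, with cm² columns
#'   when scaled), `calibration` (per-frame calibration report or `NULL`)
#'   and `flags` (anomaly flags tibble).
#' @export
run_measure <- function(mask_dir, out_dir = NULL, scale = NULL,
                        laser_dir = NULL, true_separation_cm = 5,
                        min_region_px = 3, connectivity = 8,
                        foreground_rule = "any_nonzero", threshold = 0,
                        allow_partial = FALSE) {
  paths <- list_pngs(mask_dir)
  if (!length(paths)) stop("no PNG masks found in `mask_dir`", call. = FALSE)
  masks <- purrr::map(paths, read_mask, foreground_rule = foreground_rule,
                      threshold = threshold)
  tables <- purrr::map(masks, measure_regions, connectivity = connectivity)
  regions <- combine_region_tables(tables)
  calib <- NULL
  flags <- tibble::tibble(image_id = character(), rule = character(),
                          detail = character())
  if (!is.null(laser_dir)) {
    mb <- match_basenames(mask_dir, laser_dir)
    check_matching(mb, "masks", "lasers", allow_partial)
    laser_masks <- purrr::map(list_pngs(laser_dir), read_mask,
                              foreground_rule = foreground_rule,
                              threshold = threshold)
    calib <- calibrate_frames(laser_masks, true_separation_cm, min_region_px,
                              connectivity)
    missing_laser <- setdiff(names(masks), calib$image_id)
    if (length(missing_laser)) {
      calib <- dplyr::bind_rows(calib, tibble::tibble(
        image_id = missing_laser, n_laser_regions = 0L,
        x1 = NA_real_, y1 = NA_real_, x2 = NA_real_, y2 = NA_real_,
        pixel_distance = NA_real_, px_per_cm = NA_real_,
        status = "excluded", reason = "laser mask missing"))
    }
    regions <- dplyr::left_join(
      regions,
      dplyr::select(calib, "image_id", "px_per_cm", laser_status = "status"),
      by = "image_id")
    regions$area_cm2 <- ifelse(is.na(regions$px_per_cm), NA_real_,
                               regions$area_px / regions$px_per_cm^2)
    excluded <- calib[calib$status == "excluded", , drop = FALSE]
    if (nrow(excluded)) {
      flags <- dplyr::bind_rows(flags, tibble::tibble(
        image_id = excluded$image_id, rule = "laser_excluded",
        detail = excluded$reason))
    }
  } else if (!is.null(scale)) {
    ppc <- scale_px_per_cm(scale)
    regions$px_per_cm <- ppc
    regions$area_cm2 <- regions$area_px / ppc^2
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(regions, file.path(out_dir, "region_table.csv"))
    if (!is.null(calib)) readr::write_csv(
      dplyr::select(calib, "image_id", "n_laser_regions", "pixel_distance",
                    "px_per_cm", "status", "reason"),
      file.path(out_dir, "calibration_report.csv"))
    readr::write_csv(flags, file.path(out_dir, "anomaly_flags.csv"))
  }
  list(regions = regions, calibration = calib, flags = flags)
}

#' Rule-based anomaly flags over a frame series
#'
#' An automated, conservative stand-in for the visual sweep through
#' segmentation thumbnails that catches camera malfunctions, missing
#' subjects and obstructions. Frames receive at most one primary flag, in
#' priority order: `zero_regions` (no regions where regions are expected),
#' `region_count_change` (count differs from `expected_regions`), then
#' `area_jump` (total area deviates from the series median by more than
#' `z_threshold` robust z-units, median/MAD). Flags are advisory: flagged
#' frames should be excluded from summaries but never deleted from
#' row-level output.
#'
#' @param frame_table A data frame ordered by frame with columns
#'   `image_id`, `n_regions`, `total_area`.
#' @param expected_regions Expected region count per frame, or `NULL`.
#' @param z_threshold Robust z-score threshold (default 4).
#' @return A tibble `image_id`, `rule`, `detail` (possibly empty).
#' @export
flag_anomalies <- function(frame_table, expected_regions = NULL, z_threshold = 4) {
  req <- c("image_id", "n_regions", "total_area")
  if (!all(req %in% names(frame_table)))
    stop("`frame_table` needs columns image_id, n_regions, total_area", call. = FALSE)
  n <- nrow(frame_table)
  rule <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)
  expect_any <- if (!is.null(expected_regions)) expected_regions > 0
                else any(frame_table$n_regions > 0)
  zero <- frame_table$n_regions == 0 & expect_any
  rule[zero] <- "zero_regions"
  detail[zero] <- "no regions detected"
  if (!is.null(expected_regions)) {
    chg <- is.na(rule) & frame_table$n_regions != expected_regions
    rule[chg] <- "region_count_change"
    detail[chg] <- sprintf("%d regions, expected %d",
                           frame_table$n_regions[chg], expected_regions)
  }
  med <- median(frame_table$total_area)
  md <- mad(frame_table$total_area)
  if (md > 0) {
    z <- abs(frame_table$total_area - med) / md
    jump <- is.na(rule) & z > z_threshold
    rule[jump] <- "area_jump"
    detail[jump] <- sprintf("robust z = %.1f", z[jump])
  }
  keep <- !is.na(rule)
  tibble::tibble(image_id = as.character(frame_table$image_id[keep]),
                 rule = rule[keep], detail = detail[keep])
}

#' Run dataset-level validation against manual masks
#'
#' Pools confusion counts over all prediction/manual pairs, summarises
#' per-image area differences in cm², and classifies success against the
#' metric thresholds.
#'
#' @param pred_dir,manual_dir Directories of prediction and manual masks.
#' @param scale A [scale_factor()] (or anything [area_to_cm2()] accepts).
#' @param out_dir Output directory for `validation_report.csv` and a text
#'   summary; `NULL` writes no files.
#' @param thresholds Passed to [classify_success()].
#' @param foreground_rule,threshold Passed to [read_mask()].
#' @param allow_partial Proceed on basename mismatches.
#' @return A one-row tibble combining pooled metrics, the area-difference
#'   summary and the success flags.
#' @export
run_validate <- function(pred_dir, manual_dir, scale, out_dir = NULL,
                         thresholds = success_thresholds(),
                         foreground_rule = "any_nonzero", threshold = 0,
                         allow_partial = FALSE) {
  mb <- match_basenames(pred_dir, manual_dir)
  ids <- check_matching(mb, "predictions", "manual masks", allow_partial)
  if (!length(ids)) stop("no matched image pairs to validate", call. = FALSE)
  pairs <- tibble::tibble(
    image_id = ids,
    pred = purrr::map(file.path(pred_dir, paste0(ids, ".png")), read_mask,
                      foreground_rule = foreground_rule, threshold = threshold),
    manual = purrr::map(file.path(manual_dir, paste0(ids, ".png")), read_mask,
                        foreground_rule = foreground_rule, threshold = threshold))
  pooled <- pooled_metrics(pairs)
  diffs <- area_difference_summary(pairs, scale)
  success <- classify_success(pooled$precision, pooled$recall, pooled$dice,
                              pooled$accuracy, thresholds)
  report <- dplyr::bind_cols(pooled, dplyr::select(diffs, -"n_images"), success)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(report, file.path(out_dir, "validation_report.csv"))
    txt <- c(
      sprintf("Validation over %d images (pooled confusion counts)", report$n_images),
      sprintf("  precision %.4f  recall %.4f  dice %.4f  accuracy %.4f",
              report$precision, report$recall, report$dice, report$accuracy),
      sprintf("  mean |area diff| %.3f cm2 (sd %.3f); mean %% diff %.2f%% (sd %.2f)",
              report$mean_abs_diff_cm2, report$sd_abs_diff_cm2,
              report$mean_pct_diff, report$sd_pct_diff),
      sprintf("  success: %s", ifelse(report$success, "yes", "no")))
    writeLines(txt, file.path(out_dir, "validation_summary.txt"))
  }
  report
}

#' Read a pipeline run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_metrics()],
#' [run_measure()] and [run_validate()]; unknown keys are kept as-is so
#' callers can carry extra metadata. Defaults match the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(foreground_rule = "any_nonzero", threshold = 0,
                   colour_tolerance = 30, connectivity = 8,
                   window_n = 10, stop_threshold = 0.95, stop_metric = "dice",
                   true_separation_cm = 5, min_region_px = 3,
                   reference_cm = 0.43, z_threshold = 4, allow_partial = FALSE,
                   seed = 1)
  utils::modifyList(defaults, cfg)
}
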