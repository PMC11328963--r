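cc_columns <- function(cc, need_tn = FALSE) {
  req <- c("tp", "fp", "fn", if (need_tn) "tn")
  if (!is.data.frame(cc) || !all(req %in% names(cc)))
    stop("expected a data frame with confusion-count columns tp/fp/fn", if (need_tn) "/tn",
         call. = FALSE)
  if (any(unlist(cc[req]) < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  cc
}

#' Segmentation metrics from confusion counts
#'
#' Vectorised over the rows of `cc`. When an image has no predicted
#' foreground (`tp + fp == 0`), precision is 1 if there is also no missed
#' foreground (`fn == 0`) and 0 otherwise, so that a correctly empty
#' prediction is not penalised; recall applies the symmetric convention.
#' Dice is `2*tp / (2*tp + fp + fn)` (1 for the empty/empty case) and equals
#' the harmonic mean of precision and recall whenever the latter is defined.
#'
#' @param cc A data frame with columns `tp`, `fp`, `fn` (and `tn` for
#'   [accuracy()]), e.g. the output of [confusion()] or
#'   [corrective_confusion()].
#' @return A numeric vector, one value per row of `cc`, each in \[0, 1\].
#' @seealso [confusion()], [classify_success()]
#' @export
precision <- function(cc) {
  cc <- cc_columns(cc)
  denom <- cc$tp + cc$fp
  ifelse(denom > 0, cc$tp / denom, ifelse(cc$fn == 0, 1, 0))
}

#' @rdname precision
#' @export
recall <- function(cc) {
  cc <- cc_columns(cc)
  denom <- cc$tp + cc$fn
  ifelse(denom > 0, cc$tp / denom, ifelse(cc$fp == 0, 1, 0))
}

#' @rdname precision
#' @export
dice <- function(cc) {
  cc <- cc_columns(cc)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  ifelse(denom > 0, 2 * cc$tp / denom, 1)
}

#' @rdname precision
#' @export
accuracy <- function(cc) {
  cc <- cc_columns(cc, need_tn = TRUE)
  total <- cc$tp + cc$fp + cc$fn + cc$tn
  if (any(total == 0)) stop("accuracy undefined for an empty image", call. = FALSE)
  (cc$tp + cc$tn) / total
}

#' Confusion counts implied by a corrective annotation
#'
#' Treats the corrected segmentation (prediction minus green plus red) as
#' ground truth: false positives are the green strokes inside the
#' prediction, false negatives the red strokes outside it. Identical to
#' `confusion(pred, apply_correction(pred, ann))`.
#'
#' @inheritParams apply_correction
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
corrective_confusion <- function(pred, ann) {
  stopifnot(is_binary_mask(pred), is_annotation_mask(ann))
  check_same_dims(pred, ann$green)
  p <- unclass(pred)
  fp <- sum(ann$green & p)
  fn <- sum(ann$red & !p)
  tp <- sum(p) - fp
  tibble::tibble(tp = as.numeric(tp), fp = as.numeric(fp), fn = as.numeric(fn),
                 tn = as.numeric(length(p) - tp - fp - fn))
}

#' Signed area error of a prediction
#'
#' Predicted foreground area minus corrected foreground area, in pixels.
#' Positive values mean the model over-predicts.
#'
#' @inheritParams apply_correction
#' @return Signed pixel count.
#' @export
area_error <- function(pred, ann) {
  stopifnot(is_binary_mask(pred), is_annotation_mask(ann))
  check_same_dims(pred, ann$green)
  sum(ann$green & pred) - sum(ann$red & !unclass(pred))
}

#' Score an ordered sequence of predictions against their corrections
#'
#' One metric record per (prediction, annotation) pair, in input order:
#' this is the training log an interactive segmentation session produces.
#' `annotated_fraction` (annotated pixels / image pixels) is carried as a
#' diagnostic: sparse corrections can flatter the model, and this column
#' makes that visible without altering the metrics.
#'
#' @param pairs A data frame with list-columns `pred` ([binary_mask]) and
#'   `ann` ([annotation_mask]), and optionally `image_id`. The output of
#'   [generate_training_sequence()] can be passed directly.
#' @return A `training_log` tibble with columns `image_id`, `index`
#'   (0-based), `precision`, `recall`, `dice`, `accuracy`,
#'   `predicted_area_px`, `corrected_area_px`, `area_error_px`,
#'   `annotated_fraction`.
#' @export
evaluate_sequence <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("pred", "ann") %in% names(pairs)))
    stop("`pairs` must be a data frame with `pred` and `ann` list-columns", call. = FALSE)
  n <- nrow(pairs)
  ids <- if ("image_id" %in% names(pairs)) as.character(pairs$image_id)
         else sprintf("img_%04d", seq_len(n) - 1L)
  rows <- purrr::map(seq_len(n), function(i) {
    pred <- pairs$pred[[i]]; ann <- pairs$ann[[i]]
    rec <- tryCatch({
      cc <- corrective_confusion(pred, ann)
      pa <- mask_area(pred)
      ca <- pa - cc$fp + cc$fn
      tibble::tibble(
        precision = precision(cc), recall = recall(cc), dice = dice(cc),
        accuracy = accuracy(cc),
        predicted_area_px = as.numeric(pa), corrected_area_px = as.numeric(ca),
        area_error_px = as.numeric(pa - ca),
        annotated_fraction = (sum(ann$green) + sum(ann$red)) / length(ann$green))
    }, error = function(e) {
      stop(sprintf("image '%s': %s", ids[i], conditionMessage(e)), call. = FALSE)
    })
    rec
  })
  log <- dplyr::bind_cols(
    tibble::tibble(image_id = ids, index = seq_len(n) - 1L),
    dplyr::bind_rows(rows))
  class(log) <- c("training_log", class(log))
  log
}

#' Trailing rolling mean of a training-log metric
#'
#' The value reported at (0-based) index `i` is the unweighted mean of the
#' metric over records `i - window_n + 1` to `i`; indices before the first
#' full window are absent.
#'
#' @param log A `training_log` (or any data frame with an `index` column and
#'   the metric column).
#' @param metric Column name, default `"dice"`.
#' @param window_n Window length (>= 1), default 10.
#' @return A tibble with columns `index` and `roll_mean`.
#' @export
rolling_mean <- function(log, metric = "dice", window_n = 10) {
  if (window_n < 1) stop("`window_n` must be >= 1", call. = FALSE)
  if (!metric %in% names(log)) stop(sprintf("no column '%s' in log", metric), call. = FALSE)
  x <- log[[metric]]
  n <- length(x)
  if (n < window_n) return(tibble::tibble(index = integer(), roll_mean = numeric()))
  at <- seq.int(window_n, n)
  tibble::tibble(
    index = log$index[at],
    roll_mean = vapply(at, function(i) mean(x[(i - window_n + 1):i]), numeric(1)))
}

#' Stopping rule for interactive training
#'
#' Training stops once the trailing rolling mean (window `window_n`) of the
#' chosen corrective metric first reaches `threshold`. The defaults — a
#' window of 10 images and a dice threshold of 0.95 — follow common practice
#' for corrective-annotation workflows on high-contrast subjects.
#'
#' @param window_n Rolling window length (default 10).
#' @param threshold Metric threshold in (0, 1\] (default 0.95).
#' @param metric One of `"precision"`, `"recall"`, `"dice"`, `"accuracy"`.
#' @return A `stopping_rule` object.
#' @export
stopping_rule <- function(window_n = 10, threshold = 0.95, metric = "dice") {
  metric <- match.arg(metric, c("precision", "recall", "dice", "accuracy"))
  if (window_n < 1) stop("`window_n` must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]", call. = FALSE)
  structure(list(window_n = as.integer(window_n), threshold = threshold,
                 metric = metric), class = "stopping_rule")
}

#' @export
print.stopping_rule <- function(x, ...) {
  cat(sprintf("<stopping_rule: rolling mean (n = %d) of %s >= %g>\n",
              x$window_n, x$metric, x$threshold))
  invisible(x)
}

#' First index at which a stopping rule fires
#'
#' By default the rule fires at the smallest 0-based index whose trailing
#' rolling mean strictly exceeds the threshold: a window sitting exactly at
#' the threshold — e.g. nine perfect images and one at dice 0.5 under a
#' 0.95 threshold — is treated as still in transition, so training stops
#' only once the window has cleared it. Set `inclusive = TRUE` to count an
#' exact tie as reached (necessary for a threshold of 1).
#'
#' @param log A `training_log`.
#' @param rule A [stopping_rule()].
#' @param inclusive Fire on an exact tie with the threshold (default
#'   `FALSE`).
#' @return The smallest qualifying 0-based record index, or `NA` if the
#'   rule never fires (including when the log is shorter than the window).
#' @export
stopping_index <- function(log, rule = stopping_rule(), inclusive = FALSE) {
  stopifnot(inherits(rule, "stopping_rule"))
  rm <- rolling_mean(log, rule$metric, rule$window_n)
  hit <- if (inclusive) which(rm$roll_mean >= rule$threshold)
         else which(rm$roll_mean > rule$threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(rm$index[hit[1]])
}

#' Write a training log to CSV
#'
#' Columns: `image_id`, `index`, `precision`, `recall`, `dice`, `accuracy`,
#' `predicted_area_px`, `corrected_area_px`, `area_error_px`.
#'
#' @param log A `training_log`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  cols <- c("image_id", "index", "precision", "recall", "dice", "accuracy",
            "predicted_area_px", "corrected_area_px", "area_error_px")
  readr::write_csv(as.data.frame(log)[, cols], path)
  invisible(path)
}

#' @rdname write_training_log
#' @export
read_training_log <- function(path) {
  log <- readr::read_csv(path, show_col_types = FALSE)
  class(log) <- c("training_log", class(log))
  log
}
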