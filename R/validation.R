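#' Pooled (micro-averaged) metrics over an image set
#'
#' Confusion counts are summed across all images first and the metric
#' formulas applied once to the totals. This weights every pixel equally —
#' images with more foreground contribute more — and differs from averaging
#' per-image metric values, which over-weights small or empty frames.
#'
#' @param pairs A data frame with list-columns `pred` and `manual` (both
#'   [binary_mask]); each pair must be dimension-matched.
#' @return A one-row tibble: `n_images`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `dice`, `accuracy`.
#' @export
pooled_metrics <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("pred", "manual") %in% names(pairs)))
    stop("`pairs` must be a data frame with `pred` and `manual` list-columns", call. = FALSE)
  if (nrow(pairs) == 0L) stop("`pairs` must contain at least one image", call. = FALSE)
  ccs <- purrr::map2(pairs$pred, pairs$manual, confusion)
  tot <- dplyr::summarise(dplyr::bind_rows(ccs),
                          dplyr::across(c("tp", "fp", "fn", "tn"), sum))
  tibble::tibble(n_images = nrow(pairs), tot,
                 precision = precision(tot), recall = recall(tot),
                 dice = dice(tot), accuracy = accuracy(tot))
}

#' Per-image area differences between prediction and manual annotation
#'
#' Reports the mean absolute difference of the scaled areas (with sample
#' standard deviation) and the mean percentage difference relative to the
#' manual area. The signed mean (predicted minus manual; positive =
#' over-prediction) is reported alongside because "average difference" is
#' ambiguous in common usage. Images with zero manual area are excluded
#' from the percentage summary and counted in `n_pct_excluded`.
#'
#' @inheritParams pooled_metrics
#' @param scale A [scale_factor()] (or anything [area_to_cm2()] accepts).
#' @return A one-row tibble: `n_images`, `mean_abs_diff_cm2`,
#'   `sd_abs_diff_cm2`, `mean_pct_diff`, `sd_pct_diff`,
#'   `mean_signed_diff_cm2`, `sd_signed_diff_cm2`, `n_pct_excluded`.
#' @export
area_difference_summary <- function(pairs, scale) {
  if (!is.data.frame(pairs) || !all(c("pred", "manual") %in% names(pairs)))
    stop("`pairs` must be a data frame with `pred` and `manual` list-columns", call. = FALSE)
  if (nrow(pairs) == 0L) stop("`pairs` must contain at least one image", call. = FALSE)
  pa <- area_to_cm2(purrr::map_dbl(pairs$pred, mask_area), scale)
  ma <- area_to_cm2(purrr::map_dbl(pairs$manual, mask_area), scale)
  signed <- pa - ma
  ok <- ma > 0
  pct <- 100 * abs(signed[ok]) / ma[ok]
  tibble::tibble(
    n_images = nrow(pairs),
    mean_abs_diff_cm2 = mean(abs(signed)),
    sd_abs_diff_cm2 = if (length(signed) > 1) sd(abs(signed)) else NA_real_,
    mean_pct_diff = if (any(ok)) mean(pct) else NA_real_,
    sd_pct_diff = if (sum(ok) > 1) sd(pct) else NA_real_,
    mean_signed_diff_cm2 = mean(signed),
    sd_signed_diff_cm2 = if (length(signed) > 1) sd(signed) else NA_real_,
    n_pct_excluded = sum(!ok))
}

#' Agreement between corrected (or manual) and predicted areas
#'
#' Ordinary least squares of predicted on corrected area plus the Pearson
#' correlation. The intercept is interpretable as a systematic over- or
#' under-prediction in cm²; the signed mean error is reported alongside as
#' a model-free counterpart.
#'
#' @param data A data frame, or a numeric vector of corrected/true areas.
#' @param corrected,predicted Column names (tidy evaluation) when `data` is
#'   a data frame; when `data` is a numeric vector, `corrected` is the
#'   vector of predicted areas and `predicted` is ignored.
#' @return An `area_agreement` object; see [glance.area_agreement()] and
#'   [tidy.area_agreement()].
#' @examples
#' x <- c(1, 2, 3, 4)
#' fit <- area_agreement(x, x + 5)
#' glance(fit)
#' @export
area_agreement <- function(data, corrected, predicted) {
  if (is.data.frame(data)) {
    x <- dplyr::pull(data, {{ corrected }})
    y <- dplyr::pull(data, {{ predicted }})
  } else {
    x <- as.numeric(data)
    y <- as.numeric(corrected)
  }
  if (length(x) != length(y)) stop("`corrected` and `predicted` differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) <= 0) stop("corrected areas have zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  # an exactly collinear input is a legitimate case here, not a misuse
  sm <- suppressWarnings(summary(fit))
  r <- cor(x, y)
  structure(list(
    fit = fit, n = length(x), pearson_r = r,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    slope_se = sm$coefficients[2, 2], intercept_se = sm$coefficients[1, 2],
    r_squared = sm$r.squared, mean_signed_error = mean(y - x),
    x = x, y = y), class = "area_agreement")
}

#' @export
print.area_agreement <- function(x, ...) {
  cat(sprintf(paste0(
    "<area_agreement: n = %d>\n",
    "  pearson r = %.4f (R^2 = %.4f)\n",
    "  predicted = %.4f * corrected + %.4f\n",
    "  mean signed error = %.4f\n"),
    x$n, x$pearson_r, x$r_squared, x$slope, x$intercept, x$mean_signed_error))
  invisible(x)
}

#' @rdname area_agreement
#' @param x An `area_agreement` object.
#' @param ... Unused.
#' @export
glance.area_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, pearson_r = x$pearson_r, r_squared = x$r_squared,
                 slope = x$slope, intercept = x$intercept,
                 slope_se = x$slope_se, intercept_se = x$intercept_se,
                 mean_signed_error = x$mean_signed_error)
}

#' @rdname area_agreement
#' @export
tidy.area_agreement <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std_error = c(x$intercept_se, x$slope_se))
}

#' @rdname area_agreement
#' @param object An `area_agreement` object.
#' @export
autoplot.area_agreement <- function(object, ...) {
  df <- tibble::tibble(corrected = object$x, predicted = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$corrected, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "corrected / manual area",
                  y = "predicted area",
                  title = sprintf("r = %.3f, slope = %.3f, intercept = %.3f",
                                  object$pearson_r, object$slope, object$intercept)) +
    ggplot2::theme_minimal()
}

#' Default model-success thresholds
#'
#' Published working thresholds for segmentation models on marine imagery:
#' precision >= 0.71, recall >= 0.75, dice >= 0.74, accuracy >= 0.76.
#'
#' @return A named numeric vector.
#' @export
success_thresholds <- function() {
  c(precision = 0.71, recall = 0.75, dice = 0.74, accuracy = 0.76)
}

#' Classify model success against metric thresholds
#'
#' All four thresholds must be met (inclusive) for overall success.
#'
#' @param precision,recall,dice,accuracy Metric values in \[0, 1\].
#' @param thresholds Named numeric vector as [success_thresholds()].
#' @return A one-row tibble with per-metric flags (`precision_ok`, ...) and
#'   an overall `success` logical.
#' @export
classify_success <- function(precision, recall, dice, accuracy,
                             thresholds = success_thresholds()) {
  vals <- c(precision = precision, recall = recall, dice = dice, accuracy = accuracy)
  if (any(vals < 0 | vals > 1)) stop("metrics must be in [0, 1]", call. = FALSE)
  ok <- vals >= thresholds[names(vals)]
  tibble::tibble(precision_ok = ok[["precision"]], recall_ok = ok[["recall"]],
                 dice_ok = ok[["dice"]], accuracy_ok = ok[["accuracy"]],
                 success = all(ok))
}
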