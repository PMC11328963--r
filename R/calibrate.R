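#' Euclidean distance between two laser points
#'
#' @param p1,p2 Numeric `(x, y)` coordinate pairs in pixels.
#' @return Distance in pixels.
#' @examples
#' laser_distance(c(0, 0), c(3, 4))  # 5
#' @export
laser_distance <- function(p1, p2) {
  stopifnot(length(p1) == 2, length(p2) == 2, is.finite(p1), is.finite(p2))
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Pixel-to-centimetre scale factor
#'
#' @param px_per_cm Pixels per centimetre (> 0).
#' @param source `"lasers"` or `"fixed_reference"`.
#' @param rel_error Optional relative error of the reference length,
#'   propagated as metadata (not a distribution).
#' @return A `scale_factor` object with fields `px_per_cm`, `cm2_per_px`,
#'   `source`, `rel_error`.
#' @export
scale_factor <- function(px_per_cm, source = c("fixed_reference", "lasers"),
                         rel_error = NA_real_) {
  source <- match.arg(source)
  if (!is.finite(px_per_cm) || px_per_cm <= 0)
    stop("`px_per_cm` must be positive", call. = FALSE)
  structure(list(px_per_cm = px_per_cm, cm2_per_px = (1 / px_per_cm)^2,
                 source = source, rel_error = rel_error),
            class = "scale_factor")
}

#' @export
print.scale_factor <- function(x, ...) {
  cat(sprintf("<scale_factor: %.4g px/cm (%.4g cm^2/px), source = %s>\n",
              x$px_per_cm, x$cm2_per_px, x$source))
  invisible(x)
}

#' Scale factor from a fixed reference length
#'
#' When no lasers are available, a structure of known physical size visible
#' in the frame — by default the average width of a *Lophelia pertusa*
#' branch, 0.43 cm (sd 0.09) — calibrates the image.
#'
#' @param reference_px Measured reference length in pixels (> 0).
#' @param reference_cm True reference length in cm (default 0.43).
#' @param reference_cm_sd Spread of the reference length in cm (default
#'   0.09), carried as a relative error on the scale factor.
#' @return A [scale_factor()].
#' @examples
#' fixed_reference_scale(43)  # 100 px/cm
#' @export
fixed_reference_scale <- function(reference_px, reference_cm = 0.43,
                                  reference_cm_sd = 0.09) {
  if (!is.finite(reference_px) || reference_px <= 0)
    stop("`reference_px` must be positive", call. = FALSE)
  if (!is.finite(reference_cm) || reference_cm <= 0)
    stop("`reference_cm` must be positive", call. = FALSE)
  scale_factor(reference_px / reference_cm, source = "fixed_reference",
               rel_error = if (is.finite(reference_cm_sd)) reference_cm_sd / reference_cm
                           else NA_real_)
}

#' Per-frame scale calibration from a segmented laser-dot mask
#'
#' Connected regions smaller than `min_region_px` are discarded as noise.
#' If exactly two regions survive, their sub-pixel centroids give the pixel
#' distance between the lasers and hence `px_per_cm = distance /
#' true_separation_cm`. Any other surviving count — one laser out of frame,
#' or extra reflections — excludes the frame; exclusion is reported as a
#' status, not an error, so batch runs keep an audit trail.
#'
#' @param laser_mask A [binary_mask] of segmented laser dots.
#' @param true_separation_cm Physical laser separation in cm (default 5).
#' @param min_region_px Minimum region area in pixels kept as a laser dot
#'   (default 3).
#' @param connectivity Connectivity for dot labelling (default 8).
#' @return A one-row tibble: `n_laser_regions`, `x1`, `y1`, `x2`, `y2`
#'   (0-based centroid coordinates), `pixel_distance`, `px_per_cm`,
#'   `status` (`"ok"`/`"excluded"`), `reason`.
#' @export
calibrate_from_lasers <- function(laser_mask, true_separation_cm = 5,
                                  min_region_px = 3, connectivity = 8) {
  stopifnot(is_binary_mask(laser_mask))
  if (true_separation_cm <= 0) stop("`true_separation_cm` must be positive", call. = FALSE)
  props <- measure_regions(laser_mask, connectivity)
  props <- props[props$area_px >= min_region_px, , drop = FALSE]
  k <- nrow(props)
  if (k != 2L) {
    reason <- if (k == 1L) "one laser region detected"
              else sprintf("%d laser regions detected", k)
    return(tibble::tibble(n_laser_regions = k, x1 = NA_real_, y1 = NA_real_,
                          x2 = NA_real_, y2 = NA_real_,
                          pixel_distance = NA_real_, px_per_cm = NA_real_,
                          status = "excluded", reason = reason))
  }
  props <- props[order(props$centroid_x, props$centroid_y), ]
  d <- laser_distance(c(props$centroid_x[1], props$centroid_y[1]),
                      c(props$centroid_x[2], props$centroid_y[2]))
  tibble::tibble(n_laser_regions = 2L,
                 x1 = props$centroid_x[1], y1 = props$centroid_y[1],
                 x2 = props$centroid_x[2], y2 = props$centroid_y[2],
                 pixel_distance = d, px_per_cm = d / true_separation_cm,
                 status = "ok", reason = NA_character_)
}

#' Calibrate a set of laser frames
#'
#' @param masks A named list of [binary_mask] laser masks (names are image
#'   ids).
#' @inheritParams calibrate_from_lasers
#' @return A tibble with one calibration row per frame (`image_id`,
#'   `n_laser_regions`, `pixel_distance`, `px_per_cm`, `status`, `reason`).
#' @export
calibrate_frames <- function(masks, true_separation_cm = 5, min_region_px = 3,
                             connectivity = 8) {
  if (!length(masks)) stop("`masks` must contain at least one frame", call. = FALSE)
  purrr::imap_dfr(masks, function(m, id) {
    dplyr::bind_cols(
      tibble::tibble(image_id = id),
      calibrate_from_lasers(m, true_separation_cm, min_region_px, connectivity))
  })
}

scale_px_per_cm <- function(scale) {
  if (inherits(scale, "scale_factor")) return(scale$px_per_cm)
  if (is.data.frame(scale) && "px_per_cm" %in% names(scale)) {
    if (nrow(scale) != 1L) stop("scale data frame must have one row", call. = FALSE)
    return(scale$px_per_cm)
  }
  if (is.numeric(scale) && length(scale) == 1L) return(scale)
  stop("`scale` must be a scale_factor, a one-row calibration, or px_per_cm", call. = FALSE)
}

#' Convert pixel areas to square centimetres
#'
#' Multiplies by `cm2_per_px = (1/px_per_cm)^2`. Applies identically to
#' signed area errors; the conversion is linear.
#'
#' @param area_px Pixel areas (may be signed, e.g. area errors).
#' @param scale A [scale_factor()], a one-row calibration tibble from
#'   [calibrate_from_lasers()], or a bare `px_per_cm` number.
#' @return Areas in cm². Vectorised.
#' @export
area_to_cm2 <- function(area_px, scale) {
  ppc <- scale_px_per_cm(scale)
  if (!is.finite(ppc) || ppc <= 0) stop("invalid or excluded scale factor", call. = FALSE)
  area_px / ppc^2
}

#' Relative areas within a series
#'
#' Each area divided by the series maximum, so the largest observation maps
#' to 1. Useful for comparing contraction/expansion cycles across
#' differently scaled datasets.
#'
#' @param areas Numeric vector of non-negative areas, at least one positive.
#' @return Ratios in \[0, 1\].
#' @export
relative_areas <- function(areas) {
  if (!length(areas)) stop("`areas` must be non-empty", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("`areas` must be finite and non-negative", call. = FALSE)
  mx <- max(areas)
  if (mx <= 0) stop("all areas are zero; relative areas undefined", call. = FALSE)
  areas / mx
}
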