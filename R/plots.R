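#' Plot a training log
#'
#' Metric-versus-image curves for an interactive-training sequence, with
#' the rolling mean of the stopping metric overlaid and the stopping index
#' (if reached) marked by a vertical line.
#'
#' @param object A `training_log` from [evaluate_sequence()].
#' @param rule A [stopping_rule()] used for the rolling-mean overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_log <- function(object, rule = stopping_rule(), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as.data.frame(object), "index", "precision", "recall",
                  "dice", "accuracy"),
    cols = c("precision", "recall", "dice", "accuracy"),
    names_to = "metric", values_to = "value")
  rm <- rolling_mean(object, rule$metric, rule$window_n)
  si <- stopping_index(object, rule)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_line(data = rm,
                       ggplot2::aes(x = .data$index, y = .data$roll_mean),
                       inherit.aes = FALSE, linewidth = 1) +
    ggplot2::geom_hline(yintercept = rule$threshold, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "image index", y = "metric value",
                  title = sprintf("corrective-annotation metrics (rolling %s, n = %d)",
                                  rule$metric, rule$window_n)) +
    ggplot2::theme_minimal()
  if (!is.na(si)) p <- p + ggplot2::geom_vline(xintercept = si, linetype = "dashed")
  p
}

#' Plot a binary mask or labelled regions
#'
#' @param mask A [binary_mask] or `labeled_regions` object.
#' @return A ggplot raster of the mask (regions coloured by label, with
#'   centroids marked).
#' @export
plot_mask <- function(mask) {
  if (is_binary_mask(mask)) {
    df <- tidyr::expand_grid(y = seq_len(nrow(mask)) - 1L,
                             x = seq_len(ncol(mask)) - 1L)
    df$fg <- as.vector(t(unclass(mask)))
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$fg)) +
             ggplot2::geom_raster() +
             ggplot2::scale_y_reverse() +
             ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95",
                                                   `TRUE` = "steelblue"),
                                        guide = "none") +
             ggplot2::coord_fixed() + ggplot2::theme_void())
  }
  stopifnot(inherits(mask, "labeled_regions"))
  df <- tidyr::expand_grid(y = seq_len(nrow(mask)) - 1L,
                           x = seq_len(ncol(mask)) - 1L)
  df$label <- as.vector(t(unclass(mask)))
  props <- region_properties(mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = props,
                        ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y),
                        inherit.aes = FALSE, shape = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_d(option = "C", begin = 0.2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "region") +
    ggplot2::theme_void()
}
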