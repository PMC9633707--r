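#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a distance-binned similarity profile
#'
#' Observed per-bin means with SEM ribbons; when a spatial-shuffle null is
#' supplied its mean and 95% CI band are overlaid, and flagged bins from a
#' cluster-excess test are marked.
#'
#' @param object A [binned_profile()] tibble.
#' @param null Optional [spatial_shuffle_null()] tibble.
#' @param flags Optional [cluster_excess_test()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wm_binned_profile
#' @export
autoplot.wm_binned_profile <- function(object, null = NULL, flags = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::labs(x = "inter-soma distance (µm)",
                  y = "tuning similarity") +
    ggplot2::theme_classic()
  if (!is.null(null)) {
    null$bin_mid <- (null$bin_lo + null$bin_hi) / 2
    p <- p +
      ggplot2::geom_ribbon(data = null,
                           ggplot2::aes(x = .data$bin_mid, y = .data$null_mean,
                                        ymin = .data$null_lo,
                                        ymax = .data$null_hi),
                           fill = "grey50", alpha = 0.3) +
      ggplot2::geom_line(data = null,
                         ggplot2::aes(x = .data$bin_mid, y = .data$null_mean),
                         colour = "grey40")
  }
  if (!is.null(flags) && any(flags$flag)) {
    fb <- flags[flags$flag, ]
    fb$bin_mid <- (fb$bin_lo + fb$bin_hi) / 2
    p <- p + ggplot2::geom_point(data = fb,
                                 ggplot2::aes(x = .data$bin_mid,
                                              y = .data$observed_mean),
                                 shape = 8, colour = "black", size = 2)
  }
  p
}

#' Plot a barrel map with an optional tuned-cell roster
#'
#' Column boundaries and centroids; when tuning summaries and a roster are
#' given, responsive cells are drawn colour-coded by BW identity with
#' shape distinguishing CW-tuned from non-CW-tuned cells.
#'
#' @param map A [barrel_map()].
#' @param rois Optional roster (`roi_id`, `x`, `y`).
#' @param summaries Optional [tuning_summaries()] tibble.
#' @return A ggplot object.
#' @export
plot_barrel_map <- function(map, rois = NULL, summaries = NULL) {
  polys <- purrr::map_dfr(seq_len(nrow(map)), function(i) {
    b <- map$boundary[[i]]
    tibble::tibble(whisker = map$whisker[i], x = b[, 1], y = b[, 2])
  })
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(data = polys,
                          ggplot2::aes(.data$x, .data$y, group = .data$whisker),
                          fill = NA, colour = "grey30") +
    ggplot2::geom_text(
      data = tibble::tibble(w = map$whisker, x = map$centroid_x,
                            y = map$centroid_y),
      ggplot2::aes(.data$x, .data$y, label = .data$w),
      colour = "grey55", size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_classic()
  if (!is.null(rois) && !is.null(summaries)) {
    d <- dplyr::inner_join(summaries, rois, by = "roi_id")
    if ("column_class" %in% names(d)) {
      p <- p + ggplot2::geom_point(
        data = d, ggplot2::aes(.data$x, .data$y, colour = .data$bw,
                               shape = .data$column_class), size = 1.6)
    } else {
      p <- p + ggplot2::geom_point(
        data = d, ggplot2::aes(.data$x, .data$y, colour = .data$bw),
        size = 1.6)
    }
    p <- p + ggplot2::labs(colour = "BW", shape = NULL)
  }
  p
}

#' Plot interval-subsampled stability estimates
#'
#' Mean and bootstrap 95% CI of a stability quantity per session-interval
#' class.
#'
#' @param estimates An [interval_subsample()] tibble.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_interval_estimates <- function(estimates,
                                    ylab = "fraction with tuning change") {
  ggplot2::ggplot(estimates, ggplot2::aes(x = factor(.data$delta),
                                          y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::labs(x = "session interval (Δ)", y = ylab) +
    ggplot2::theme_classic()
}
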