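#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a precision-recall / discrimination-threshold curve
#'
#' Precision, recall and F1 against the discrimination threshold, the
#' standard view for choosing a behavior classifier's cutoff.
#'
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pr_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$value, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "discrimination threshold", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ethogram raster of behavior bouts
#'
#' @param bouts Bout tibble (any mix of behaviors), e.g. row-bound
#'   [labels_to_bouts()] output.
#' @param fps Frames per second, used for the time axis.
#' @return A ggplot.
#' @export
plot_ethogram <- function(bouts, fps) {
  ggplot2::ggplot(bouts, ggplot2::aes(
    xmin = .data$start_frame / fps,
    xmax = (.data$end_frame + 1) / fps,
    ymin = as.integer(factor(.data$behavior)) - 0.4,
    ymax = as.integer(factor(.data$behavior)) + 0.4,
    fill = .data$behavior
  )) +
    ggplot2::geom_rect(show.legend = FALSE) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(factor(bouts$behavior))),
      labels = levels(factor(bouts$behavior))
    ) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of category mean importance ranks across behaviors
#'
#' @param rank_tbl Row-bound [category_mean_rank()] outputs with an added
#'   `behavior` column.
#' @return A ggplot (yellow = more important, dark = less).
#' @export
plot_category_ranks <- function(rank_tbl) {
  ggplot2::ggplot(rank_tbl, ggplot2::aes(
    x = .data$behavior, y = .data$category, fill = .data$mean_rank
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  name = "mean rank\n(1 = top)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-category attribution sums, present vs absent frames
#'
#' @param sums Output of [attribution_category_sums()], optionally
#'   row-bound over behaviors with a `behavior` column.
#' @return A ggplot.
#' @export
plot_attribution_sums <- function(sums) {
  long <- tidyr::pivot_longer(
    sums, c("present_sum", "absent_sum"),
    names_to = "frames", values_to = "sum"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sum, y = .data$category, fill = .data$frames
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "summed attribution (probability shift)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("behavior" %in% names(long)) {
    p <- p + ggplot2::facet_wrap(~behavior)
  }
  p
}
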