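#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a cohort of activity series
#'
#' Activity against hours before farrowing onset, one line per sow.
#'
#' @param cohort Tibble with `sow_id`, `minutes_to_onset`, `activity`.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_activity_cohort <- function(cohort, alpha = 0.7) {
  ggplot(cohort, aes(x = -.data$minutes_to_onset / 60, y = .data$activity,
                     group = .data$sow_id, colour = .data$sow_id)) +
    geom_line(alpha = alpha) +
    labs(x = "hours before farrowing onset", y = "activity (normalized)",
         colour = "sow") +
    theme_minimal()
}

#' @describeIn interval_report Plot MAE and R-squared per pre-onset interval.
#' @param object An `interval_report`.
#' @param ... Unused.
#' @method autoplot interval_report
#' @export
autoplot.interval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, interval = factor(.data$interval,
                                            levels = rev(.data$interval))),
    cols = c("mae", "r2"), names_to = "metric", values_to = "value"
  )
  ggplot(df, aes(x = .data$interval, y = .data$value)) +
    geom_col() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "interval before onset", y = NULL) +
    theme_minimal()
}

#' @describeIn claptnet_fit Plot the training history (train loss and
#'   validation MAE per epoch).
#' @param object A trained `claptnet`.
#' @param ... Unused.
#' @method autoplot claptnet
#' @export
autoplot.claptnet <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0L) fc_abort("model has no training history to plot.")
  df <- tidyr::pivot_longer(h, cols = c("train_loss", "val_mae"),
                            names_to = "series", values_to = "value")
  df <- df[is.finite(df$value), , drop = FALSE]
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}

#' Plot an activity series with its STL trend
#'
#' @param decomposition Tibble from [stl_trend()].
#' @return A ggplot object.
#' @export
plot_stl_trend <- function(decomposition) {
  ggplot(decomposition, aes(x = .data$point_index)) +
    geom_line(aes(y = .data$value), colour = "grey60") +
    geom_line(aes(y = .data$trend), colour = "darkgreen", linewidth = 0.9) +
    labs(x = "time point", y = "activity",
         title = "activity (grey) and STL trend (green)") +
    theme_minimal()
}
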