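# ggplot2 displays: weekly allocation bars against capacity, and
# forecast-vs-observed traces.

#' Plot a schedule's weekly allocation
#'
#' Bars of harvested ears per week; dashed line at the storage capacity and
#' (for three-step fixed-capacity plans) the relaxed per-week capacity.
#'
#' @param object a `harvest_schedule` or `harvest_plan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.harvest_schedule <- function(object, ...) {
  weekly <- object$weekly[object$weekly$used, , drop = FALSE]
  p <- ggplot2::ggplot(weekly,
                       ggplot2::aes(x = .data$week,
                                    y = .data$total_quantity)) +
    ggplot2::geom_col(fill = "goldenrod3") +
    ggplot2::labs(x = "harvest week", y = "ears of corn",
                  title = "Weekly harvest allocation")
  if (!is.na(object$capacity)) {
    p <- p + ggplot2::geom_hline(yintercept = object$capacity,
                                 linetype = "dashed", colour = "steelblue")
  }
  if (any(weekly$extra_capacity > 0)) {
    p <- p + ggplot2::geom_point(
      data = weekly[weekly$extra_capacity > 0, , drop = FALSE],
      ggplot2::aes(y = .data$capacity + .data$extra_capacity),
      shape = 4, colour = "firebrick")
  }
  p
}

#' @rdname autoplot.harvest_schedule
#' @export
autoplot.harvest_plan <- function(object, ...) {
  p <- autoplot(object$schedule)
  if (!is.null(object$proposed_capacity)) {
    p <- p + ggplot2::geom_hline(yintercept = object$proposed_capacity,
                                 linetype = "dashed", colour = "steelblue")
  }
  p
}

#' Plot forecast against observation
#'
#' @param pred numeric forecast values (one horizon).
#' @param obs numeric observed values, same length.
#' @param start_day day index of the first forecast day (for the x axis).
#' @return a ggplot.
#' @export
plot_forecast <- function(pred, obs, start_day = 1L) {
  stopifnot(length(pred) == length(obs))
  df <- tibble(
    day = start_day + seq_along(pred) - 1L,
    value = c(obs, pred),
    series = rep(c("observed", "forecast"), each = length(pred))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "GDU (degree-days)",
                  title = "Daily GDU forecast")
}
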