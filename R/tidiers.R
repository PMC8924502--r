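# broom-style tidiers for the fitted/solved objects.

#' Tidy a harvest schedule
#'
#' @param x a `harvest_schedule`.
#' @param ... unused.
#' @return the per-population assignment tibble (`population`,
#'   `harvest_week`, `quantity`, and `planting_day` when attached).
#' @export
tidy.harvest_schedule <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.harvest_schedule
#' @export
tidy.harvest_plan <- function(x, ...) {
  tidy(x$schedule)
}

#' One-row summary of a harvest schedule
#'
#' @param x a `harvest_schedule`.
#' @param ... unused.
#' @return tibble with `status`, `weeks_used`, `last_week`,
#'   `total_quantity`, `capacity`, `max_weekly_total`.
#' @export
glance.harvest_schedule <- function(x, ...) {
  tibble(
    status = x$status,
    weeks_used = length(x$used_weeks),
    last_week = if (length(x$used_weeks) > 0L) max(x$used_weeks) else 0L,
    total_quantity = sum(x$assignment$quantity),
    capacity = x$capacity,
    max_weekly_total = max(x$weekly$total_quantity)
  )
}

#' @rdname glance.harvest_schedule
#' @export
glance.harvest_plan <- function(x, ...) {
  out <- glance(x$schedule)
  out$path <- x$path
  out$extra_capacity_total <- sum(x$m %||% 0)
  out$proposed_capacity <- x$proposed_capacity %||% NA_real_
  out
}

#' Tidy a fitted CNN forecaster
#'
#' @param x a `cnn_forecaster`.
#' @param ... unused.
#' @return tibble of per-epoch training loss (`epoch`, `mse_scaled`).
#' @export
tidy.cnn_forecaster <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), mse_scaled = x$loss)
}

#' One-row summary of a fitted CNN forecaster
#'
#' @param x a `cnn_forecaster`.
#' @param ... unused.
#' @return tibble with the architecture sizes and final training loss.
#' @export
glance.cnn_forecaster <- function(x, ...) {
  tibble(
    lookback = x$lookback, horizon = x$horizon,
    conv_filters = x$spec$conv_filters, kernel_size = x$spec$kernel_size,
    dense_units = x$spec$dense_units, epochs = x$spec$epochs,
    final_loss_scaled = tail(x$loss, 1)
  )
}
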