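# Seasonal-naive benchmark forecaster: the always-available reference the
# CNN is compared against. Any library forecaster (e.g. a TBATS fit with a
# 365.25-day season) can be plugged in through the same `hp_forecaster`
# contract by supplying a `predict` function field.

#' Seasonal-naive forecaster
#'
#' Predicts each future day by copying the value observed `period` days
#' earlier, repeating the final observed cycle across the horizon. Requires
#' no fitting and is exact on any noiseless series with integer period
#' `period`.
#'
#' @param period seasonal period in days (e.g. 365).
#' @param horizon forecast length in days (default 547).
#' @return a `seasonal_naive_forecaster` (also class `hp_forecaster`).
#' @export
#' @examples
#' fc <- seasonal_naive(365, horizon = 30)
#' predict_horizon(fc, sin(2 * pi * (1:730) / 365))[1:5]
seasonal_naive <- function(period, horizon = 547L) {
  stopifnot(is_count(period), is_count(horizon))
  structure(
    list(name = "seasonal_naive", period = as.integer(period),
         horizon = as.integer(horizon)),
    class = c("seasonal_naive_forecaster", "hp_forecaster")
  )
}

#' @rdname predict_horizon
#' @export
predict_horizon.seasonal_naive_forecaster <- function(object, recent, ...) {
  recent <- as.numeric(recent)
  p <- object$period
  if (length(recent) < p) {
    abort(sprintf(
      "seasonal-naive needs at least `period` = %d recent values, got %d",
      p, length(recent)))
  }
  cycle <- tail(recent, p)
  h <- object$horizon
  cycle[((seq_len(h) - 1L) %% p) + 1L]
}

#' Wrap a prediction function as a pluggable forecaster
#'
#' Adapter for external forecasters (a TBATS library fit, an ensemble, ...):
#' anything that maps the last `lookback` daily values to `horizon` daily
#' values can stand behind the forecaster contract.
#'
#' @param predict function taking a numeric vector of recent values and
#'   returning `horizon` forecast values.
#' @param name identifier used in reports.
#' @param horizon forecast length the function returns.
#' @return an `hp_forecaster`.
#' @export
plugin_forecaster <- function(predict, name = "plugin", horizon = 547L) {
  stopifnot(is.function(predict), is_count(horizon))
  structure(list(name = name, predict = predict,
                 horizon = as.integer(horizon)),
            class = "hp_forecaster")
}
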