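#' Forecast error metrics
#'
#' Mean squared error and relative root mean squared error,
#' `RRMSE = 100 * RMSE / mean(observed)` in percent. RRMSE is undefined
#' (returned as `NA` with a warning) when the observed mean is not positive.
#'
#' @param pred numeric forecast values.
#' @param obs numeric observed values, same length.
#' @return one-row tibble with `mse` (squared degree-days) and `rrmse_pct`.
#' @export
#' @examples
#' forecast_metrics(c(3, 3, 3, 3), c(2, 2, 2, 2))  # mse 1, rrmse 50%
forecast_metrics <- function(pred, obs) {
  pred <- as.numeric(pred)
  obs <- as.numeric(obs)
  if (length(pred) != length(obs)) {
    abort(sprintf("`pred` (%d) and `obs` (%d) must have equal length",
                  length(pred), length(obs)))
  }
  if (length(obs) == 0L) abort("empty inputs")
  mse <- mean((pred - obs)^2)
  mo <- mean(obs)
  rrmse <- if (mo > 0) 100 * sqrt(mse) / mo else {
    warn("mean(obs) <= 0: RRMSE undefined, returning NA")
    NA_real_
  }
  tibble(mse = mse, rrmse_pct = rrmse)
}

#' Evaluate a forecaster over a windowed test set
#'
#' Runs one-shot horizon predictions for every test sample and pools the
#' errors into a single MSE/RRMSE pair.
#'
#' @param object a fitted forecaster.
#' @param test a `gdu_windows` dataset.
#' @return one-row tibble with `model`, `n_samples`, `mse`, `rrmse_pct`.
#' @export
evaluate_forecaster <- function(object, test) {
  stopifnot(inherits(test, "gdu_windows"))
  n <- nrow(test$features)
  if (n < 1L) abort("empty test dataset")
  preds <- t(vapply(seq_len(n), function(t) {
    predict_horizon(object, test$features[t, ])
  }, numeric(test$horizon)))
  m <- forecast_metrics(as.numeric(preds), as.numeric(test$responses))
  tibble(model = object$name %||% "forecaster", n_samples = n,
         mse = m$mse, rrmse_pct = m$rrmse_pct)
}
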