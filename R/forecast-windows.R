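# Sliding-window preprocessing for multi-horizon forecasting: each sample
# uses `lookback` consecutive daily GDUs as features and the following
# `horizon` days as the multi-output response; consecutive samples are
# shifted by one day.

#' Sliding windows over a daily GDU series
#'
#' @param series [gdu_series()] tibble or numeric vector of daily GDUs.
#' @param lookback feature length in days (default 730 = two years).
#' @param horizon response length in days (default 547 = 1.5 years).
#' @return a `gdu_windows` object: list with `features`
#'   (`n_samples x lookback` matrix), `responses` (`n_samples x horizon`),
#'   `lookback`, `horizon`. A series shorter than `lookback + horizon`
#'   yields an empty dataset with a warning.
#' @export
#' @examples
#' w <- make_sliding_windows(sin(1:200), lookback = 60, horizon = 30)
#' nrow(w$features)  # 200 - 60 - 30 + 1
make_sliding_windows <- function(series, lookback = 730L, horizon = 547L) {
  stopifnot(is_count(lookback), is_count(horizon))
  values <- gdu_values(series)
  n <- length(values) - lookback - horizon + 1L
  if (n < 1L) {
    warn(sprintf(
      "series of length %d is shorter than lookback + horizon = %d; empty dataset",
      length(values), lookback + horizon))
    n <- 0L
  }
  features <- matrix(NA_real_, n, lookback)
  responses <- matrix(NA_real_, n, horizon)
  for (t in seq_len(n)) {
    features[t, ] <- values[t:(t + lookback - 1L)]
    responses[t, ] <- values[(t + lookback):(t + lookback + horizon - 1L)]
  }
  structure(list(features = features, responses = responses,
                 lookback = as.integer(lookback),
                 horizon = as.integer(horizon)),
            class = "gdu_windows")
}

#' @export
print.gdu_windows <- function(x, ...) {
  cat("<gdu_windows> ", nrow(x$features), " samples; lookback ", x$lookback,
      ", horizon ", x$horizon, "\n", sep = "")
  invisible(x)
}

#' Chronological train/test split
#'
#' Splits a windowed dataset without shuffling: samples strictly before
#' `boundary` train, samples at or after it test. Use `frac` to place the
#' boundary at a fraction of the samples (the study design trains on the
#' first 8.5 of 10 years).
#'
#' @param dataset a `gdu_windows` object.
#' @param boundary 1-based sample index where the test set starts; or
#'   `NULL` to use `frac`.
#' @param frac train fraction used when `boundary` is `NULL` (default 0.85).
#' @return list with `train` and `test`, both `gdu_windows`.
#' @export
chronological_split <- function(dataset, boundary = NULL, frac = 0.85) {
  stopifnot(inherits(dataset, "gdu_windows"))
  n <- nrow(dataset$features)
  if (is.null(boundary)) boundary <- floor(n * frac) + 1L
  if (!is.numeric(boundary) || length(boundary) != 1L ||
      boundary < 0 || boundary > n + 1L) {
    abort(sprintf("`boundary` must be a sample index in 0..%d", n + 1L))
  }
  boundary <- as.integer(boundary)
  if (boundary <= 1L) {
    warn("empty training set: boundary at or before the first sample")
    boundary <- 1L
  }
  take <- function(idx) {
    structure(list(features = dataset$features[idx, , drop = FALSE],
                   responses = dataset$responses[idx, , drop = FALSE],
                   lookback = dataset$lookback, horizon = dataset$horizon),
              class = "gdu_windows")
  }
  list(train = take(seq_len(max(boundary - 1L, 0L))),
       test = take(seq.int(boundary, length.out = n - boundary + 1L)))
}
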