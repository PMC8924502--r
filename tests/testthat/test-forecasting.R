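test_that("sliding windows have the right count and one-day-shift structure", {
  w <- make_sliding_windows(seq_len(1286), lookback = 730, horizon = 547)
  expect_equal(nrow(w$features), 10L)   # T - lookback - horizon + 1
  expect_equal(ncol(w$features), 730L)
  expect_equal(ncol(w$responses), 547L)
  # minimal length gives exactly one sample
  w1 <- make_sliding_windows(seq_len(1277), 730, 547)
  expect_equal(nrow(w1$features), 1L)
  # sample t is the series slice starting at t
  expect_equal(w$features[3, ], 3:732)
  expect_equal(w$responses[3, ], 733:1279)
  # one-day shift property row-wise
  for (t in 1:9) {
    expect_equal(w$features[t, -1], w$features[t + 1, -730])
  }
  # too-short series warns and yields an empty dataset
  expect_warning(w0 <- make_sliding_windows(seq_len(100), 730, 547),
                 "shorter")
  expect_equal(nrow(w0$features), 0L)
})

test_that("chronological split preserves order and handles edges", {
  w <- make_sliding_windows(seq_len(1286), 730, 547)  # 10 samples
  sp <- chronological_split(w, boundary = 9)
  expect_equal(nrow(sp$train$features), 8L)
  expect_equal(nrow(sp$test$features), 2L)
  # no shuffling: last train sample immediately precedes first test sample
  expect_equal(sp$train$features[8, -1], sp$test$features[1, -730])
  expect_warning(sp0 <- chronological_split(w, boundary = 0), "empty training")
  expect_equal(nrow(sp0$train$features), 0L)
  expect_equal(nrow(sp0$test$features), 10L)
  expect_error(chronological_split(w, boundary = 20), "0..11")
  # default fraction puts ~85% in training
  spf <- chronological_split(w)
  expect_equal(nrow(spf$train$features), 8L)
})

test_that("seasonal naive continues a periodic series exactly", {
  x <- sin(2 * pi * (1:730) / 365)
  fc <- seasonal_naive(365, horizon = 365)
  pred <- predict_horizon(fc, x)
  expect_equal(pred, sin(2 * pi * (731:1095) / 365), tolerance = 1e-12)
  m <- forecast_metrics(pred, sin(2 * pi * (731:1095) / 365) + 2)
  # constant series: rrmse 0
  fc2 <- seasonal_naive(5, horizon = 12)
  pred2 <- predict_horizon(fc2, rep(3, 10))
  expect_equal(forecast_metrics(pred2, rep(3, 12))$rrmse_pct, 0)
  # period 1 repeats the last value
  fc3 <- seasonal_naive(1, horizon = 4)
  expect_equal(predict_horizon(fc3, c(5, 9, 2)), rep(2, 4))
  expect_error(predict_horizon(seasonal_naive(50, 10), rep(1, 20)),
               "at least")
})

test_that("forecast metrics match hand arithmetic and scale invariance", {
  m <- forecast_metrics(rep(3, 4), rep(2, 4))
  expect_equal(m$mse, 1)
  expect_equal(m$rrmse_pct, 50)
  expect_equal(forecast_metrics(1:5, 1:5)$mse, 0)
  expect_equal(forecast_metrics(1:5, 1:5)$rrmse_pct, 0)
  # RRMSE invariant under common positive rescaling
  set.seed(3)
  pred <- runif(50, 5, 10)
  obs <- runif(50, 5, 10)
  r1 <- forecast_metrics(pred, obs)$rrmse_pct
  r2 <- forecast_metrics(3.7 * pred, 3.7 * obs)$rrmse_pct
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_warning(bad <- forecast_metrics(c(1, 2), c(-3, 1)), "undefined")
  expect_true(is.na(bad$rrmse_pct))
  expect_error(forecast_metrics(1:3, 1:4), "equal length")
})

test_that("the reference architecture builds and validates shapes", {
  spec <- cnn_spec()
  expect_equal(spec$input_length, 730L)
  expect_equal(spec$conv_filters, 128L)
  expect_equal(spec$kernel_size, 2L)
  expect_equal(spec$dense_units, 100L)
  expect_equal(spec$output_units, 547L)
  # mismatched dataset is a configuration error
  w <- make_sliding_windows(seq_len(200), 60, 30)
  expect_error(fit_cnn(spec, w), "lookback")
  small <- cnn_spec(input_length = 60, output_units = 40)
  expect_error(fit_cnn(small, w), "horizon")
})

test_that("CNN training is seeded and deterministic", {
  vals <- benchmark_series(n = 300)
  w <- make_sliding_windows(vals, 60, 30)
  spec <- cnn_spec(input_length = 60, conv_filters = 4, kernel_size = 2,
                   dense_units = 8, output_units = 30, epochs = 3,
                   batch_size = 32, seed = 7)
  m1 <- fit_cnn(spec, w)
  m2 <- fit_cnn(spec, w)
  recent <- tail(vals, 60)
  expect_identical(predict_horizon(m1, recent), predict_horizon(m2, recent))
  expect_equal(length(predict_horizon(m1, recent)), 30L)
  expect_true(all(is.finite(predict_horizon(m1, recent))))
  expect_error(predict_horizon(m1, recent[-1]), "exactly 60")
  # training reduces the loss
  expect_lt(tail(m1$loss, 1), m1$loss[1])
})

test_that("CNN gradients agree with finite differences on a tiny net", {
  set.seed(5)
  spec <- cnn_spec(input_length = 8, conv_filters = 2, kernel_size = 2,
                   dense_units = 3, output_units = 2, epochs = 1,
                   batch_size = 4, seed = 1)
  X <- matrix(runif(4 * 8), 4, 8)
  Y <- matrix(runif(4 * 2), 4, 2)
  par <- harvestplan:::cnn_init(spec)
  fw <- harvestplan:::cnn_forward(par, spec, X, keep = TRUE)
  grad <- harvestplan:::cnn_gradients(par, spec, fw, Y)
  loss_at <- function(p) {
    mean((harvestplan:::cnn_forward(p, spec, X) - Y)^2)
  }
  eps <- 1e-6
  for (nm in c("Wc", "W2", "W3", "bc", "b2", "b3")) {
    target <- par[[nm]]
    for (ii in seq_len(min(length(target), 4L))) {
      pp <- par; pp[[nm]][ii] <- pp[[nm]][ii] + eps
      pm <- par; pm[[nm]][ii] <- pm[[nm]][ii] - eps
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grad[[nm]][ii], fd, tolerance = 1e-3)
    }
  }
})

test_that("plugin forecasters satisfy the contract", {
  fc <- plugin_forecaster(function(recent) rep(mean(recent), 12),
                          name = "mean", horizon = 12)
  out <- predict_horizon(fc, 1:10)
  expect_equal(out, rep(5.5, 12))
  bad <- plugin_forecaster(function(recent) c(1, NA), horizon = 2)
  expect_error(predict_horizon(bad, 1:5), "non-finite")
})
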