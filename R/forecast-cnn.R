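# One-dimensional convolutional forecaster, implemented directly in R:
# input -> conv1d (filters, kernel) -> ReLU -> max-pool -> dense (ReLU) ->
# linear output, trained by Adam on mean squared error. Shapes follow the
# reference architecture: 730-day input, 128 filters of kernel 2, pool 2,
# 100 dense units, 547 linear outputs.

#' 1D-CNN forecaster specification
#'
#' @param input_length feature length in days (default 730).
#' @param conv_filters number of convolution filters (default 128).
#' @param kernel_size convolution kernel width in days (default 2).
#' @param activation `"relu"` (the only supported activation).
#' @param pool_size max-pooling width and stride (default 2).
#' @param dense_units fully connected layer width (default 100).
#' @param output_units forecast horizon in days (default 547).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param scale min-max scale inputs/outputs on the training range
#'   (default `TRUE`).
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return a `cnn_spec` object.
#' @export
cnn_spec <- function(input_length = 730L, conv_filters = 128L,
                     kernel_size = 2L, activation = "relu",
                     pool_size = 2L, dense_units = 100L,
                     output_units = 547L, epochs = 50L, batch_size = 32L,
                     learning_rate = 1e-3, scale = TRUE, seed = 42L) {
  stopifnot(is_count(input_length), is_count(conv_filters),
            is_count(kernel_size), is_count(pool_size),
            is_count(dense_units), is_count(output_units),
            is_count(epochs), is_count(batch_size),
            is_number(learning_rate), learning_rate > 0)
  if (!identical(activation, "relu")) {
    abort("only activation = \"relu\" is supported")
  }
  if (kernel_size > input_length) {
    abort("kernel_size cannot exceed input_length")
  }
  conv_len <- input_length - kernel_size + 1L
  if (conv_len < pool_size) abort("pool_size too large for the conv output")
  structure(
    list(input_length = as.integer(input_length),
         conv_filters = as.integer(conv_filters),
         kernel_size = as.integer(kernel_size), activation = activation,
         pool_size = as.integer(pool_size),
         dense_units = as.integer(dense_units),
         output_units = as.integer(output_units),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, scale = isTRUE(scale),
         seed = as.integer(seed)),
    class = "cnn_spec"
  )
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("<cnn_spec> input ", x$input_length, " -> conv(", x$conv_filters,
      " x k", x$kernel_size, ", relu) -> maxpool(", x$pool_size,
      ") -> dense(", x$dense_units, ", relu) -> linear(", x$output_units,
      ")\n", sep = "")
  invisible(x)
}

# ---- internal forward / backward machinery -------------------------------
# X: n x L matrix. Conv output stored as a list of n x T1 matrices, one per
# filter (T1 = L - k + 1); pooled output flattened to n x (T2 * F).

cnn_init <- function(spec) {
  k <- spec$kernel_size
  f <- spec$conv_filters
  t1 <- spec$input_length - k + 1L
  t2 <- t1 %/% spec$pool_size
  flat <- t2 * f
  he <- function(nr, nc, fan_in) {
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(Wc = he(k, f, k), bc = rep(0, f),
       W2 = he(flat, spec$dense_units, flat), b2 = rep(0, spec$dense_units),
       W3 = he(spec$dense_units, spec$output_units, spec$dense_units),
       b3 = rep(0, spec$output_units),
       t1 = t1, t2 = t2, flat = flat)
}

cnn_forward <- function(par, spec, X, keep = FALSE) {
  n <- nrow(X)
  k <- spec$kernel_size
  p <- spec$pool_size
  t1 <- par$t1
  t2 <- par$t2
  f <- spec$conv_filters
  Z1 <- vector("list", f)
  Fl <- matrix(0, n, par$flat)
  argmax <- if (keep) vector("list", f)
  pool_cols <- lapply(seq_len(p), function(u) seq(u, by = p, length.out = t2))
  for (fi in seq_len(f)) {
    z <- matrix(par$bc[fi], n, t1)
    for (u in seq_len(k)) {
      z <- z + X[, u:(u + t1 - 1L), drop = FALSE] * par$Wc[u, fi]
    }
    a <- pmax(z, 0)
    m <- a[, pool_cols[[1L]], drop = FALSE]
    am <- if (keep) matrix(1L, n, t2)
    for (u in seq.int(2L, length.out = p - 1L)) {
      cand <- a[, pool_cols[[u]], drop = FALSE]
      upd <- cand > m
      m[upd] <- cand[upd]
      if (keep) am[upd] <- u
    }
    Fl[, (fi - 1L) * t2 + seq_len(t2)] <- m
    if (keep) {
      Z1[[fi]] <- z
      argmax[[fi]] <- am
    }
  }
  H1 <- pmax(sweep(Fl %*% par$W2, 2, par$b2, `+`), 0)
  Yhat <- sweep(H1 %*% par$W3, 2, par$b3, `+`)
  if (!keep) return(Yhat)
  list(Yhat = Yhat, H1 = H1, Fl = Fl, Z1 = Z1, argmax = argmax, X = X,
       pool_cols = pool_cols)
}

cnn_gradients <- function(par, spec, fw, Y) {
  n <- nrow(Y)
  p <- spec$pool_size
  t1 <- par$t1
  t2 <- par$t2
  k <- spec$kernel_size
  f <- spec$conv_filters
  dY <- 2 * (fw$Yhat - Y) / (n * ncol(Y))
  dW3 <- crossprod(fw$H1, dY)
  db3 <- colSums(dY)
  dH1 <- (dY %*% t(par$W3)) * (fw$H1 > 0)
  dW2 <- crossprod(fw$Fl, dH1)
  db2 <- colSums(dH1)
  dFl <- dH1 %*% t(par$W2)
  dWc <- matrix(0, k, f)
  dbc <- numeric(f)
  for (fi in seq_len(f)) {
    dM <- dFl[, (fi - 1L) * t2 + seq_len(t2), drop = FALSE]
    am <- fw$argmax[[fi]]
    dZ <- matrix(0, n, t1)
    for (u in seq_len(p)) {
      sel <- am == u
      if (any(sel)) {
        slice <- dZ[, fw$pool_cols[[u]], drop = FALSE]
        slice[sel] <- slice[sel] + dM[sel]
        dZ[, fw$pool_cols[[u]]] <- slice
      }
    }
    dZ <- dZ * (fw$Z1[[fi]] > 0)
    dbc[fi] <- sum(dZ)
    for (u in seq_len(k)) {
      dWc[u, fi] <- sum(dZ * fw$X[, u:(u + t1 - 1L), drop = FALSE])
    }
  }
  list(Wc = dWc, bc = dbc, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

adam_state <- function(par) {
  nm <- c("Wc", "bc", "W2", "b2", "W3", "b3")
  list(m = lapply(par[nm], function(x) x * 0),
       v = lapply(par[nm], function(x) x * 0), t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grad)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

#' Fit the 1D-CNN forecaster
#'
#' Trains the convolutional network on a windowed dataset with Adam and
#' mean-squared-error loss. Training is fully seeded: two fits with the
#' same spec and data produce bit-identical predictions. Inputs and outputs
#' are min-max scaled on the training range when `spec$scale` is `TRUE`.
#'
#' @param spec a [cnn_spec()]; `input_length`/`output_units` must match the
#'   dataset's lookback/horizon.
#' @param train a non-empty `gdu_windows` dataset.
#' @return a `cnn_forecaster` (also class `hp_forecaster`) with the fitted
#'   weights, the scaling range, and the per-epoch training loss.
#' @export
fit_cnn <- function(spec, train) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(train, "gdu_windows"))
  n <- nrow(train$features)
  if (n < 1L) abort("training dataset is empty")
  if (spec$input_length != train$lookback) {
    abort(sprintf("spec input_length %d != dataset lookback %d",
                  spec$input_length, train$lookback))
  }
  if (spec$output_units != train$horizon) {
    abort(sprintf("spec output_units %d != dataset horizon %d",
                  spec$output_units, train$horizon))
  }
  rng <- if (spec$scale) {
    r <- range(c(train$features, train$responses))
    if (diff(r) == 0) r <- c(r[1] - 0.5, r[2] + 0.5)
    r
  } else c(0, 1)
  sc <- function(x) (x - rng[1]) / (rng[2] - rng[1])
  X <- sc(train$features)
  Y <- sc(train$responses)
  losses <- numeric(spec$epochs)
  with_seed(spec$seed, {
    par <- cnn_init(spec)
    st <- adam_state(par)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      ep_loss <- 0
      for (b in starts) {
        idx <- ord[b:min(b + spec$batch_size - 1L, n)]
        fw <- cnn_forward(par, spec, X[idx, , drop = FALSE], keep = TRUE)
        grad <- cnn_gradients(par, spec, fw, Y[idx, , drop = FALSE])
        upd <- adam_step(par, grad, st, spec$learning_rate)
        par <- upd$par
        st <- upd$st
        ep_loss <- ep_loss + mean((fw$Yhat - Y[idx, , drop = FALSE])^2) *
          length(idx)
      }
      losses[ep] <- ep_loss / n
    }
    structure(
      list(name = "cnn", spec = spec, par = par, range = rng,
           lookback = spec$input_length, horizon = spec$output_units,
           loss = losses),
      class = c("cnn_forecaster", "hp_forecaster")
    )
  })
}

#' Forecast a full horizon from the most recent lookback window
#'
#' One-shot multi-horizon prediction: given exactly `lookback` recent daily
#' GDU values, returns the next `horizon` daily values.
#'
#' @param object a fitted forecaster (`cnn_forecaster`,
#'   `seasonal_naive_forecaster`, or any `hp_forecaster` with a `predict`
#'   function field).
#' @param recent numeric vector of the last `lookback` daily GDUs.
#' @param ... unused.
#' @return numeric vector of length `horizon`.
#' @export
predict_horizon <- function(object, recent, ...) {
  UseMethod("predict_horizon")
}

#' @rdname predict_horizon
#' @export
predict_horizon.cnn_forecaster <- function(object, recent, ...) {
  recent <- as.numeric(recent)
  if (length(recent) != object$lookback) {
    abort(sprintf("`recent` must have exactly %d values, got %d",
                  object$lookback, length(recent)))
  }
  rng <- object$range
  x <- matrix((recent - rng[1]) / (rng[2] - rng[1]), 1)
  yhat <- cnn_forward(object$par, object$spec, x)
  as.numeric(yhat) * (rng[2] - rng[1]) + rng[1]
}

#' @rdname predict_horizon
#' @export
predict_horizon.hp_forecaster <- function(object, recent, ...) {
  if (!is.function(object$predict)) {
    abort("plugin forecaster must carry a `predict` function field")
  }
  out <- object$predict(as.numeric(recent))
  if (!is.numeric(out) || any(!is.finite(out))) {
    abort("plugin forecaster returned non-finite values")
  }
  out
}
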