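# Feed-forward 7-10-1 network with log-sigmoid activations, trained by
# online backpropagation with momentum. The training inner loop is compiled
# (src/bpnn.cpp); the R-level gradient and single-step functions implement
# the identical arithmetic and back the finite-difference and equivalence
# tests.

#' Network training configuration
#'
#' Defaults follow the clinical modeling setup: one hidden layer of 10
#' nodes, learning rate 0.005 compensated by 10,000 epochs, momentum 0.15.
#'
#' @param n_inputs,n_hidden,n_outputs layer sizes (output fixed at 1).
#' @param learning_rate gradient step size.
#' @param momentum fraction of the previous update added to the current one,
#'   in `[0, 1)`.
#' @param epochs full passes over the training rows.
#' @param init_scale weights initialized uniformly on
#'   `[-init_scale, init_scale]`.
#' @param seed seed for weight initialization and epoch shuffling.
#' @param batch `TRUE` for full-batch gradient updates instead of online
#'   per-sample updates.
#' @return list of class `nn_config`.
#' @export
nn_config <- function(n_inputs = 7L, n_hidden = 10L, n_outputs = 1L,
                      learning_rate = 0.005, momentum = 0.15,
                      epochs = 10000L, init_scale = 0.5, seed = 1L,
                      batch = FALSE) {
  stopifnot(n_inputs >= 1, n_hidden >= 1, n_outputs == 1,
            learning_rate > 0, momentum >= 0, momentum < 1, epochs >= 1,
            init_scale > 0)
  structure(
    list(n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
         n_outputs = 1L, learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), init_scale = init_scale,
         seed = as.integer(seed), batch = isTRUE(batch)),
    class = "nn_config"
  )
}

#' Initialize a network from its configuration
#'
#' Weights and biases are drawn uniformly on `[-init_scale, init_scale]`
#' from the configuration seed.
#'
#' @param config an [nn_config()].
#' @return list of class `nn_model` with `W1` (`n_hidden x n_inputs`), `b1`,
#'   `W2` (length `n_hidden`), `b2`, `config`; `bounds` and `mse_history`
#'   are filled by [nn_train()].
#' @export
nn_init <- function(config = nn_config()) {
  stopifnot(inherits(config, "nn_config"))
  p <- config$n_inputs
  h <- config$n_hidden
  with_seed(substream_seed(config$seed, 11L), {
    u <- function(k) runif(k, -config$init_scale, config$init_scale)
    structure(
      list(W1 = matrix(u(h * p), h, p), b1 = u(h), W2 = u(h), b2 = u(1),
           config = config, bounds = NULL, mse_history = numeric(0)),
      class = "nn_model"
    )
  })
}

#' Forward pass
#'
#' `h = sigma(W1 x + b1)`, `y = sigma(W2 h + b2)` with
#' `sigma(z) = 1 / (1 + exp(-z))`; output strictly in (0, 1).
#'
#' @param model an `nn_model`.
#' @param x input matrix (rows = samples) or a single input vector, values
#'   expected in `[0, 1]`.
#' @return numeric vector of outputs in (0, 1).
#' @export
nn_forward <- function(model, x) {
  stopifnot(inherits(model, "nn_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$config$n_inputs) stop("input width mismatch")
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(x %*% t(model$W1) + rep(model$b1, each = nrow(x)))
  as.vector(sig(h %*% model$W2 + model$b2))
}

#' Analytic gradients of the half squared error for one sample
#'
#' Chain rule with `sigma'(z) = sigma(z)(1 - sigma(z))` on the loss
#' `E = 0.5 (y - t)^2`. This is the arithmetic the compiled training loop
#' applies; the test suite checks it against central finite differences.
#'
#' @param model an `nn_model`.
#' @param x input vector.
#' @param target scalar target in `[0, 1]`.
#' @return list `W1, b1, W2, b2` of gradients, plus `output`.
#' @export
nn_gradients <- function(model, x, target) {
  sig <- function(z) 1 / (1 + exp(-z))
  hid <- sig(as.vector(model$W1 %*% x) + model$b1)
  yhat <- sig(sum(model$W2 * hid) + model$b2)
  delta2 <- (yhat - target) * yhat * (1 - yhat)
  delta1 <- delta2 * model$W2 * hid * (1 - hid)
  g <- list(W1 = outer(delta1, x), b1 = delta1, W2 = delta2 * hid,
            b2 = delta2, output = yhat)
  if (!all(vapply(g[1:4], function(z) all(is.finite(z)), logical(1)))) {
    stop("non-finite gradient (output = ", yhat, ", target = ", target, ")")
  }
  g
}

#' One online backpropagation update with momentum
#'
#' `dw = -lr * grad + momentum * dw_prev`; `state` carries the previous
#' deltas (zeros when `NULL`).
#'
#' @param model an `nn_model`.
#' @param x input vector; `target` scalar in `[0, 1]`.
#' @param target training target.
#' @param state previous-update deltas as returned in `$state`.
#' @return list `model` (updated) and `state` (new deltas).
#' @export
backprop_step <- function(model, x, target, state = NULL) {
  cfg <- model$config
  if (is.null(state)) {
    state <- list(W1 = model$W1 * 0, b1 = model$b1 * 0, W2 = model$W2 * 0,
                  b2 = 0)
  }
  g <- nn_gradients(model, x, target)
  new_state <- list(
    W1 = -cfg$learning_rate * g$W1 + cfg$momentum * state$W1,
    b1 = -cfg$learning_rate * g$b1 + cfg$momentum * state$b1,
    W2 = -cfg$learning_rate * g$W2 + cfg$momentum * state$W2,
    b2 = -cfg$learning_rate * g$b2 + cfg$momentum * state$b2
  )
  model$W1 <- model$W1 + new_state$W1
  model$b1 <- model$b1 + new_state$b1
  model$W2 <- model$W2 + new_state$W2
  model$b2 <- model$b2 + new_state$b2
  list(model = model, state = new_state)
}

#' Train the network
#'
#' Online (per-sample) stochastic updates with the row order reshuffled
#' every epoch from the configuration seed; momentum buffers persist across
#' samples and epochs. With `config$batch = TRUE`, one full-batch gradient
#' update per epoch is used instead. Identical seed and data give
#' bit-identical weights.
#'
#' @param X numeric matrix of normalized inputs (rows = samples, values in
#'   `[0, 1]`).
#' @param y numeric targets in `[0, 1]`.
#' @param config an [nn_config()].
#' @return a trained `nn_model` with `mse_history` (per-epoch mean squared
#'   error, pre-update predictions).
#' @export
nn_train <- function(X, y, config = nn_config()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1, length(y) == nrow(X), all(is.finite(X)),
            all(is.finite(y)))
  if (ncol(X) != config$n_inputs) stop("input width mismatch")
  model <- nn_init(config)
  if (config$batch) {
    return(nn_train_batch(model, X, y, config))
  }
  order <- with_seed(substream_seed(config$seed, 13L), {
    t(vapply(seq_len(config$epochs), function(e) sample.int(nrow(X)),
             integer(nrow(X))))
  })
  fit <- cpp_bpnn_train(X, as.numeric(y), model$W1, model$b1, model$W2,
                        model$b2, config$learning_rate, config$momentum,
                        order)
  model$W1 <- fit$W1
  model$b1 <- as.vector(fit$b1)
  model$W2 <- as.vector(fit$W2)
  model$b2 <- fit$b2
  model$mse_history <- as.vector(fit$mse)
  model
}

# full-batch variant: mean gradient over all rows, one momentum update per
# epoch (vectorized, no compiled code needed)
nn_train_batch <- function(model, X, y, config) {
  sig <- function(z) 1 / (1 + exp(-z))
  n <- nrow(X)
  prev <- list(W1 = model$W1 * 0, b1 = model$b1 * 0, W2 = model$W2 * 0,
               b2 = 0)
  mse <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    H <- sig(X %*% t(model$W1) + rep(model$b1, each = n))
    yhat <- as.vector(sig(H %*% model$W2 + model$b2))
    err <- yhat - y
    mse[e] <- mean(err^2)
    d2 <- err * yhat * (1 - yhat)
    D1 <- (d2 %o% model$W2) * H * (1 - H)
    g <- list(W1 = t(D1) %*% X / n, b1 = colMeans(D1),
              W2 = as.vector(t(H) %*% d2) / n, b2 = mean(d2))
    prev <- lapply(stats::setNames(names(prev), names(prev)), function(nm) {
      -config$learning_rate * g[[nm]] + config$momentum * prev[[nm]]
    })
    model$W1 <- model$W1 + prev$W1
    model$b1 <- model$b1 + prev$b1
    model$W2 <- model$W2 + prev$W2
    model$b2 <- model$b2 + as.numeric(prev$b2)
  }
  model$mse_history <- mse
  model
}

#' Predict the 0-100 DoA index
#'
#' Denormalizes the network's (0, 1) output to the clinician index scale by
#' multiplying by 100.
#'
#' @param model a trained `nn_model`.
#' @param table normalized feature table (or input matrix).
#' @return numeric DoA index series, strictly inside (0, 100).
#' @export
predict_index <- function(model, table) {
  X <- if (is.data.frame(table)) as.matrix(table[FEATURE_COLUMNS]) else
    as.matrix(table)
  100 * nn_forward(model, X)
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf(
    "log-sigmoid network %d-%d-1 (lr %g, momentum %g, %d epochs%s)\n",
    x$config$n_inputs, x$config$n_hidden, x$config$learning_rate,
    x$config$momentum, x$config$epochs,
    if (length(x$mse_history)) sprintf(", final MSE %.4g",
                                       utils::tail(x$mse_history, 1)) else
      ", untrained"
  ))
  invisible(x)
}

#' Serialize / restore a trained model as JSON
#'
#' @param model a trained `nn_model`; `path` file path.
#' @param path file to write/read.
#' @return `read_model` returns the restored `nn_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    config = unclass(model$config),
    bounds = if (!is.null(model$bounds)) lapply(model$bounds, identity),
    mse_final = if (length(model$mse_history))
      utils::tail(model$mse_history, 1) else NULL
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(nn_config, obj$config[setdiff(names(obj$config), "n_outputs")])
  m <- nn_init(cfg)
  m$W1 <- matrix(as.numeric(obj$W1), cfg$n_hidden, cfg$n_inputs)
  m$b1 <- as.numeric(obj$b1)
  m$W2 <- as.numeric(obj$W2)
  m$b2 <- as.numeric(obj$b2)
  if (!is.null(obj$bounds)) {
    m$bounds <- structure(lapply(obj$bounds, as.numeric),
                          class = "norm_bounds")
  }
  m
}
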