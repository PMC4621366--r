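# Backpropagation network: forward arithmetic, gradients, training
# determinism and learnability.

test_that("forward pass reproduces straight-line matrix arithmetic", {
  m <- nn_init(nn_config(seed = 81))
  set.seed(81)
  x <- runif(7)
  sig <- function(z) 1 / (1 + exp(-z))
  by_hand <- sig(sum(m$W2 * sig(m$W1 %*% x + m$b1)) + m$b2)
  expect_equal(nn_forward(m, x), as.vector(by_hand), tolerance = 1e-12)

  # all-zero parameters: hidden all 0.5 but W2 = 0, so output sigma(0)
  z <- m
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2 <- 0
  expect_equal(nn_forward(z, x), 0.5)

  # sigmoid output strictly inside (0, 1)
  set.seed(82)
  for (k in 1:10) {
    y <- nn_forward(m, runif(7))
    expect_true(y > 0 && y < 1)
  }
  expect_error(nn_forward(m, runif(5)), "width mismatch")
})

test_that("analytic gradients match central finite differences", {
  # 20 random (weights, input, target) triples; epsilon = 1e-6. The
  # comparison is relative to the gradient magnitude with a small floor
  # absorbing finite-difference round-off on near-zero entries.
  set.seed(83)
  for (k in 1:20) {
    m <- nn_init(nn_config(seed = 830 + k))
    x <- runif(7)
    tg <- runif(1)
    g <- nn_gradients(m, x, tg)
    ana <- c(g$W1, g$b1, g$W2, g$b2)
    num <- fd_gradient(m, x, tg, eps = 1e-6)
    rel <- abs(ana - num) / pmax(abs(ana), abs(num), 1e-4)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("single updates behave at the fixed points", {
  m <- nn_init(nn_config(seed = 84))
  x <- runif(7)

  # learning rate ~0 leaves the model numerically unchanged
  m0 <- m
  m0$config$learning_rate <- 1e-300
  r <- backprop_step(m0, x, 0.3)
  expect_equal(r$model$W1, m$W1, tolerance = 1e-12)

  # target equal to the current output: zero gradient, only momentum moves
  y0 <- nn_forward(m, x)
  prev <- list(W1 = m$W1 * 0 + 0.01, b1 = m$b1 * 0, W2 = m$W2 * 0, b2 = 0)
  r2 <- backprop_step(m, x, y0, state = prev)
  expect_equal(r2$model$W1, m$W1 + m$config$momentum * 0.01,
               tolerance = 1e-12)
})

test_that("the compiled training loop equals the R reference updates", {
  set.seed(85)
  X <- matrix(runif(21), 3, 7)
  y <- runif(3)
  cfg <- nn_config(epochs = 3L, momentum = 0.15, seed = 85)
  m <- nn_init(cfg)
  ord <- matrix(rep(1:3, 3), nrow = 3, byrow = TRUE)
  fit <- cpp_bpnn_train(X, y, m$W1, m$b1, m$W2, m$b2, cfg$learning_rate,
                        cfg$momentum, ord)
  ref <- m
  st <- NULL
  for (e in 1:3) {
    for (i in 1:3) {
      r <- backprop_step(ref, X[i, ], y[i], st)
      ref <- r$model
      st <- r$state
    }
  }
  expect_equal(fit$W1, ref$W1, tolerance = 1e-14)
  expect_equal(as.vector(fit$b1), ref$b1, tolerance = 1e-14)
  expect_equal(as.vector(fit$W2), ref$W2, tolerance = 1e-14)
  expect_equal(fit$b2, ref$b2, tolerance = 1e-14)
})

test_that("training is bit-reproducible under the seed", {
  set.seed(86)
  X <- matrix(runif(70), 10, 7)
  y <- runif(10)
  a <- nn_train(X, y, nn_config(epochs = 50L, seed = 9))
  b <- nn_train(X, y, nn_config(epochs = 50L, seed = 9))
  expect_identical(a$W1, b$W1)
  expect_identical(a$mse_history, b$mse_history)
  c <- nn_train(X, y, nn_config(epochs = 50L, seed = 10))
  expect_false(identical(a$W1, c$W1))
})

test_that("an XOR-style toy is learned within the epoch budget", {
  X <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), matrix(0.5, 4, 5))
  y <- c(0.05, 0.95, 0.95, 0.05)
  m <- nn_train(X, y, nn_config(learning_rate = 0.5, momentum = 0.9,
                                epochs = 10000L, seed = 2))
  expect_lt(utils::tail(m$mse_history, 1), 0.01)
})

test_that("epoch MSE trends down on a learnable linear toy", {
  set.seed(87)
  X <- matrix(runif(7 * 40), 40, 7)
  y <- pmin(pmax(0.2 + 0.6 * X[, 1], 0), 1)
  m <- nn_train(X, y, nn_config(epochs = 2000L, seed = 3))
  h <- m$mse_history
  expect_lt(utils::tail(h, 1), h[1])
  expect_lte(mean(diff(utils::tail(h, 100))), 0)  # non-increasing on average
})

test_that("batch mode also trains and is deterministic", {
  set.seed(88)
  X <- matrix(runif(7 * 30), 30, 7)
  y <- pmin(pmax(0.1 + 0.8 * X[, 2], 0), 1)
  cfg <- nn_config(epochs = 3000L, learning_rate = 0.5, seed = 4,
                   batch = TRUE)
  a <- nn_train(X, y, cfg)
  b <- nn_train(X, y, cfg)
  expect_identical(a$W1, b$W1)
  expect_lt(utils::tail(a$mse_history, 1), a$mse_history[1])
})

test_that("predict_index maps the unit output onto the 0-100 scale", {
  m <- nn_init(nn_config(seed = 89))
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2 <- 0
  X <- matrix(runif(14), 2, 7)
  expect_equal(predict_index(m, X), c(50, 50))
  m2 <- nn_init(nn_config(seed = 90))
  idx <- predict_index(m2, X)
  expect_true(all(idx > 0 & idx < 100))
  expect_equal(idx, 100 * nn_forward(m2, X))
})

test_that("models serialize to JSON and back without drift", {
  set.seed(91)
  X <- matrix(runif(70), 10, 7)
  y <- runif(10)
  m <- nn_train(X, y, nn_config(epochs = 20L, seed = 5))
  m$bounds <- fit_normalizer(
    data.frame(sampen = runif(5), emg = runif(5), hr = runif(5),
               pulse = runif(5), sbp = runif(5), dbp = runif(5),
               sqi = runif(5))
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$W1, m$W1, tolerance = 1e-15)
  expect_equal(m2$b2, m$b2, tolerance = 1e-15)
  expect_equal(m2$bounds$hr, m$bounds$hr, tolerance = 1e-15)
  expect_equal(nn_forward(m2, X[1, ]), nn_forward(m, X[1, ]),
               tolerance = 1e-15)
})
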