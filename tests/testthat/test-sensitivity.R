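# Perturbation sensitivity analysis: baseline, sweeps, fold ranking.

mk_norm_table <- function(seed, n = 25) {
  with_seed(seed, {
    tab <- as.data.frame(matrix(runif(n * 7), n, 7))
    names(tab) <- FEATURE_COLUMNS
    tab$time_s <- seq_len(n) * 5
    tab
  })
}

test_that("baseline output is the forward pass at the column means", {
  m <- nn_init(nn_config(seed = 101))
  tab <- mk_norm_table(101)
  expect_equal(baseline_output(m, tab),
               nn_forward(m, colMeans(as.matrix(tab[FEATURE_COLUMNS]))),
               tolerance = 1e-12)

  half <- mk_norm_table(102, n = 4)
  half[FEATURE_COLUMNS] <- 0.5
  expect_equal(baseline_output(m, half), nn_forward(m, rep(0.5, 7)),
               tolerance = 1e-12)
  one_row <- mk_norm_table(103, n = 1)
  expect_equal(baseline_output(m, one_row),
               nn_forward(m, as.numeric(one_row[1, FEATURE_COLUMNS])),
               tolerance = 1e-12)
})

test_that("sweeps cover exactly the 11-point grid deterministically", {
  m <- nn_init(nn_config(seed = 104))
  tab <- mk_norm_table(104)
  s1 <- sweep_input(m, tab, 2)
  expect_equal(s1$grid, seq(0, 1, by = 0.1))
  expect_length(s1$outputs, 11)
  expect_identical(s1, sweep_input(m, tab, "emg"))
  expect_error(sweep_input(m, tab, 9), "7 inputs")
})

test_that("a disconnected input has exactly zero sweep MSE and ranks last", {
  m <- nn_init(nn_config(seed = 105))
  m$W1[, 4] <- 0  # cut all first-layer weights of input 4 (pulse)
  tab <- mk_norm_table(105)
  expect_identical(sweep_input(m, tab, 4)$mse, 0)
  reports <- lapply(1:3, function(f) fold_sensitivity(m, mk_norm_table(f)))
  rep <- rank_inputs(reports)
  expect_equal(rev(rep$ranking)[1], "pulse")
})

test_that("single-hidden-unit sweep matches a closed-form computation", {
  # 1 effective hidden unit, only input 1 connected: the sweep outputs are
  # sigma(w2 * sigma(w1 * g + b1) + b2) on the grid g
  m <- nn_init(nn_config(seed = 106))
  m$W1[] <- 0; m$W2[] <- 0
  m$W1[1, 1] <- 1.7; m$b1[] <- 0; m$b1[1] <- -0.3
  m$W2[1] <- 2.1; m$b2 <- -0.4
  tab <- mk_norm_table(106)
  mu <- colMeans(as.matrix(tab[FEATURE_COLUMNS]))
  sig <- function(z) 1 / (1 + exp(-z))
  g <- seq(0, 1, by = 0.1)
  hidden_rest <- sum(m$W2[-1] * 0.5)  # other units saturate at sigma(0)
  closed <- sig(2.1 * sig(1.7 * g - 0.3) + hidden_rest - 0.4)
  base <- sig(2.1 * sig(1.7 * mu[1] - 0.3) + hidden_rest - 0.4)
  s <- sweep_input(m, tab, 1)
  expect_equal(s$outputs, as.vector(closed), tolerance = 1e-12)
  expect_equal(s$mse, mean((closed - base)^2), tolerance = 1e-12)
})

test_that("sweep MSE is invariant to input processing order", {
  m <- nn_init(nn_config(seed = 107))
  tab <- mk_norm_table(107)
  fwd <- vapply(1:7, function(i) sweep_input(m, tab, i)$mse, numeric(1))
  bwd <- vapply(7:1, function(i) sweep_input(m, tab, i)$mse, numeric(1))
  expect_equal(fwd, rev(bwd), tolerance = 1e-15)
})

test_that("constructed dominance is ranked first in every fold", {
  dominant <- function(seed) {
    m <- nn_init(nn_config(seed = seed))
    m$W1[, -1] <- m$W1[, -1] / 10  # input 1 weights 10x the rest
    m
  }
  reports <- lapply(1:5, function(f)
    fold_sensitivity(dominant(200 + f), mk_norm_table(f)))
  rep <- rank_inputs(reports)
  expect_equal(rep$ranking[1], "sampen")
  expect_true(all(apply(rep$fold_mse, 1, which.max) == 1))
  expect_true(all(rep$p_adjacent >= 0 & rep$p_adjacent <= 1))
})

test_that("identical fold scores tie-break by input order with p ~ 1", {
  flat <- rep(stats::setNames(list(stats::setNames(rep(0.2, 7),
                                                   FEATURE_COLUMNS)), NULL),
              4)
  rep <- rank_inputs(flat)
  expect_equal(rep$ranking, FEATURE_COLUMNS)
  expect_true(all(rep$p_adjacent == 1))
})

test_that("inconsistent fold inputs are rejected", {
  a <- stats::setNames(runif(7), FEATURE_COLUMNS)
  b <- stats::setNames(runif(7), rev(FEATURE_COLUMNS))
  expect_error(rank_inputs(list(a, b)), "inconsistent")
  expect_error(rank_inputs(list(a)), "length")
})

test_that("the t-test alternative runs on the same report", {
  reports <- lapply(1:4, function(f) {
    with_seed(f, stats::setNames(runif(7, 0.1, 0.2) + (7:1) / 50,
                                 FEATURE_COLUMNS))
  })
  rw <- rank_inputs(reports, method = "wilcoxon")
  rt <- rank_inputs(reports, method = "t")
  expect_equal(rw$ranking, rt$ranking)
  expect_false(identical(rw$p_adjacent, rt$p_adjacent))
})
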