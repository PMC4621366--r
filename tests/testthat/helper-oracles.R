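# Independent oracles: deliberately naive re-implementations used to verify
# the optimized code paths.

# Exhaustive O(N^2) sample entropy: double loop over unordered template
# pairs with starts in [1, N - m] for both template lengths.
sampen_brute <- function(x, m = 2L, r_frac = 0.15) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(0)
  tol <- r_frac * s
  n_tpl <- n - m
  B <- 0
  A <- 0
  for (i in 1:(n_tpl - 1)) {
    for (j in (i + 1):n_tpl) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) B <- B + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= tol) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Brute-force match fraction for count_matches (ordered pairs, averaged)
match_fraction_brute <- function(x, m, tol) {
  n <- length(x)
  n_tpl <- n - m
  cnt <- 0
  for (i in 1:n_tpl) {
    for (j in 1:n_tpl) {
      if (i != j &&
          max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        cnt <- cnt + 1
      }
    }
  }
  cnt / (n_tpl * (n_tpl - 1))
}

# Mann-Whitney concordance AUC: probability that a positive (unconscious,
# low index) scores below a negative, ties counted 1/2.
auc_concordance <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p < neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Power of a signal near a target frequency from the raw periodogram
band_power <- function(x, fs, f0, halfwidth = 1) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$spec[abs(sp$freq - f0) <= halfwidth])
}

# Central finite-difference gradient of the half squared error w.r.t. every
# network parameter, flattened in (W1, b1, W2, b2) order.
fd_gradient <- function(model, x, target, eps = 1e-6) {
  loss <- function(m) 0.5 * (nn_forward(m, x) - target)^2
  slots <- c("W1", "b1", "W2", "b2")
  unlist(lapply(slots, function(sl) {
    v <- model[[sl]]
    g <- v
    for (i in seq_along(v)) {
      mp <- model; mp[[sl]][i] <- v[i] + eps
      mn <- model; mn[[sl]][i] <- v[i] - eps
      g[i] <- (loss(mp) - loss(mn)) / (2 * eps)
    }
    g
  }))
}

# Constant-state latent trajectory (bypasses the ramp generator so plateaus
# can be compared directly)
plateau_latent <- function(level, n_windows) {
  structure(data.frame(time_s = seq_len(n_windows) * 5,
                       state = rep(level, n_windows)),
            class = c("latent_trajectory", "data.frame"))
}
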