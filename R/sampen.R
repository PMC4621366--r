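# Sample entropy of short windows.
#
# SampEn(m, r, N) = -ln(A / B) where B is the number of template pairs of
# length m within Chebyshev tolerance r and A the number that still match
# when extended to length m + 1. Self-matches are excluded; both counts run
# over templates i in [1, N - m] so the shared normalization cancels in the
# ratio. Tolerance is r_fraction * SD of the analysed window.

#' Sample entropy configuration
#'
#' @param m embedding (template) dimension, default 2.
#' @param r_fraction tolerance as a fraction of the window standard
#'   deviation, default 0.15.
#' @return list of class `sampen_config`.
#' @export
sampen_config <- function(m = 2L, r_fraction = 0.15) {
  m <- as.integer(m)
  stopifnot(m >= 1, r_fraction > 0, r_fraction < 1)
  structure(list(m = m, r_fraction = r_fraction), class = "sampen_config")
}

#' Fraction of matching template pairs
#'
#' For templates `X_m(i) = (y_i, ..., y_{i+m-1})`, `i` in `[1, N - m]`,
#' counts ordered pairs `j != i` whose Chebyshev distance
#' `max_k |y_{i+k} - y_{j+k}|` is at most `tolerance`, and averages the
#' per-template counts over the `(N - m - 1)` possible partners.
#'
#' @param series numeric vector, length > m.
#' @param m template length.
#' @param tolerance non-negative match tolerance (absolute units).
#' @return matching fraction in `[0, 1]`.
#' @export
count_matches <- function(series, m, tolerance) {
  n <- length(series)
  m <- as.integer(m)
  stopifnot(n > m, tolerance >= 0)
  n_tpl <- n - m
  if (n_tpl < 2) return(0)
  2 * template_match_pairs(series, m, tolerance) / (n_tpl * (n_tpl - 1))
}

# Number of unordered template pairs (i < j, starts in [1, n_tpl]) of
# length `m` within Chebyshev `tolerance`. Vectorized over lags: for lag L
# the Chebyshev distances of all templates are a running max over m
# consecutive absolute differences |y_t - y_{t+L}|.
template_match_pairs <- function(series, m, tolerance, n_tpl = NULL) {
  n <- length(series)
  if (is.null(n_tpl)) n_tpl <- n - m
  stopifnot(n_tpl + m - 1 <= n)
  total <- 0
  for (lag in seq_len(n_tpl - 1)) {
    d <- abs(series[seq_len(n - lag)] - series[(lag + 1):n])
    # running max of window m over d, evaluated at template starts 1..n_tpl-lag
    k <- n_tpl - lag
    cheb <- d[seq_len(k)]
    if (m > 1) {
      for (off in seq_len(m - 1)) cheb <- pmax(cheb, d[seq_len(k) + off])
    }
    total <- total + sum(cheb <= tolerance)
  }
  total
}

#' Sample entropy of a series
#'
#' `SE(m, r, N) = -ln(A^m(r) / B^m(r))` with the tolerance set to
#' `r_fraction` times `SD(series)`. A constant series (SD = 0) returns 0 by
#' convention; when no template pairs match at length `m` (or none extend to
#' `m + 1`) the value is `NA` — an undefined sentinel, not an error — and
#' downstream stages drop the window.
#'
#' @param series finite numeric vector.
#' @param config a [sampen_config()].
#' @return list of class `sampen_result`: `value` (nats, >= 0, or `NA`),
#'   `b_fraction`, `a_fraction`, `tolerance`, `n`.
#' @examples
#' sample_entropy(sin(seq(0, 20, by = 0.1)))$value
#' @export
sample_entropy <- function(series, config = sampen_config()) {
  stopifnot(inherits(config, "sampen_config"))
  if (!all(is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  m <- config$m
  if (n <= m + 1) stop("series too short for the embedding dimension")
  s <- sd(series)
  res <- function(value, a, b) {
    structure(list(value = value, a_fraction = a, b_fraction = b,
                   tolerance = config$r_fraction * s, n = n),
              class = "sampen_result")
  }
  if (s == 0) return(res(0, 1, 1))
  tol <- config$r_fraction * s
  # both template lengths range over starts [1, N - m], so normalization
  # constants cancel in the ratio and raw pair counts can be compared
  n_tpl <- n - m
  denom <- n_tpl * (n_tpl - 1) / 2
  b <- template_match_pairs(series, m, tol, n_tpl = n_tpl)
  a <- template_match_pairs(series, m + 1L, tol, n_tpl = n_tpl)
  if (b == 0 || a == 0) return(res(NA_real_, a / denom, b / denom))
  res(-log(a / b), a / denom, b / denom)
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn = %s (A = %.4g, B = %.4g, r = %.4g, N = %d)\n",
              format(x$value), x$a_fraction, x$b_fraction, x$tolerance, x$n))
  invisible(x)
}

#' Windowed sample entropy at the vital-sign rate
#'
#' Cuts the (typically EMD-filtered) EEG into non-overlapping windows of
#' `window_s` seconds and computes one sample entropy per window, with the
#' tolerance derived from each window's own SD. Windows are timestamped at
#' their end, matching the 0.2 Hz vital-sign sample that closes the window.
#'
#' @param signal numeric vector sampled at `fs` Hz.
#' @param fs sampling rate (default 125 Hz).
#' @param window_s window length in seconds (default 5).
#' @param config a [sampen_config()].
#' @return data.frame with columns `time_s` and `sampen` (`NA` for windows
#'   whose entropy is undefined).
#' @export
windowed_entropy <- function(signal, fs = 125, window_s = 5,
                             config = sampen_config()) {
  wlen <- as.integer(fs * window_s)
  n_win <- length(signal) %/% wlen
  if (n_win == 0) stop("signal shorter than one window")
  if (length(signal) %% wlen != 0) {
    warning(sprintf("dropping trailing partial window (%d samples)",
                    length(signal) %% wlen))
  }
  vals <- vapply(seq_len(n_win), function(w) {
    x <- signal[((w - 1L) * wlen + 1L):(w * wlen)]
    sample_entropy(x, config)$value
  }, numeric(1))
  data.frame(time_s = seq_len(n_win) * window_s, sampen = vals)
}
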