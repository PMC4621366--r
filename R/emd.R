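# Empirical mode decomposition of short EEG windows.
#
# Sifting follows Huang's scheme: cubic-spline envelopes through local
# maxima/minima (mirror-extended at the boundaries), iterate h <- h - mean
# envelope until the Huang SD criterion SD = sum((h_prev - h)^2)/sum(h_prev^2)
# drops below `sd_stop`, capped at `max_sift` iterations. Decomposition stops
# when the residual is monotone or has fewer than 3 extrema.

#' Cubic-spline envelope through extrema with mirror boundary extension
#'
#' Two extrema at each end are reflected about the first/last sample to tame
#' spline end-swing. Requires at least two extrema.
#'
#' @keywords internal
spline_envelope <- function(x, idx) {
  n <- length(x)
  t <- idx
  v <- x[idx]
  k <- length(idx)
  ext <- min(2L, k)
  # mirror about sample 1 and sample n
  tl <- 2 - t[seq_len(ext)]
  vl <- v[seq_len(ext)]
  tr <- 2 * n - t[k - seq_len(ext) + 1L]
  vr <- v[k - seq_len(ext) + 1L]
  tt <- c(rev(tl), t, rev(tr))
  vv <- c(rev(vl), v, rev(vr))
  keep <- !duplicated(tt)
  f <- splinefun(tt[keep], vv[keep], method = "fmm")
  f(seq_len(n))
}

# IMF criterion: interior extrema and zero-crossing counts differ by <= 1
is_imf <- function(h) {
  ex <- local_extrema(h)
  abs(length(ex$maxima) + length(ex$minima) - count_zero_crossings(h)) <= 1
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the mean of the upper and lower cubic-spline
#' envelopes until the Huang SD stopping criterion is met and the result
#' satisfies the IMF criterion (extrema and zero-crossing counts differing
#' by at most one). A signal with too
#' few interior extrema to envelope is returned unchanged as a residual
#' (`imf = NULL`).
#'
#' @param signal numeric vector, length >= 4.
#' @param sd_stop Huang SD stopping threshold (default 0.2).
#' @param max_sift hard cap on sifting iterations (default 100).
#' @return list with `imf` (or `NULL` when the input is a residual) and
#'   `remainder` such that `imf + remainder == signal` exactly.
#' @examples
#' t <- seq(0, 5, length.out = 625)
#' s <- sift_imf(sin(2 * pi * 10 * t))
#' stopifnot(max(abs(s$imf + s$remainder - sin(2 * pi * 10 * t))) == 0)
#' @export
sift_imf <- function(signal, sd_stop = 0.2, max_sift = 100L) {
  stopifnot(is.numeric(signal), length(signal) >= 4)
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  h <- signal
  for (iter in seq_len(max_sift)) {
    ex <- local_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) {
      if (iter == 1L) {
        return(list(imf = NULL, remainder = signal))
      }
      break
    }
    upper <- spline_envelope(h, ex$maxima)
    lower <- spline_envelope(h, ex$minima)
    m <- (upper + lower) / 2
    h_new <- h - m
    sd_crit <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (sd_crit < sd_stop && is_imf(h)) break
  }
  list(imf = h, remainder = signal - h)
}

#' Decompose a signal into intrinsic mode functions plus a residual
#'
#' Iterates [sift_imf()] on successive remainders until the residual is
#' monotone, has fewer than 3 extrema, or `max_imfs` is reached. The
#' components reproduce the input exactly: `rowSums(imfs) + residual ==
#' signal` up to floating-point round-off.
#'
#' @param signal finite numeric vector, length >= 16.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_stop,max_sift sifting controls, see [sift_imf()].
#' @return an object of class `imf_decomposition`: list with `source`,
#'   `imfs` (matrix, one column per IMF, possibly 0 columns), `residual`,
#'   and `n` (IMF count).
#' @export
emd_decompose <- function(signal, max_imfs = 10L, sd_stop = 0.2,
                          max_sift = 100L) {
  stopifnot(is.numeric(signal), length(signal) >= 16)
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  n <- length(signal)
  imfs <- list()
  res <- signal
  for (i in seq_len(max_imfs)) {
    ex <- local_extrema(res)
    if (length(ex$maxima) + length(ex$minima) < 3) break
    s <- sift_imf(res, sd_stop = sd_stop, max_sift = max_sift)
    if (is.null(s$imf)) break
    imfs[[i]] <- s$imf
    res <- s$remainder
  }
  structure(
    list(
      source = signal,
      imfs = if (length(imfs)) do.call(cbind, imfs) else
        matrix(numeric(0), nrow = n, ncol = 0),
      residual = res,
      n = length(imfs)
    ),
    class = "imf_decomposition"
  )
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf(
    "IMF decomposition: %d samples, %d IMFs + residual (recon err %.2e)\n",
    length(x$source), x$n,
    max(abs(rowSums(cbind(x$imfs, x$residual)) - x$source))
  ))
  invisible(x)
}

#' Reconstruct a frequency band from a range of IMFs
#'
#' Sums IMFs `first_imf..last_imf`. With 125 Hz EEG and 5-second windows,
#' IMFs 2-6 carry the 0.8-32 Hz EEG band: dropping IMF 1 removes
#' high-frequency interference (powerline, electrosurgical bursts) and
#' dropping IMFs beyond 6 removes slow drift. When the decomposition has
#' fewer than `first_imf` IMFs the zero signal is returned and flagged;
#' when it has fewer than `last_imf` the available tail is used and flagged
#' as truncated.
#'
#' @param decomp an `imf_decomposition`.
#' @param first_imf,last_imf 1-based inclusive IMF range (default 2..6).
#' @return numeric vector with attribute `flag` (`"ok"`, `"truncated"`, or
#'   `"empty"`).
#' @export
band_reconstruct <- function(decomp, first_imf = 2L, last_imf = 6L) {
  stopifnot(inherits(decomp, "imf_decomposition"))
  if (first_imf > last_imf) stop("first_imf must be <= last_imf")
  n_imfs <- decomp$n
  if (n_imfs < first_imf) {
    out <- numeric(length(decomp$source))
    attr(out, "flag") <- "empty"
    return(out)
  }
  hi <- min(last_imf, n_imfs)
  out <- rowSums(decomp$imfs[, first_imf:hi, drop = FALSE])
  attr(out, "flag") <- if (hi < last_imf) "truncated" else "ok"
  out
}

#' EMD band-filter a long signal window by window
#'
#' Splits the signal into non-overlapping windows of `window_s` seconds
#' (dropping a trailing partial window with a warning), decomposes each
#' window independently, and reconstructs the `first_imf..last_imf` band.
#' Window-wise decomposition matches the per-window entropy cadence of the
#' downstream pipeline.
#'
#' @param signal numeric vector sampled at `fs` Hz.
#' @param fs sampling rate in Hz (default 125).
#' @param window_s window length in seconds (default 5).
#' @inheritParams band_reconstruct
#' @param ... passed to [emd_decompose()].
#' @return numeric vector of length `n_windows * fs * window_s`; attribute
#'   `flags` holds the per-window reconstruction flag.
#' @export
emd_filter_windows <- function(signal, fs = 125, window_s = 5,
                               first_imf = 2L, last_imf = 6L, ...) {
  wlen <- as.integer(fs * window_s)
  n_win <- length(signal) %/% wlen
  if (n_win == 0) stop("signal shorter than one window")
  if (length(signal) %% wlen != 0) {
    warning(sprintf("dropping trailing partial window (%d samples)",
                    length(signal) %% wlen))
  }
  flags <- character(n_win)
  out <- numeric(n_win * wlen)
  for (w in seq_len(n_win)) {
    i <- ((w - 1L) * wlen + 1L):(w * wlen)
    d <- emd_decompose(signal[i], ...)
    r <- band_reconstruct(d, first_imf, last_imf)
    flags[w] <- attr(r, "flag")
    out[i] <- r
  }
  attr(out, "flags") <- flags
  out
}
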