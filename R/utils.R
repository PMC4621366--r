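# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' Expands one master seed into independent per-stream seeds so that adding
#' or reordering random streams (EEG, each vital channel, each rater) does
#' not perturb the others.
#'
#' @param seed master integer seed.
#' @param stream_id integer offset identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stream_id) {
  # Affine hash mod the Mersenne prime 2^31 - 1; distinct streams decorrelate
  # under R's default RNG seeding.
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(stream_id) * 16807 + 12345
  as.integer(s %% m)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so library
#' code never clobbers the caller's RNG state.
#'
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rms <- function(x) sqrt(mean(x^2))

#' Indices of interior local maxima / minima
#'
#' Plateaus of equal samples contribute a single extremum at their centre.
#'
#' @param x numeric vector.
#' @return list with integer index vectors `maxima` and `minima`.
#' @keywords internal
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  dx <- diff(x)
  # collapse exact ties so flat tops register once
  nz <- which(dx != 0)
  if (length(nz) < 2) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(dx[nz])
  turn <- which(diff(s) != 0)
  idx <- integer(length(turn))
  kind <- s[turn] # +1 then -1 => maximum
  for (k in seq_along(turn)) {
    a <- nz[turn[k]] + 1L       # last point of the rising/falling run
    b <- nz[turn[k] + 1L]       # first point of the next run
    idx[k] <- as.integer(floor((a + b) / 2))
  }
  list(maxima = idx[kind > 0], minima = idx[kind < 0])
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}
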