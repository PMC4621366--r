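# Feature-table construction: align the 0.2 Hz entropy series with the
# vital signs and the averaged rater score, then min-max normalize to [0,1]
# for the log-sigmoid network.

FEATURE_COLUMNS <- c("sampen", "emg", "hr", "pulse", "sbp", "dbp", "sqi")

#' Average rater scores into a single target series
#'
#' @param rater_scores data.frame with `time_s` and one column per rater.
#' @return data.frame `time_s, target` (arithmetic mean per timestamp).
#' @export
average_raters <- function(rater_scores) {
  rater_cols <- setdiff(names(rater_scores), "time_s")
  if (length(rater_cols) < 1) stop("no rater columns")
  data.frame(
    time_s = rater_scores$time_s,
    target = rowMeans(rater_scores[rater_cols])
  )
}

#' Merge entropy, vitals and target onto one 0.2 Hz grid
#'
#' Inner-joins the three tables on `time_s`; rows carrying a missing value
#' in any column (e.g. an undefined-entropy window) are dropped and counted.
#'
#' @param entropy_series data.frame `time_s, sampen` from
#'   [windowed_entropy()].
#' @param vitals data.frame `time_s, emg, hr, pulse, sbp, dbp, sqi`.
#' @param rater_scores data.frame `time_s, r1, ...` (any number of raters).
#' @return data.frame `time_s, sampen, emg, hr, pulse, sbp, dbp, sqi,
#'   target`, strictly increasing in time, with attribute `n_dropped`.
#' @export
align_and_merge <- function(entropy_series, vitals, rater_scores) {
  target <- average_raters(rater_scores)
  tab <- merge(entropy_series, vitals, by = "time_s")
  tab <- merge(tab, target, by = "time_s")
  if (nrow(tab) == 0) stop("no common timestamps across inputs")
  tab <- tab[order(tab$time_s), c("time_s", FEATURE_COLUMNS, "target")]
  complete <- stats::complete.cases(tab) & apply(is.finite(as.matrix(
    tab[, -1])), 1, all)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("align_and_merge: dropped %d incomplete row(s)",
                    n_dropped))
  }
  tab <- tab[complete, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Fit per-column min-max normalization bounds
#'
#' Bounds are fitted on training rows only and reused for validation/test
#' data. Degenerate (constant) columns are flagged; they map to 0.5 on
#' application.
#'
#' @param table feature table with the seven input columns.
#' @param columns columns to normalize (default the seven inputs).
#' @return list of class `norm_bounds`: per-column `c(min, max)`.
#' @export
fit_normalizer <- function(table, columns = FEATURE_COLUMNS) {
  stopifnot(all(columns %in% names(table)), nrow(table) >= 1)
  bounds <- lapply(columns, function(cn) range(table[[cn]]))
  names(bounds) <- columns
  degenerate <- vapply(bounds, function(b) b[1] == b[2], logical(1))
  if (any(degenerate)) {
    warning("constant feature column(s): ",
            paste(columns[degenerate], collapse = ", "),
            " (will normalize to 0.5)")
  }
  structure(bounds, class = "norm_bounds")
}

#' Apply (or invert) min-max normalization
#'
#' `x' = (x - min) / (max - min)`, clipped to `[0, 1]` so out-of-range
#' test-time values saturate rather than extrapolate (the log-sigmoid
#' saturates anyway). The target column is mapped by the fixed index scale
#' `/ 100`. Constant training columns map to 0.5.
#'
#' @param table feature table (with or without a `target` column).
#' @param bounds a [fit_normalizer()] result.
#' @return table with normalized input columns (and `target` in `[0, 1]`
#'   when present).
#' @export
apply_normalizer <- function(table, bounds) {
  stopifnot(inherits(bounds, "norm_bounds"))
  out <- table
  for (cn in names(bounds)) {
    b <- bounds[[cn]]
    out[[cn]] <- if (b[1] == b[2]) rep(0.5, nrow(table)) else
      clip((table[[cn]] - b[1]) / (b[2] - b[1]), 0, 1)
  }
  if ("target" %in% names(out)) out$target <- clip(out$target / 100, 0, 1)
  out
}

#' Invert normalization for the input columns
#'
#' Round-trips with [apply_normalizer()] for in-range, non-degenerate
#' columns.
#'
#' @inheritParams apply_normalizer
#' @export
denormalize <- function(table, bounds) {
  stopifnot(inherits(bounds, "norm_bounds"))
  out <- table
  for (cn in names(bounds)) {
    b <- bounds[[cn]]
    if (b[1] != b[2]) out[[cn]] <- table[[cn]] * (b[2] - b[1]) + b[1]
  }
  if ("target" %in% names(out)) out$target <- table$target * 100
  out
}

#' Build the full feature table for one patient
#'
#' Runs the signal path end to end: window-wise EMD band filtering of the
#' EEG (IMFs 2-6), windowed sample entropy, and alignment with vitals and
#' the averaged rater score. Returns the unnormalized table; normalization
#' bounds are fitted later on training patients only.
#'
#' @param patient a `synthetic_patient`, or any list with elements `eeg`
#'   (125 Hz numeric), `vitals` and `raters` (0.2 Hz data.frames).
#' @param config a [sampen_config()].
#' @param fs,window_s EEG sampling rate and window length.
#' @return unnormalized feature table (see [align_and_merge()]).
#' @export
build_feature_table <- function(patient, config = sampen_config(),
                                fs = 125, window_s = 5) {
  filtered <- emd_filter_windows(patient$eeg, fs = fs, window_s = window_s)
  ent <- windowed_entropy(filtered, fs = fs, window_s = window_s,
                          config = config)
  align_and_merge(ent, patient$vitals, patient$raters)
}
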