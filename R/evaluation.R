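# Performance metrics: MAE +/- SD, per-patient Pearson correlation, and
# ROC/AUC at consciousness thresholds. Throughout, SD is the sample SD
# (n - 1 denominator).

#' Mean absolute error with its standard deviation
#'
#' @param pred,ref equal-length numeric vectors.
#' @return named vector `c(mae, sd)`: mean and sample SD of
#'   `abs(pred - ref)`.
#' @export
mae <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  stopifnot(length(pred) >= 1)
  e <- abs(pred - ref)
  c(mae = mean(e), sd = if (length(e) > 1) sd(e) else 0)
}

#' Pearson correlation between a predicted index and a reference
#'
#' Computed per patient; a constant input yields the undefined sentinel
#' `NA` rather than an error.
#'
#' @param pred,ref numeric vectors, length >= 3.
#' @return Pearson r, or `NA` for constant inputs.
#' @export
per_patient_correlation <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  stopifnot(length(pred) >= 3)
  if (sd(pred) == 0 || sd(ref) == 0) return(NA_real_)
  cor(pred, ref)
}

#' ROC curve and AUC for unconscious-state detection
#'
#' The positive class is "unconscious": reference index at or below
#' `threshold`. Low predicted scores indicate the positive class, so the
#' decision rule is `score <= cutoff`; the curve sweeps the cutoff over all
#' observed score values and the AUC is the trapezoid area. Equivalently
#' (and checked in the test suite) the AUC is the Mann-Whitney concordance
#' probability that a positive scores below a negative, ties counted 1/2.
#'
#' @param scores predicted DoA index (lower = deeper).
#' @param labels logical/0-1 vector, `TRUE` = unconscious; alternatively
#'   supply `ref` and `threshold` to derive labels.
#' @param ref reference index used to derive labels when `labels` is
#'   missing.
#' @param threshold consciousness cut (default 48.8, a published mean BIS
#'   value separating consciousness levels).
#' @param flip set `TRUE` to score the conscious class instead.
#' @return list of class `roc_result`: `auc`, `curve` (data.frame `cutoff,
#'   fpr, tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels = NULL, ref = NULL, threshold = 48.8,
                    flip = FALSE) {
  if (is.null(labels)) {
    if (is.null(ref)) stop("supply labels or ref")
    labels <- ref <= threshold
  }
  labels <- as.logical(labels)
  if (flip) labels <- !labels
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  # positives score LOW: sweep cutoff upward, predict positive if score <= c
  cuts <- c(-Inf, sort(unique(scores)), Inf)
  tpr <- vapply(cuts, function(cc) sum(scores[labels] <= cc) / n_pos,
                numeric(1))
  fpr <- vapply(cuts, function(cc) sum(scores[!labels] <= cc) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(auc = auc,
         curve = data.frame(cutoff = cuts, fpr = fpr, tpr = tpr),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Consciousness thresholds from training targets
#'
#' `mean + k * SD` of the training-set reference index for each multiplier
#' `k`, clipped to `(0, 100)`. With `k = 2` this reproduces the
#' highest-threshold scheme used to separate conscious from unconscious
#' states.
#'
#' @param training_targets numeric vector of reference index values,
#'   length >= 2 and non-constant.
#' @param multipliers SD multipliers (default `c(1, 1.5, 2)`).
#' @return named numeric vector of thresholds.
#' @export
derive_thresholds <- function(training_targets, multipliers = c(1, 1.5, 2)) {
  stopifnot(length(training_targets) >= 2)
  if (sd(training_targets) == 0) stop("constant training targets")
  th <- mean(training_targets) + multipliers * sd(training_targets)
  stats::setNames(clip(th, 1e-9, 100 - 1e-9),
                  paste0("k", multipliers))
}

#' Published per-fold test MAE of the clinical cross-validation
#'
#' The clinical study behind this index design reported, for each of the
#' ten cross-validation fold models evaluated on a fixed 46-patient test
#' set, the mean absolute error against the averaged clinician index.
#' These printed values are inputs for aggregate checks; they are not
#' computed by this package.
#'
#' @return data.frame `fold, mae, sd` with ten rows.
#' @export
clinical_fold_mae <- function() {
  data.frame(
    fold = 1:10,
    mae = c(6.45, 6.6, 6.56, 6.79, 6.64, 6.51, 6.58, 6.94, 6.59, 6.5),
    sd = c(6.61, 6.68, 6.59, 6.89, 6.75, 6.68, 6.70, 6.69, 6.69, 6.8)
  )
}

#' Aggregate per-fold MAE values into a cohort summary
#'
#' @param fold_mae numeric vector of per-fold MAE values.
#' @return named vector `c(mean, sd)` (sample SD).
#' @export
aggregate_fold_mae <- function(fold_mae) {
  stopifnot(length(fold_mae) >= 2)
  c(mean = mean(fold_mae), sd = sd(fold_mae))
}
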