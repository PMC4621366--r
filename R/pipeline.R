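# Patient-level 10-fold cross-validation and fold ensembling.
#
# Splits are by patient, never by row: rows within a patient are strongly
# autocorrelated and row-level splits would leak. Normalization bounds are
# fitted per fold on that fold's training patients; the ensemble shares one
# set of bounds fitted on all modeling patients pooled.

#' Assign patients to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment; fold sizes differ by
#' at most one patient and every patient lands in exactly one fold.
#'
#' @param patient_ids character vector of patient identifiers.
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @return list of class `fold_plan`: `assignments` (named integer vector),
#'   `k`, `seed`.
#' @export
make_folds <- function(patient_ids, k = 10L, seed = 1L) {
  n <- length(patient_ids)
  if (n < k) stop("fewer patients than folds")
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  shuffled <- with_seed(substream_seed(seed, 21L), sample(patient_ids))
  folds <- rep_len(seq_len(k), n)
  structure(
    list(assignments = stats::setNames(folds[order(match(patient_ids,
                                                         shuffled))],
                                       patient_ids),
         k = as.integer(k), seed = as.integer(seed)),
    class = "fold_plan"
  )
}

#' Patient-level k-fold cross-validation of the DoA network
#'
#' For each fold `f`: pool the feature-table rows of all patients outside
#' `f`, fit normalization bounds on them, train one network, and measure
#' the mean squared error (normalized scale) on the held-out fold-`f`
#' patients. Validation patients are never seen by that fold's model or its
#' normalizer.
#'
#' @param tables_by_patient named list of unnormalized feature tables (see
#'   [build_feature_table()]).
#' @param plan a [make_folds()] plan over `names(tables_by_patient)`.
#' @param config an [nn_config()]; fold `f` trains with seed
#'   `config$seed + f` so members differ.
#' @return list of class `cv_result`: `models`, `bounds` (per fold),
#'   `val_mse`, `val_predictions` (per fold, denormalized 0-100 index with
#'   targets), `plan`, `config`.
#' @export
cross_validate <- function(tables_by_patient, plan, config = nn_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- names(tables_by_patient)
  if (!setequal(ids, names(plan$assignments))) {
    stop("plan does not cover the supplied patients")
  }
  models <- vector("list", plan$k)
  bounds_l <- vector("list", plan$k)
  val_mse <- numeric(plan$k)
  val_pred <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    val_ids <- ids[plan$assignments[ids] == f]
    train_ids <- setdiff(ids, val_ids)
    if (length(val_ids) == 0) stop("empty fold ", f)
    train_tab <- do.call(rbind, tables_by_patient[train_ids])
    val_tab <- do.call(rbind, tables_by_patient[val_ids])
    bounds <- fit_normalizer(train_tab)
    tr <- apply_normalizer(train_tab, bounds)
    va <- apply_normalizer(val_tab, bounds)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- nn_train(as.matrix(tr[FEATURE_COLUMNS]), tr$target, cfg)
    model$bounds <- bounds
    yhat <- nn_forward(model, as.matrix(va[FEATURE_COLUMNS]))
    models[[f]] <- model
    bounds_l[[f]] <- bounds
    val_mse[f] <- mean((yhat - va$target)^2)
    val_pred[[f]] <- data.frame(patient = rep(val_ids,
                                              vapply(tables_by_patient[val_ids],
                                                     nrow, integer(1))),
                                time_s = val_tab$time_s,
                                index = 100 * yhat,
                                target = val_tab$target * 100)
  }
  structure(
    list(models = models, bounds = bounds_l, val_mse = val_mse,
         val_predictions = val_pred, plan = plan, config = config),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d patients: validation MSE %.4g +/- %.4g\n",
              x$plan$k, length(x$plan$assignments), mean(x$val_mse),
              sd(x$val_mse)))
  invisible(x)
}

#' Build the fold ensemble
#'
#' Collects the k fold models behind one set of normalization bounds fitted
#' on all modeling patients pooled, so the ensemble can score unseen test
#' patients.
#'
#' @param cv a [cross_validate()] result.
#' @param tables_by_patient the modeling-cohort feature tables used to fit
#'   the shared bounds.
#' @return list of class `doa_ensemble`: `models`, `bounds`, `config`.
#' @export
build_ensemble <- function(cv, tables_by_patient) {
  stopifnot(inherits(cv, "cv_result"))
  pooled <- do.call(rbind, tables_by_patient)
  structure(
    list(models = cv$models, bounds = fit_normalizer(pooled),
         config = cv$config),
    class = "doa_ensemble"
  )
}

#' Ensemble DoA prediction
#'
#' Normalizes the table with the ensemble's shared bounds and averages the
#' member predictions row-wise. The ensemble mean is bounded by the member
#' minimum and maximum pointwise.
#'
#' @param ensemble a [build_ensemble()] result.
#' @param table unnormalized feature table of the patient to score.
#' @return numeric 0-100 DoA index series.
#' @export
ensemble_predict <- function(ensemble, table) {
  stopifnot(inherits(ensemble, "doa_ensemble"))
  norm <- apply_normalizer(table, ensemble$bounds)
  X <- as.matrix(norm[FEATURE_COLUMNS])
  preds <- vapply(ensemble$models, function(m) {
    if (m$config$n_inputs != ncol(X)) stop("member shape mismatch")
    predict_index(m, X)
  }, numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Run the whole pipeline on a synthetic cohort
#'
#' Feature extraction (EMD filter, windowed entropy, vitals merge) for each
#' patient, fold planning, cross-validation, and ensembling, all under one
#' master seed.
#'
#' @param cohort named list of `synthetic_patient`s (or lists with `eeg`,
#'   `vitals`, `raters`).
#' @param k folds.
#' @param config an [nn_config()].
#' @param seed master seed for the fold plan.
#' @return list: `tables` (per patient), `plan`, `cv`, `ensemble`.
#' @export
run_doa_pipeline <- function(cohort, k = 10L, config = nn_config(),
                             seed = 1L) {
  tables <- lapply(cohort, build_feature_table)
  plan <- make_folds(names(cohort), k = k, seed = seed)
  cv <- cross_validate(tables, plan, config)
  list(tables = tables, plan = plan, cv = cv,
       ensemble = build_ensemble(cv, tables))
}
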