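# Perturbation sensitivity analysis: hold every input at its mean, sweep
# one input over [0, 1] in 0.1 steps, and score each input by the MSE of
# the swept outputs against the all-means baseline output. The larger the
# MSE, the more the network's output depends on that input.

SWEEP_GRID <- seq(0, 1, by = 0.1)

#' Baseline network output at the input means
#'
#' @param model a trained `nn_model`.
#' @param table normalized feature table (columns in `[0, 1]`).
#' @return scalar network output at the vector of column means.
#' @export
baseline_output <- function(model, table) {
  stopifnot(nrow(table) >= 1)
  nn_forward(model, colMeans(as.matrix(table[FEATURE_COLUMNS])))
}

#' Sweep one input over the unit interval and score its influence
#'
#' All inputs sit at their column means except `input_index`, which takes
#' the values 0.0, 0.1, ..., 1.0. The influence score is the MSE of the 11
#' outputs against the baseline (all-means) output.
#'
#' @param model a trained `nn_model`.
#' @param table normalized feature table.
#' @param input_index input position in 1..7 (order: sampen, emg, hr,
#'   pulse, sbp, dbp, sqi) or an input name.
#' @return list: `input`, `grid`, `outputs` (11 values), `mse`.
#' @export
sweep_input <- function(model, table, input_index) {
  if (is.character(input_index)) {
    input_index <- match(input_index, FEATURE_COLUMNS)
  }
  if (is.na(input_index) || input_index < 1 ||
      input_index > length(FEATURE_COLUMNS)) {
    stop("input_index must identify one of the 7 inputs")
  }
  mu <- colMeans(as.matrix(table[FEATURE_COLUMNS]))
  base <- nn_forward(model, mu)
  X <- matrix(rep(mu, each = length(SWEEP_GRID)), nrow = length(SWEEP_GRID))
  X[, input_index] <- SWEEP_GRID
  outputs <- nn_forward(model, X)
  list(input = FEATURE_COLUMNS[input_index], grid = SWEEP_GRID,
       outputs = outputs, mse = mean((outputs - base)^2))
}

#' Sensitivity scores of all inputs for one fold model
#'
#' @param model a trained `nn_model`.
#' @param table normalized feature table used as the operating point.
#' @return named numeric vector of per-input sweep MSEs.
#' @export
fold_sensitivity <- function(model, table) {
  vapply(seq_along(FEATURE_COLUMNS),
         function(i) sweep_input(model, table, i)$mse,
         numeric(1)) |>
    stats::setNames(FEATURE_COLUMNS)
}

#' Rank the inputs by fold-averaged sensitivity
#'
#' Averages the per-fold sweep MSEs, sorts descending (rank 1 = most
#' sensitive; ties broken by the fixed input order sampen, emg, hr, pulse,
#' sbp, dbp, sqi), and tests each adjacent pair of ranks on the fold-wise
#' MSE values with a paired two-sided test.
#'
#' @param reports_by_fold list of named per-input MSE vectors, one per fold
#'   (>= 2 folds), e.g. from [fold_sensitivity()].
#' @param method `"wilcoxon"` (signed-rank, default) or `"t"` (paired t).
#' @param alpha significance level recorded in the report (default 0.05).
#' @return list of class `sensitivity_report`: `fold_mse` (folds x inputs
#'   matrix), `mean_mse`, `ranking` (input names, most sensitive first),
#'   `p_adjacent` (named p-values between consecutive ranks), `alpha`,
#'   `method`.
#' @export
rank_inputs <- function(reports_by_fold, method = c("wilcoxon", "t"),
                        alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(reports_by_fold) >= 2)
  nms <- names(reports_by_fold[[1]])
  if (!all(vapply(reports_by_fold,
                  function(r) identical(names(r), nms), logical(1)))) {
    stop("inconsistent input sets across folds")
  }
  fold_mse <- do.call(rbind, reports_by_fold)
  mean_mse <- colMeans(fold_mse)
  ord <- order(-mean_mse, match(nms, FEATURE_COLUMNS))
  ranking <- nms[ord]
  p_adjacent <- numeric(length(ranking) - 1)
  for (i in seq_along(p_adjacent)) {
    a <- fold_mse[, ranking[i]]
    b <- fold_mse[, ranking[i + 1]]
    p_adjacent[i] <- if (all(a == b)) 1 else if (method == "wilcoxon") {
      suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
    } else {
      t.test(a, b, paired = TRUE)$p.value
    }
  }
  names(p_adjacent) <- paste(ranking[-length(ranking)], "vs",
                             ranking[-1])
  structure(
    list(fold_mse = fold_mse, mean_mse = mean_mse, ranking = ranking,
         p_adjacent = p_adjacent, alpha = alpha, method = method),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Input sensitivity ranking (fold-averaged sweep MSE):\n")
  for (i in seq_along(x$ranking)) {
    nm <- x$ranking[i]
    p <- if (i < length(x$ranking))
      sprintf("  p(vs next) = %.3g", x$p_adjacent[i]) else ""
    cat(sprintf("  %d. %-7s MSE = %.4g%s\n", i, nm, x$mean_mse[nm], p))
  }
  invisible(x)
}

#' Per-fold sensitivity over a cross-validation result
#'
#' Convenience wrapper: for each fold, scores the inputs with that fold's
#' model at the operating point of its own (normalized) training patients,
#' then ranks.
#'
#' @param cv a [cross_validate()] result.
#' @param tables_by_patient the modeling-cohort feature tables.
#' @inheritParams rank_inputs
#' @return a `sensitivity_report`.
#' @export
cv_sensitivity <- function(cv, tables_by_patient,
                           method = c("wilcoxon", "t")) {
  stopifnot(inherits(cv, "cv_result"))
  ids <- names(tables_by_patient)
  reports <- lapply(seq_len(cv$plan$k), function(f) {
    train_ids <- ids[cv$plan$assignments[ids] != f]
    tab <- apply_normalizer(do.call(rbind, tables_by_patient[train_ids]),
                            cv$bounds[[f]])
    fold_sensitivity(cv$models[[f]], tab)
  })
  rank_inputs(reports, method = method)
}
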