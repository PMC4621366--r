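# One shared end-to-end run of the reduced pipeline (10 modeling patients
# with a dominant EMG channel, 500 training epochs, 5 held-out test
# patients), computed lazily and cached so several test files can assert
# against the same run.

.doa_cache <- new.env(parent = emptyenv())

reduced_pipeline_run <- function() {
  if (!is.null(.doa_cache$run)) return(.doa_cache$run)
  cohort <- generate_cohort(10, duration_s = 500, seed = 100)
  run <- run_doa_pipeline(cohort, k = 10,
                          config = nn_config(epochs = 500L, seed = 1),
                          seed = 1)
  sens <- cv_sensitivity(run$cv, run$tables)

  test_cohort <- generate_cohort(5, duration_s = 500, seed = 900)
  train_target_mean <- mean(unlist(lapply(run$tables,
                                          function(t) t$target)))
  test_eval <- lapply(test_cohort, function(p) {
    tab <- build_feature_table(p)
    pred <- ensemble_predict(run$ensemble, tab)
    lat <- p$latent$state[match(tab$time_s, p$latent$time_s)]
    list(
      pred = pred, latent = lat,
      mae = mae(pred, lat)[["mae"]],
      const_mae = mae(rep(train_target_mean, length(lat)), lat)[["mae"]],
      r = per_patient_correlation(pred, lat)
    )
  })
  .doa_cache$run <- list(cohort = cohort, run = run, sens = sens,
                         test_eval = test_eval)
  .doa_cache$run
}
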