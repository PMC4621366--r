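# doaindex

Depth-of-anesthesia (DoA) estimation from a raw single-channel EEG and
routine operating-room vital signs.

During general anesthesia, clinicians track a patient's consciousness on a
0–100 index (100 = fully awake). Commercial EEG monitors such as the
bispectral index are opaque and degrade under electrosurgical interference.
`doaindex` implements an open alternative built from three ingredients:

1. **EMD-filtered EEG irregularity.** Each 5-second window (625 samples at
   125 Hz) is decomposed by empirical mode decomposition; summing intrinsic
   mode functions (IMFs) 2–6 reconstructs the 0.8–32 Hz EEG band, stripping
   high-frequency interference and slow drift. The filtered window is
   summarized by its sample entropy

   *SE(m, r, N) = −ln( Aᵐ(r) / Bᵐ(r) )*,  m = 2, r = 0.15·SD,

   where *Bᵐ* counts template pairs of length *m* within Chebyshev
   tolerance *r* and *Aᵐ* those still matching at length *m + 1*
   (self-matches excluded). Entropy falls as consciousness falls: deep
   anesthesia produces quasi-periodic slow waves, wakefulness an irregular
   broadband signal.
2. **Vital-sign fusion.** The 0.2 Hz entropy series is merged with EMG,
   heart rate, pulse, systolic/diastolic blood pressure and signal quality
   index, min–max normalized, and regressed onto an averaged multi-rater
   clinician consciousness score by a 7–10–1 log-sigmoid network trained
   with online backpropagation and momentum (η = 0.005, α = 0.15, 10,000
   epochs by default; fully seeded and bit-reproducible).
3. **Patient-level 10-fold cross-validation** with fold ensembling,
   perturbation sensitivity ranking of the seven inputs, and MAE /
   per-patient Pearson correlation / ROC-AUC evaluation at consciousness
   thresholds.

A seeded synthetic-patient generator (latent consciousness trajectory →
EEG, six vitals with configurable gains, five noisy raters, optional
electrosurgical-style bursts) provides ground truth for every stage, so the
whole pipeline is testable without clinical recordings.

## Worked example

```r
library(doaindex)

# one synthetic case: 300 s spanning induction -> maintenance -> emergence
patient <- generate_patient(duration_s = 300, seed = 42)
patient
#> Synthetic patient (seed 42): 60 windows (300 s), 5 raters

# EEG -> EMD filter -> windowed sample entropy -> merge with vitals/raters
features <- build_feature_table(patient)
head(features, 3)
#>   time_s    sampen      emg       hr    pulse      sbp      dbp      sqi   target
#> 1      5 0.7173340 79.74904 69.56327 68.49407 105.1552 67.57735 88.36918 88.62321
#> 2     10 0.7673894 77.64956 70.20528 69.37176 105.5186 66.18635 90.12711 88.17050
#> 3     15 0.7810465 77.63263 71.91969 67.54431 103.2029 66.81598 91.32771 87.37329

# patient-level cross-validation and fold ensemble (reduced size for speed)
cohort <- generate_cohort(6, duration_s = 300, seed = 7)
run <- run_doa_pipeline(cohort, k = 3,
                        config = nn_config(epochs = 300L, seed = 7), seed = 7)
run$cv
#> 3-fold CV over 6 patients: validation MSE 0.009345 +/- 0.001394

# score an unseen patient against its latent consciousness state
test_patient <- generate_patient(duration_s = 300, seed = 99)
tab <- build_feature_table(test_patient)
index <- ensemble_predict(run$ensemble, tab)
latent <- test_patient$latent$state[match(tab$time_s,
                                          test_patient$latent$time_s)]
round(mae(index, latent), 2)
#>   mae    sd
#> 10.05  4.22
round(per_patient_correlation(index, latent), 3)
#> [1] 0.987
roc_auc(index, ref = latent, threshold = 48.8)
#> ROC: AUC = 1.0000 (25 positive, 35 negative)

# which input drives the model? (EMG is the designed dominant channel)
cv_sensitivity(run$cv, run$tables)
#> Input sensitivity ranking (fold-averaged sweep MSE):
#>   1. emg     MSE = 0.01859  p(vs next) = 0.25
#>   2. sampen  MSE = 0.005954  p(vs next) = 0.25
#>   3. hr      MSE = 0.00119  p(vs next) = 0.75
#>   ...
```

The index tracks the latent state closely (r ≈ 0.99), separates conscious
from unconscious windows perfectly at the 48.8 threshold on this toy run,
and the sensitivity sweep recovers EMG — generated with a gain 16× the
other vitals — as the most influential input, with the EEG entropy second.

A thin command-line front end over the same functions lives in
`inst/cli/doa.R` (`synth`, `features`, `crossval`, `evaluate` subcommands).

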