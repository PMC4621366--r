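# Synthetic-patient generator: bounds, determinism, designed correlations.

test_that("latent trajectory has awake and anesthetized phases within bounds", {
  lat <- generate_trajectory(500, seed = 1)
  expect_s3_class(lat, "latent_trajectory")
  expect_equal(nrow(lat), 100)
  expect_true(all(lat$state >= 0 & lat$state <= 100))
  expect_gte(lat$state[1], 80)          # starts awake
  expect_lte(min(lat$state), 40)        # reaches anesthetized depth
  expect_gte(lat$state[nrow(lat)], 60)  # emergence ramp back up

  short <- generate_trajectory(50, seed = 7)
  expect_equal(nrow(short), 10)
  expect_true(all(short$state >= 0 & short$state <= 100))

  expect_error(generate_trajectory(40, seed = 1), "at least 50")
})

test_that("generators are bit-identical under the same seed", {
  p1 <- generate_patient(100, seed = 12)
  p2 <- generate_patient(100, seed = 12)
  expect_identical(p1, p2)
  p3 <- generate_patient(100, seed = 13)
  expect_false(identical(p1$eeg, p3$eeg))
})

test_that("EEG irregularity increases with the latent consciousness level", {
  # mean windowed sample entropy over plateaus must be strictly ordered
  se_at <- function(level) {
    eeg <- generate_eeg(plateau_latent(level, 30), seed = 11)
    mean(windowed_entropy(emd_filter_windows(eeg))$sampen, na.rm = TRUE)
  }
  se <- vapply(c(10, 50, 90), se_at, numeric(1))
  expect_true(all(diff(se) > 0))
})

test_that("EEG stays finite-amplitude at the latent floor", {
  eeg <- generate_eeg(plateau_latent(0, 5), seed = 2)
  expect_true(all(is.finite(eeg)))
  expect_gt(sd(eeg), 0)
  # noise floor: even at state 0 the signal is not a pure tone
  expect_gt(sample_entropy(eeg[1:625])$value, 0.05)
})

test_that("vitals follow the designed gains and clip to physiology", {
  lat <- generate_trajectory(500, seed = 4)
  v <- generate_vitals(lat, seed = 5, effect_profile())
  cors <- vapply(c("emg", "hr", "pulse", "sbp", "dbp", "sqi"),
                 function(ch) abs(cor(v[[ch]], lat$state)), numeric(1))
  expect_equal(names(which.max(cors)), "emg")

  # all-zero gains: channels decorrelated from the state
  v0 <- generate_vitals(lat, seed = 5,
                        effect_profile(dominant = NULL, other_gain = 0))
  cors0 <- vapply(c("emg", "hr", "pulse", "sbp", "dbp", "sqi"),
                  function(ch) abs(cor(v0[[ch]], lat$state)), numeric(1))
  expect_true(all(cors0 < 0.3))

  # gain driving HR past its ceiling saturates at 180 bpm
  v_hi <- generate_vitals(lat, seed = 6,
                          effect_profile(dominant = "hr",
                                         dominant_gain = 5))
  expect_equal(max(v_hi$hr), 180)
  expect_true(all(v_hi$sbp >= 60 & v_hi$sbp <= 220))

  expect_error(generate_vitals(lat, 1, data.frame(gain = 1)), "profile")
})

test_that("rater scores are noisy copies of the latent state", {
  lat <- generate_trajectory(250, seed = 3)
  exact <- generate_rater_scores(lat, seed = 1, noise_sd = 0)
  for (k in 1:5) expect_equal(exact[[paste0("r", k)]], lat$state)

  # averaging 5 raters beats any single rater (RMSE over 20 seeds)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  gains <- vapply(1:20, function(s) {
    r <- generate_rater_scores(lat, seed = 1000 + s)
    rmse(rowMeans(r[, -1]), lat$state) - rmse(r$r1, lat$state)
  }, numeric(1))
  expect_lt(mean(gains), 0)

  big <- generate_rater_scores(lat, seed = 2, noise_sd = 60)
  expect_true(all(as.matrix(big[, -1]) >= 0 & as.matrix(big[, -1]) <= 100))
})

test_that("artifact bursts hit only the selected windows at >= 10x RMS", {
  eeg <- generate_eeg(plateau_latent(50, 6), seed = 21)
  dirty <- inject_artifact(eeg, windows = 3, seed = 5)
  w3 <- 1251:1875
  expect_identical(dirty[-w3], eeg[-w3])
  expect_gte(rms(dirty[w3] - eeg[w3]) / rms(eeg[w3]), 10)
  expect_error(inject_artifact(eeg, windows = 7, seed = 1), "out of range")
})

test_that("EMD band reconstruction strips out-of-band burst energy", {
  eeg <- generate_eeg(plateau_latent(40, 2), seed = 30)
  dirty <- inject_artifact(eeg, windows = 1, seed = 31)
  filt <- emd_filter_windows(dirty)
  w <- 1:625
  raw_hi <- band_power(dirty[w], 125, 48, halfwidth = 14)
  filt_hi <- band_power(filt[w], 125, 48, halfwidth = 14)
  expect_lt(filt_hi, 0.1 * raw_hi)
})

test_that("patient directories round-trip through CSV/JSON", {
  p <- generate_patient(100, seed = 8)
  dir <- withr::local_tempdir()
  write_patient(p, dir)
  expect_setequal(list.files(dir),
                  c("eeg.csv", "vitals.csv", "raters.csv", "meta.json"))
  q <- read_patient(dir)
  expect_equal(q$eeg, p$eeg, tolerance = 1e-12)
  expect_equal(q$vitals, p$vitals, tolerance = 1e-12)
  expect_equal(q$raters, p$raters, tolerance = 1e-12)
  expect_equal(q$seed, 8)
  expect_equal(q$latent$state, p$latent$state, tolerance = 1e-12)
})
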