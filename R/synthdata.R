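# Synthetic anesthesia cases with known ground truth.
#
# A latent consciousness trajectory (0-100) on the 0.2 Hz grid drives
# (a) a 125 Hz EEG whose irregularity rises with consciousness, (b) six
# vital-sign channels with configurable per-channel linear gains, and
# (c) several noisy rater score series. Everything is seeded: one master
# seed per patient is expanded into independent substreams so channels do
# not perturb each other.

VITAL_CHANNELS <- c("emg", "hr", "pulse", "sbp", "dbp", "sqi")

# physiological clipping bounds; out-of-range effects saturate, never error
VITAL_BOUNDS <- list(
  emg   = c(0, 100),
  hr    = c(30, 180),
  pulse = c(30, 180),
  sbp   = c(60, 220),
  dbp   = c(30, 130),
  sqi   = c(0, 100)
)

VITAL_BASELINES <- c(emg = 5, hr = 65, pulse = 65, sbp = 100, dbp = 60,
                     sqi = 85)

#' Latent consciousness trajectory
#'
#' Piecewise-smooth consciousness level on the 0.2 Hz grid: an awake plateau
#' (>= 80), a sigmoidal induction ramp, an anesthetized maintenance plateau
#' (<= 40) with slow drift, and an emergence ramp back up. Segment
#' boundaries and plateau levels are jittered from the seed.
#'
#' @param duration_s total duration in seconds, >= 50 (at least 10 windows).
#' @param seed integer seed.
#' @return data.frame of class `latent_trajectory` with columns `time_s`
#'   (5, 10, ...) and `state` in `[0, 100]`.
#' @export
generate_trajectory <- function(duration_s, seed) {
  if (duration_s < 50) stop("duration_s must be at least 50 (10 windows)")
  n <- as.integer(duration_s %/% 5)
  with_seed(substream_seed(seed, 1L), {
    t <- seq_len(n) * 5
    awake <- runif(1, 88, 97)
    deep <- runif(1, 15, 32)
    # induction midpoint in the first third, emergence in the last third
    t_ind <- duration_s * runif(1, 0.15, 0.30)
    t_emg <- duration_s * runif(1, 0.70, 0.85)
    tau <- duration_s * 0.03
    down <- 1 / (1 + exp((t - t_ind) / tau))   # 1 awake -> 0 asleep
    up <- 1 / (1 + exp(-(t - t_emg) / tau))
    frac <- pmin(down + up, 1)
    state <- deep + (awake - deep) * frac
    # slow maintenance drift
    drift <- 3 * sin(2 * pi * t / (duration_s * 0.9) + runif(1, 0, 2 * pi))
    state <- clip(state + drift * (1 - frac), 0, 100)
    structure(data.frame(time_s = t, state = state),
              class = c("latent_trajectory", "data.frame"))
  })
}

#' Synthetic 125 Hz EEG driven by a latent consciousness level
#'
#' Each 5-second window is a mixture of band-limited noise (0.8-32 Hz,
#' 4th-order Butterworth) and a slow 1-3 Hz oscillation; the noise weight is
#' linear in the latent state, so an awake brain produces an irregular
#' broadband signal (high sample entropy) and a deeply anesthetized one a
#' quasi-periodic slow wave (low sample entropy). A noise floor keeps the
#' signal irregular even at state 0.
#'
#' @param latent a [generate_trajectory()] result (one window per row).
#' @param seed integer seed.
#' @param amplitude overall scale in arbitrary microvolt-like units.
#' @return numeric vector of length `625 * nrow(latent)`.
#' @export
generate_eeg <- function(latent, seed, amplitude = 20) {
  stopifnot(inherits(latent, "latent_trajectory"))
  fs <- 125
  wlen <- 625L
  bp <- signal::butter(4, c(0.8, 32) / (fs / 2), type = "pass")
  n_win <- nrow(latent)
  out <- numeric(n_win * wlen)
  for (w in seq_len(n_win)) {
    s <- latent$state[w]
    x <- with_seed(substream_seed(seed, 100L + w), {
      noise <- signal::filtfilt(bp, rnorm(wlen))
      noise <- noise / sd(noise)
      f_slow <- runif(1, 1, 3)
      phase <- runif(1, 0, 2 * pi)
      slow <- sqrt(2) * sin(2 * pi * f_slow * (0:(wlen - 1)) / fs + phase)
      wt <- 0.15 + 0.85 * s / 100  # noise weight, floor keeps signal alive
      wt * noise + (1 - wt) * slow
    })
    out[((w - 1L) * wlen + 1L):(w * wlen)] <- amplitude * x
  }
  out
}

#' Per-channel effect profile for the vital-sign generator
#'
#' Assigns each channel a linear gain from the latent state and a Gaussian
#' noise SD, so the designed "most influential" channel is known ground
#' truth for sensitivity-recovery experiments. The default makes EMG the
#' dominant channel with a gain 16 times the others.
#'
#' @param dominant channel name receiving `dominant_gain` (default "emg").
#' @param dominant_gain,other_gain state-to-channel gains (units of the
#'   channel per consciousness point).
#' @param noise_sd per-channel Gaussian noise SD (recycled).
#' @return data.frame with rows `emg, hr, pulse, sbp, dbp, sqi` and columns
#'   `gain`, `noise_sd`.
#' @export
effect_profile <- function(dominant = "emg", dominant_gain = 0.8,
                           other_gain = 0.05, noise_sd = 2) {
  if (!is.null(dominant) && !dominant %in% VITAL_CHANNELS) {
    stop("dominant must be one of: ", paste(VITAL_CHANNELS, collapse = ", "))
  }
  gain <- rep(other_gain, length(VITAL_CHANNELS))
  names(gain) <- VITAL_CHANNELS
  if (!is.null(dominant)) gain[dominant] <- dominant_gain
  data.frame(gain = gain, noise_sd = rep_len(noise_sd,
                                             length(VITAL_CHANNELS)),
             row.names = VITAL_CHANNELS)
}

#' Synthetic 0.2 Hz vital signs
#'
#' Each channel is `baseline + gain * state + Gaussian noise`, clipped to
#' physiological ranges (HR and pulse 30-180 bpm, SBP 60-220 mmHg, DBP
#' 30-130 mmHg, EMG and SQI 0-100).
#'
#' @param latent a [generate_trajectory()] result.
#' @param seed integer seed.
#' @param profile an [effect_profile()].
#' @return data.frame `time_s, emg, hr, pulse, sbp, dbp, sqi`.
#' @export
generate_vitals <- function(latent, seed, profile = effect_profile()) {
  stopifnot(inherits(latent, "latent_trajectory"))
  if (!all(VITAL_CHANNELS %in% rownames(profile)) ||
      !all(c("gain", "noise_sd") %in% colnames(profile))) {
    stop("profile must have rows ", paste(VITAL_CHANNELS, collapse = ", "),
         " and columns gain, noise_sd")
  }
  n <- nrow(latent)
  out <- data.frame(time_s = latent$time_s)
  for (k in seq_along(VITAL_CHANNELS)) {
    ch <- VITAL_CHANNELS[k]
    raw <- with_seed(substream_seed(seed, 200L + k), {
      VITAL_BASELINES[[ch]] + profile[ch, "gain"] * latent$state +
        rnorm(n, sd = profile[ch, "noise_sd"])
    })
    out[[ch]] <- clip(raw, VITAL_BOUNDS[[ch]][1], VITAL_BOUNDS[[ch]][2])
  }
  out
}

#' Synthetic rater (clinician) consciousness scores
#'
#' Each rater observes the latent state plus independent Gaussian noise,
#' clipped to `[0, 100]`. Averaging raters therefore converges on the
#' latent state, mirroring the multi-clinician consensus target.
#'
#' @param latent a [generate_trajectory()] result.
#' @param seed integer seed.
#' @param n_raters number of raters (default 5).
#' @param noise_sd per-rater score noise SD (default 5 index points).
#' @return data.frame `time_s, r1, ..., r<n_raters>`.
#' @export
generate_rater_scores <- function(latent, seed, n_raters = 5L, noise_sd = 5) {
  stopifnot(inherits(latent, "latent_trajectory"), n_raters >= 1)
  out <- data.frame(time_s = latent$time_s)
  for (k in seq_len(n_raters)) {
    noise <- with_seed(substream_seed(seed, 300L + k),
                       rnorm(nrow(latent), sd = noise_sd))
    out[[paste0("r", k)]] <- clip(latent$state + noise, 0, 100)
  }
  out
}

#' Inject electrosurgical-style artifact bursts
#'
#' Overwrites selected 5-second windows with the clean signal plus a
#' high-amplitude interference burst scaled to `amplitude_factor` times the
#' clean window RMS. Electrosurgical (cautery) interference reaching a
#' 125 Hz EEG recording is dominated by components above the EEG band, so
#' the burst is broadband noise high-passed at 30 Hz; its energy sits
#' almost entirely outside 0.8-32 Hz, which is what makes band-limited EMD
#' reconstruction an effective counter-measure. Other windows are
#' bit-identical to the input.
#'
#' @param eeg 125 Hz signal whose length is a multiple of 625.
#' @param windows 1-based indices of 5-second windows to contaminate.
#' @param amplitude_factor burst RMS relative to the clean window RMS
#'   (default 12, comfortably above the 10x contamination regime).
#' @param seed integer seed.
#' @return contaminated signal, same length as `eeg`.
#' @export
inject_artifact <- function(eeg, windows, amplitude_factor = 12, seed = 1L) {
  wlen <- 625L
  n_win <- length(eeg) %/% wlen
  windows <- as.integer(windows)
  if (any(windows < 1 | windows > n_win)) stop("window index out of range")
  out <- eeg
  hp <- signal::butter(4, 30 / 62.5, type = "high")
  for (w in windows) {
    i <- ((w - 1L) * wlen + 1L):(w * wlen)
    burst <- with_seed(substream_seed(seed, 400L + w),
                       signal::filtfilt(hp, rnorm(wlen)))
    out[i] <- eeg[i] + burst / rms(burst) * amplitude_factor * rms(eeg[i])
  }
  out
}

#' Generate one complete synthetic patient
#'
#' @param duration_s recording length in seconds (default 500, i.e. 100
#'   windows spanning induction, maintenance and emergence).
#' @param seed per-patient master seed.
#' @param profile vital-sign [effect_profile()].
#' @param n_raters,rater_noise_sd rater simulation controls.
#' @return list of class `synthetic_patient`: `latent`, `eeg`, `vitals`,
#'   `raters`, `seed`, `profile`.
#' @examples
#' p <- generate_patient(duration_s = 100, seed = 42)
#' length(p$eeg) # 20 windows * 625
#' @export
generate_patient <- function(duration_s = 500, seed = 1L,
                             profile = effect_profile(),
                             n_raters = 5L, rater_noise_sd = 5) {
  latent <- generate_trajectory(duration_s, seed)
  structure(
    list(
      latent = latent,
      eeg = generate_eeg(latent, seed),
      vitals = generate_vitals(latent, seed, profile),
      raters = generate_rater_scores(latent, seed, n_raters, rater_noise_sd),
      seed = as.integer(seed),
      profile = profile
    ),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "Synthetic patient (seed %d): %d windows (%g s), %d raters\n",
    x$seed, nrow(x$latent), max(x$latent$time_s), ncol(x$raters) - 1L
  ))
  invisible(x)
}

#' Generate a cohort of synthetic patients
#'
#' Patient `i` uses master seed `seed + i`, so cohorts are reproducible and
#' individual patients can be regenerated in isolation.
#'
#' @param n_patients cohort size.
#' @inheritParams generate_patient
#' @return named list (`p1`, `p2`, ...) of `synthetic_patient` objects.
#' @export
generate_cohort <- function(n_patients, duration_s = 500, seed = 1L,
                            profile = effect_profile()) {
  stats::setNames(
    lapply(seq_len(n_patients), function(i) {
      generate_patient(duration_s, seed = seed + i, profile = profile)
    }),
    paste0("p", seq_len(n_patients))
  )
}
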