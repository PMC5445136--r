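#' Simulate one stimulation trial
#'
#' Generates the three stimulus-locked channels of a single 1-minute trial
#' for one subject at one pain level. The waveform models are deliberately
#' simple -- the fidelity target is that the four levels are visibly and
#' statistically different, not physiological realism:
#'
#' * **BVP** (percent reflectance): a sum of three harmonics at the
#'   subject's heart rate; the pulse amplitude shrinks by a factor
#'   `(1 - bvp_attenuation_per_level)^rank` and the rate rises with level
#'   (sympathetic vasoconstriction and cardio-acceleration).
#' * **ECG** (microvolts): a template beat train (P-QRS-T bumps) whose beat
#'   rate rises with level, superimposed on slow baseline wander that the
#'   preprocessing stage is expected to remove.
#' * **SCL** (microsiemens): tonic level plus a stimulus-locked exponential
#'   phasic ramp whose asymptote scales with level (`gain x rank`); at
#'   baseline (`L0`) the phasic component is exactly zero.
#'
#' Gaussian noise is added to every channel. Trial-to-trial jitter of tonic
#' level, phasic gain and heart rate (controlled by `params$trial_jitter`)
#' creates realistic within-class spread; setting those entries to zero
#' together with zero `noise_sd_per_channel` yields fully deterministic
#' level-dependent waveforms.
#'
#' @param params A `subject_params` object from [gen_subject_params()].
#' @param level One of `"L0".."L3"`.
#' @param cfg A [protocol_config()].
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @param day_index,session_index Metadata carried into the record.
#' @param day_factors Optional length-3 numeric (tonic/amplitude/heart-rate
#'   multipliers) modelling day-to-day drift; defaults to no drift.
#' @return A one-row tibble (a trial record) with columns `subject_id`,
#'   `day_index`, `session_index`, `level`, `seed` and list-columns `bvp`,
#'   `ecg`, `scl` holding the sampled waveforms, plus `fs` (Hz).
#' @examples
#' p <- gen_subject_params(1, 1)
#' tr <- simulate_trial(p, "L2", protocol_config(), seed = 7)
#' length(tr$scl[[1]]) == 60 * 256
#' @export
simulate_trial <- function(params, level, cfg = protocol_config(), seed = 1L,
                           day_index = 1L, session_index = 1L,
                           day_factors = c(1, 1, 1)) {
  if (!as.character(level) %in% cfg$stimulus_levels) {
    abort(sprintf("unknown stimulus level '%s' (expected one of %s)",
                  level, paste(cfg$stimulus_levels, collapse = ", ")))
  }
  rank <- level_rank(level)
  fs <- cfg$sampling_rate_hz
  n <- round(cfg$trial_duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  jit <- params$trial_jitter
  nsd <- params$noise_sd_per_channel

  with_seed(seed, {
    tonic <- params$scl_tonic_level_us * day_factors[1] *
      (1 + rnorm(1, 0, jit[["tonic"]]))
    gain <- params$scl_phasic_gain_per_level * (1 + rnorm(1, 0, jit[["gain"]]))
    hr <- params$baseline_heart_rate_bpm * day_factors[3] +
      params$heart_rate_gain_per_level * rank + rnorm(1, 0, jit[["hr_bpm"]])
    hr <- max(hr, 40)

    # BVP: harmonic pulse wave, amplitude attenuated per level
    amp <- params$bvp_amplitude * day_factors[2] *
      (1 - params$bvp_attenuation_per_level)^rank
    f0 <- hr / 60
    phi <- runif(1, 0, 2 * pi)
    bvp <- amp * (0.6 * sin(2 * pi * f0 * t + phi) +
                  0.3 * sin(4 * pi * f0 * t + 2 * phi + 0.5) +
                  0.1 * sin(6 * pi * f0 * t + 3 * phi + 1.2))
    if (nsd[["bvp"]] > 0) bvp <- bvp + rnorm(n, 0, nsd[["bvp"]])

    # ECG: template beat train plus slow baseline wander
    ecg <- ecg_beat_train(n, fs, hr) +
      100 * sin(2 * pi * 0.08 * t + runif(1, 0, 2 * pi))
    if (nsd[["ecg"]] > 0) ecg <- ecg + rnorm(n, 0, nsd[["ecg"]])

    # SCL: tonic + level-scaled exponential phasic ramp (tau = 5 s)
    scl <- tonic + gain * rank * (1 - exp(-t / 5))
    if (nsd[["scl"]] > 0) scl <- scl + rnorm(n, 0, nsd[["scl"]])

    tibble::tibble(
      subject_id = params$subject_id,
      day_index = as.integer(day_index),
      session_index = as.integer(session_index),
      level = as.character(level),
      seed = as.integer(seed),
      fs = fs,
      bvp = list(bvp), ecg = list(ecg), scl = list(scl)
    )
  })
}

# Synthetic lead-I-like beat train: Gaussian P/Q/R/S/T bumps at each beat,
# 3% inter-beat interval jitter. Amplitudes in microvolts.
ecg_beat_train <- function(n, fs, hr_bpm) {
  y <- numeric(n)
  # offset (s), amplitude (uV), width sd (s) per wave component
  comp <- list(
    p = c(-0.17, 110, 0.025),
    q = c(-0.035, -120, 0.010),
    r = c(0.00, 1000, 0.012),
    s = c(0.035, -180, 0.012),
    t = c(0.25, 220, 0.055)
  )
  tb <- 0.3
  while (tb < n / fs) {
    for (cm in comp) {
      centre <- tb + cm[1]
      lo <- max(1L, floor((centre - 4 * cm[3]) * fs) + 1L)
      hi <- min(n, ceiling((centre + 4 * cm[3]) * fs) + 1L)
      if (hi >= lo) {
        tt <- (seq(lo, hi) - 1) / fs
        y[lo:hi] <- y[lo:hi] + cm[2] * exp(-(tt - centre)^2 / (2 * cm[3]^2))
      }
    }
    tb <- tb + (60 / hr_bpm) * (1 + rnorm(1, 0, 0.03))
  }
  y
}

#' Simulate a full cohort under the acquisition protocol
#'
#' Emits every trial of the protocol: for day 1, all `n_subjects` subjects
#' complete `sessions_per_subject` sessions of one trial per level (120
#' trials per subject at defaults); the designated multi-day subject is
#' additionally recorded on days `2..n_days`. The level order within each
#' session is a seeded random permutation, and per-day drift factors
#' (multiplicative, s.d. `day_drift_sd`) are applied to tonic skin
#' conductance, pulse amplitude and resting heart rate.
#'
#' @param cfg A [protocol_config()].
#' @param master_seed Integer; all subject draws, day factors, level orders
#'   and trial noise derive deterministically from it.
#' @param null_effects If `TRUE`, subjects are generated with zero stimulus
#'   effects (see [gen_subject_params()]): labels carry no signal, so any
#'   above-chance accuracy downstream indicates information leakage.
#' @return A tibble of trial records, one row per trial, as in
#'   [simulate_trial()].
#' @examples
#' cfg <- protocol_config(sessions_per_subject = 2L, n_subjects = 2L,
#'                        n_days = 1L, trial_duration_s = 4)
#' nrow(simulate_cohort(cfg, master_seed = 1))  # 2 subjects x 2 sessions x 4
#' @export
simulate_cohort <- function(cfg = protocol_config(), master_seed = 1L,
                            null_effects = FALSE) {
  rows <- vector("list", 0L)
  for (s in seq_len(cfg$n_subjects)) {
    params <- gen_subject_params(master_seed, s, null_effects = null_effects)
    days <- if (s == cfg$multiday_subject) seq_len(cfg$n_days) else 1L
    for (d in days) {
      fac <- with_seed(sub_seed(master_seed, 202L, s, d),
                       1 + rnorm(3, 0, params$day_drift_sd))
      for (sess in seq_len(cfg$sessions_per_subject)) {
        ord <- with_seed(sub_seed(master_seed, 303L, s, d, sess),
                         sample(cfg$stimulus_levels))
        for (k in seq_along(ord)) {
          rows[[length(rows) + 1L]] <- simulate_trial(
            params, ord[k], cfg,
            seed = sub_seed(master_seed, 404L, s, d, sess, k),
            day_index = d, session_index = sess, day_factors = fac
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
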