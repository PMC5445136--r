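#' Acquisition protocol configuration
#'
#' Describes the electrical-stimulation acquisition protocol that the
#' synthetic-signal generator emulates: four stimulus levels (baseline plus
#' 20/30/40 mA), 1-minute trials sampled at 256 Hz, 30 sessions per subject
#' and day (each session containing one trial of every level in random
#' order, i.e. 120 trials per subject per day), six subjects, and seven
#' consecutive days for one designated multi-day subject.
#'
#' @param sampling_rate_hz Sampling rate of all three channels, Hz.
#' @param stimulus_levels Ordered level labels; fixed at `L0 < L1 < L2 < L3`.
#' @param stimulus_currents_ma Nominal stimulation current per level, mA.
#' @param stimulation_frequency_hz Pulse frequency of the current stimulator.
#' @param trial_duration_s Duration of one stimulation trial, seconds.
#' @param recovery_range_s Rest interval between trials, seconds. Recovery
#'   periods are not synthesised (features use only in-trial data); the field
#'   documents the protocol.
#' @param sessions_per_subject Sessions per subject per day.
#' @param trials_per_session Trials per session; one per level.
#' @param n_subjects Number of subjects in the cohort.
#' @param n_days Consecutive recording days for the multi-day subject.
#' @param multiday_subject 1-based index of the subject recorded on all days.
#'
#' @return An object of class `protocol_config` (a named list).
#' @examples
#' cfg <- protocol_config()
#' cfg$sessions_per_subject * cfg$trials_per_session  # 120 trials/subject/day
#' @export
protocol_config <- function(sampling_rate_hz = 256,
                            stimulus_levels = pain_levels(),
                            stimulus_currents_ma = c(0, 20, 30, 40),
                            stimulation_frequency_hz = 2,
                            trial_duration_s = 60,
                            recovery_range_s = c(90, 120),
                            sessions_per_subject = 30L,
                            trials_per_session = 4L,
                            n_subjects = 6L,
                            n_days = 7L,
                            multiday_subject = 1L) {
  stopifnot(sampling_rate_hz > 0, stimulation_frequency_hz > 0,
            trial_duration_s > 0, sessions_per_subject >= 1,
            trials_per_session >= 1, n_subjects >= 1, n_days >= 1)
  if (!identical(as.character(stimulus_levels), PAIN_LEVELS)) {
    abort("stimulus_levels must be the ordered labels L0 < L1 < L2 < L3")
  }
  if (length(stimulus_currents_ma) != length(stimulus_levels) ||
      is.unsorted(stimulus_currents_ma, strictly = TRUE)) {
    abort("stimulus_currents_ma must be strictly increasing, one per level")
  }
  if (trials_per_session != length(stimulus_levels)) {
    abort("trials_per_session must equal the number of stimulus levels")
  }
  structure(
    list(
      sampling_rate_hz = sampling_rate_hz,
      stimulus_levels = as.character(stimulus_levels),
      stimulus_currents_ma = stimulus_currents_ma,
      stimulation_frequency_hz = stimulation_frequency_hz,
      trial_duration_s = trial_duration_s,
      recovery_range_s = recovery_range_s,
      sessions_per_subject = as.integer(sessions_per_subject),
      trials_per_session = as.integer(trials_per_session),
      n_subjects = as.integer(n_subjects),
      n_days = as.integer(n_days),
      multiday_subject = as.integer(multiday_subject)
    ),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("<protocol_config>\n")
  cat(sprintf("  %d subjects x %d sessions x %d trials (%d trials/subject/day)\n",
              x$n_subjects, x$sessions_per_subject, x$trials_per_session,
              x$sessions_per_subject * x$trials_per_session))
  cat(sprintf("  levels %s at %s mA, %g Hz stimulation\n",
              paste(x$stimulus_levels, collapse = "<"),
              paste(x$stimulus_currents_ma, collapse = "/"),
              x$stimulation_frequency_hz))
  cat(sprintf("  %g s trials sampled at %g Hz; multi-day subject %d over %d days\n",
              x$trial_duration_s, x$sampling_rate_hz, x$multiday_subject,
              x$n_days))
  invisible(x)
}

#' Draw the physiological parameters of one synthetic subject
#'
#' Samples a subject's stable physiology from documented ranges: resting
#' heart rate, the per-level heart-rate increase, pulse-wave amplitude and
#' its per-level attenuation, tonic skin conductance and the per-level
#' phasic gain, channel noise levels, and the day-to-day drift scale. Draws
#' are deterministic given `(master_seed, subject_index)`; all effect sizes
#' are strictly positive so the four classes are separable in expectation,
#' unless `null_effects = TRUE`, which zeroes every level-dependent effect
#' (the chance-level control used by leakage tests).
#'
#' @param master_seed Integer master seed for the cohort.
#' @param subject_index 1-based subject index.
#' @param null_effects If `TRUE`, all stimulus effect sizes are set to zero.
#' @return A `subject_params` list: `baseline_heart_rate_bpm`,
#'   `heart_rate_gain_per_level`, `bvp_amplitude`,
#'   `bvp_attenuation_per_level`, `scl_tonic_level_us`,
#'   `scl_phasic_gain_per_level`, `noise_sd_per_channel` (bvp/ecg/scl),
#'   `day_drift_sd`, `trial_jitter` and the identifying seed fields.
#' @examples
#' p <- gen_subject_params(1, 1)
#' p$scl_phasic_gain_per_level > 0
#' @export
gen_subject_params <- function(master_seed, subject_index,
                               null_effects = FALSE) {
  stopifnot(subject_index >= 1)
  with_seed(sub_seed(master_seed, 101L, subject_index), {
    p <- list(
      subject_index = as.integer(subject_index),
      subject_id = sprintf("S%02d", subject_index),
      baseline_heart_rate_bpm = runif(1, 60, 80),
      heart_rate_gain_per_level = runif(1, 3, 6),
      bvp_amplitude = runif(1, 8, 12),
      bvp_attenuation_per_level = runif(1, 0.08, 0.15),
      scl_tonic_level_us = runif(1, 2, 8),
      scl_phasic_gain_per_level = runif(1, 0.3, 0.8),
      noise_sd_per_channel = c(bvp = 0.5, ecg = 30, scl = 0.05),
      day_drift_sd = 0.05,
      # relative trial-to-trial variability of tonic level / phasic gain and
      # absolute (bpm) jitter of heart rate: creates realistic class overlap
      trial_jitter = c(tonic = 0.04, gain = 0.15, hr_bpm = 2)
    )
    if (null_effects) {
      p$heart_rate_gain_per_level <- 0
      p$bvp_attenuation_per_level <- 0
      p$scl_phasic_gain_per_level <- 0
    }
    structure(p, class = "subject_params")
  })
}
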