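test_that("subject parameter draws are deterministic and subject-specific", {
  p1 <- gen_subject_params(42, 1)
  p2 <- gen_subject_params(42, 1)
  expect_identical(p1, p2)
  p3 <- gen_subject_params(42, 2)
  expect_false(isTRUE(all.equal(p1$baseline_heart_rate_bpm,
                                p3$baseline_heart_rate_bpm)))
  # effect sizes strictly positive so mean responses are separable
  expect_gt(p1$scl_phasic_gain_per_level, 0)
  expect_gt(p1$heart_rate_gain_per_level, 0)
  expect_gt(p1$bvp_attenuation_per_level, 0)
  # null setting zeroes every stimulus effect
  pn <- gen_subject_params(42, 1, null_effects = TRUE)
  expect_equal(pn$scl_phasic_gain_per_level, 0)
  expect_equal(pn$heart_rate_gain_per_level, 0)
  expect_equal(pn$bvp_attenuation_per_level, 0)
})

test_that("simulate_trial is deterministic, sized correctly, and rejects unknown levels", {
  p <- gen_subject_params(1, 1)
  cfg <- protocol_config()
  t1 <- simulate_trial(p, "L2", cfg, seed = 7)
  t2 <- simulate_trial(p, "L2", cfg, seed = 7)
  expect_identical(t1$bvp[[1]], t2$bvp[[1]])
  expect_identical(t1$ecg[[1]], t2$ecg[[1]])
  expect_identical(t1$scl[[1]], t2$scl[[1]])
  n <- cfg$trial_duration_s * cfg$sampling_rate_hz
  expect_length(t1$bvp[[1]], n)
  expect_length(t1$ecg[[1]], n)
  expect_length(t1$scl[[1]], n)
  expect_error(simulate_trial(p, "L9", cfg, seed = 1), "L9")
})

test_that("baseline trial with zero noise and jitter has SCL exactly at tonic level", {
  p <- gen_subject_params(1, 1)
  p$noise_sd_per_channel[] <- 0
  p$trial_jitter[] <- 0
  tr <- simulate_trial(p, "L0", protocol_config(trial_duration_s = 5), seed = 3)
  expect_equal(tr$scl[[1]], rep(p$scl_tonic_level_us, length(tr$scl[[1]])))
})

test_that("per-level mean responses are monotone (Monte-Carlo over seeded trials)", {
  p <- gen_subject_params(8, 1)
  cfg <- protocol_config(trial_duration_s = 30)
  sim_stats <- function(level, seeds) {
    t(vapply(seeds, function(s) {
      tr <- simulate_trial(p, level, cfg, seed = s)
      c(scl = mean(tr$scl[[1]]), bvp_sd = sd(tr$bvp[[1]]),
        ecg_act = mean(abs(diff(tr$ecg[[1]]))))
    }, numeric(3)))
  }
  s0 <- sim_stats("L0", 1:50)
  s3 <- sim_stats("L3", 51:100)
  gain <- p$scl_phasic_gain_per_level
  # documented mean model: L3 - L0 mean SCL gap of 3 * gain * ramp average,
  # demanded margin 2 * gain * 0.5
  expect_gt(mean(s3[, "scl"]) - mean(s0[, "scl"]), 2 * gain * 0.5)
  # pulse amplitude attenuates and cardiac activity rises with level
  expect_lt(mean(s3[, "bvp_sd"]), mean(s0[, "bvp_sd"]))
  expect_gt(mean(s3[, "ecg_act"]), mean(s0[, "ecg_act"]))
  # middle level sits between the extremes for SCL
  s1 <- sim_stats("L1", 101:130)
  expect_gt(mean(s1[, "scl"]), mean(s0[, "scl"]))
  expect_lt(mean(s1[, "scl"]), mean(s3[, "scl"]))
})

test_that("cohort bookkeeping: counts, session balance, determinism", {
  cfg <- tiny_protocol()
  tr <- simulate_cohort(cfg, master_seed = 11)
  expect_equal(nrow(tr), cfg$n_subjects * cfg$sessions_per_subject *
                 cfg$trials_per_session)
  # every session holds one trial of every level (seeded permutation)
  balance <- tr |>
    dplyr::count(subject_id, day_index, session_index, level)
  expect_true(all(balance$n == 1))
  tr2 <- simulate_cohort(cfg, master_seed = 11)
  expect_identical(tr$level, tr2$level)
  expect_identical(tr$bvp[[5]], tr2$bvp[[5]])
  # multi-day subject carries every day index
  cfg7 <- protocol_config(sessions_per_subject = 1L, n_subjects = 2L,
                          n_days = 3L, trial_duration_s = 4)
  tr7 <- simulate_cohort(cfg7, master_seed = 2)
  md <- tr7[tr7$subject_id == "S01", ]
  expect_setequal(unique(md$day_index), 1:3)
  expect_equal(nrow(md), 3 * 1 * 4)
  expect_setequal(unique(tr7$day_index[tr7$subject_id == "S02"]), 1L)
})

test_that("day drift produces larger between-day than within-day variation of SCL means", {
  cfg <- protocol_config(sessions_per_subject = 6L, n_subjects = 1L,
                         n_days = 5L, trial_duration_s = 20)
  tr <- simulate_cohort(cfg, master_seed = 21)
  per_trial <- tr |>
    dplyr::mutate(scl_mean = purrr::map_dbl(scl, mean)) |>
    dplyr::group_by(day_index, session_index) |>
    dplyr::summarise(m = mean(scl_mean), .groups = "drop")
  day_means <- tapply(per_trial$m, per_trial$day_index, mean)
  within <- mean(tapply(per_trial$m, per_trial$day_index, var))
  expect_gt(var(day_means), within)
})
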