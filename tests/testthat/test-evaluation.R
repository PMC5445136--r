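test_that("stratified split preserves class proportions and partitions the data", {
  df <- tibble::tibble(level = rep(paste0("L", 0:3), each = 300),
                       id = 1:1200)
  sp <- stratified_split(df, seed = 1)
  expect_equal(nrow(sp$train), 900)
  expect_equal(nrow(sp$test), 300)
  expect_true(all(table(sp$train$level) == 225))
  expect_true(all(table(sp$test$level) == 75))
  # identical seed, identical split; union is the input exactly once
  sp2 <- stratified_split(df, seed = 1)
  expect_identical(sp$train$id, sp2$train$id)
  expect_setequal(c(sp$train$id, sp$test$id), df$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_error(stratified_split(tibble::tibble(level = c("L0", "L1", "L1"))),
               "fewer than 2")
})

test_that("grouped and stratum-aware splits keep groups intact and strata balanced", {
  df <- fake_feature_tbl(n_subjects = 4, n_sessions = 4)
  sp <- stratified_split(df, seed = 3, group_col = "trial_index")
  shared <- intersect(unique(sp$train$trial_index), unique(sp$test$trial_index))
  expect_length(shared, 0)
  sp2 <- stratified_split(df, seed = 3, group_col = "trial_index",
                          strata_col = "subject_id")
  tab <- table(sp2$train$subject_id, sp2$train$level)
  expect_true(all(tab == tab[1, 1]))  # per-subject class balance preserved
})

test_that("stratified folds cover all rows and balance classes", {
  y <- rep(c("a", "b"), c(40, 20))
  set.seed(2)
  f <- stratified_folds(y, 5)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f[y == "a"]) == 8))
  expect_true(all(table(f[y == "b"]) == 4))
  expect_error(stratified_folds(c("a", "a", "b"), 2), "fewer samples")
})

test_that("scenario fold structure: LOSO one fold per subject, LODO one per day", {
  f <- fake_feature_tbl(n_subjects = 4, n_sessions = 2)
  loso <- run_scenario(f, "between_subject_loso", classifiers = "oracle",
                       n_repeats = 2, ga = FALSE, pca_threshold = FALSE,
                       seed = 5)
  expect_equal(sort(unique(loso$runs$fold)), sprintf("S%02d", 1:4))
  expect_equal(nrow(loso$runs), 2 * 4)
  fd <- fake_feature_tbl(n_subjects = 1, n_sessions = 2, n_days = 5)
  lodo <- run_scenario(fd, "multi_day_lodo", classifiers = "oracle",
                       ga = FALSE, pca_threshold = FALSE, seed = 5)
  expect_equal(sort(unique(lodo$runs$fold)), as.character(1:5))
  # an oracle classifier is perfect in every scenario
  expect_true(all(loso$runs$accuracy == 1))
  expect_true(all(lodo$runs$accuracy == 1))
  single <- run_scenario(f, "single_signal", classifiers = "oracle",
                         n_repeats = 2, seed = 5)
  expect_true(all(single$runs$accuracy == 1))
  expect_setequal(unique(single$runs$channel), c("bvp", "ecg", "scl"))
  # missing metadata is reported by field name
  f_nosub <- dplyr::select(f, -subject_id)
  expect_error(run_scenario(f_nosub, "between_subject_loso"), "subject_id")
})

test_that("scenario reports carry consistent confusion matrices", {
  f <- fake_feature_tbl(n_subjects = 2, n_sessions = 3, shift = 3)
  rep <- run_scenario(f, "multi_signal_raw", n_repeats = 3, seed = 7)
  for (i in seq_len(nrow(rep$runs))) {
    cm <- rep$runs$confusion[[i]]
    expect_equal(sum(cm), rep$runs$n_test[i])
    expect_equal(sum(diag(cm)) / sum(cm), rep$runs$accuracy[i])
  }
  # determinism of the whole scenario under a fixed seed
  rep2 <- run_scenario(f, "multi_signal_raw", n_repeats = 3, seed = 7)
  expect_identical(rep$runs$accuracy, rep2$runs$accuracy)
})

test_that("summaries aggregate runs with mean, SD and chance level", {
  runs <- tibble::tibble(
    `repeat` = 1:2, fold = NA_character_, channel = "all",
    classifier = "lda", accuracy = c(0.8, 0.9), n_test = 10L,
    n_features_selected = 36L,
    confusion = list(matrix(c(4, 1, 0, 5), 2, 2,
                            dimnames = list(c("L0", "L1"), c("L0", "L1"))),
                     matrix(c(5, 0, 1, 4), 2, 2,
                            dimnames = list(c("L0", "L1"), c("L0", "L1")))))
  rep <- structure(list(kind = "multi_signal_raw", classes = c("L0", "L1"),
                        runs = runs, classifiers = "lda", n_repeats = 2L),
                   class = "scenario_report")
  s <- summarize_report(rep)
  ov <- s[s$class == "overall", ]
  expect_equal(ov$mean_accuracy, 0.85)
  expect_equal(ov$sd_accuracy, 0.0707, tolerance = 1e-3)
  expect_equal(unique(s$chance), 0.5)
  # single run: SD reported as 0
  rep1 <- rep
  rep1$runs <- runs[1, ]
  expect_equal(summarize_report(rep1)$sd_accuracy[1], 0)
})

test_that("feature processing does not hurt: processed >= raw on a single-subject cohort", {
  cfg <- protocol_config(n_subjects = 1L, n_days = 1L)
  f1 <- extract_features(simulate_cohort(cfg, master_seed = 2))
  raw <- run_scenario(f1, "multi_signal_raw", n_repeats = 5, seed = 3)
  proc <- run_scenario(f1, "multi_signal_processed", n_repeats = 5,
                       ga = ga_config(population_size = 20,
                                      max_generations = 5), seed = 3)
  raw_mean <- mean(raw$runs$accuracy)
  proc_best <- summarize_report(proc) |>
    dplyr::filter(class == "overall") |>
    dplyr::pull(mean_accuracy) |>
    max()
  expect_gte(proc_best, raw_mean)
  expect_gt(raw_mean, 0.5)
  # GA really prunes the feature set inside each training fold
  expect_true(all(proc$runs$n_features_selected < 36))
})
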