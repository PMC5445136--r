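test_that("window features match the hand-computed example and degenerate cases", {
  f <- extract_window_features(c(1, 2, 4))
  expect_equal(unname(f["f1"]), 7 / 3)
  expect_equal(unname(f["f2"]), sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(unname(f["f3"]), 1.5)
  expect_equal(unname(f["f4"]), 1.5 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(unname(f["f5"]), 3)
  expect_equal(unname(f["f6"]), 3 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(unname(f[c("f7", "f8", "f9", "f10", "f11", "f12")]),
               c(1, 4, 1 / 3, 4 / 3, 3, 2))
  # constant window: sd = 0, normalised differences fall back to 0
  fc <- extract_window_features(rep(5, 10))
  expect_equal(unname(fc), c(5, 0, 0, 0, 0, 0, 5, 5, 0.5, 0.5, 0, 5))
  expect_error(extract_window_features(c(1, 2)), "at least 3")
  expect_error(extract_window_features(c(1, 2, NA)), "finite")
})

test_that("features agree with a brute-force oracle on 1000 random windows", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    x <- rnorm(n, mean = runif(1, -5, 5), sd = runif(1, 0.1, 4))
    expect_equal(extract_window_features(x), oracle_window_features(x),
                 tolerance = 1e-10)
  }
})

test_that("feature identities hold on random windows", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(sample(5:100, 1))
    f <- extract_window_features(x)
    expect_equal(unname(f["f11"]), unname(f["f8"] - f["f7"]))
    expect_equal(unname(f["f4"] * f["f2"]), unname(f["f3"]), tolerance = 1e-12)
    expect_equal(unname(f["f6"] * f["f2"]), unname(f["f5"]), tolerance = 1e-12)
    expect_true(f["f7"] <= f["f12"] && f["f12"] <= f["f8"])
  }
})

test_that("window segmentation geometry follows the count formula", {
  cfg <- window_config()
  x <- sin(seq_len(60 * 256) / 50)
  w <- segment_windows(x, 256, cfg, trial_duration_s = 60)
  expect_length(w, 10)
  expect_true(all(lengths(w) == 768))
  # windows tile the last 30 s without overlap at defaults
  expect_identical(w[[1]], x[(30 * 256 + 1):(33 * 256)])
  expect_identical(w[[10]], x[(57 * 256 + 1):(60 * 256)])
  # SCL at 128 Hz: 384-sample windows
  ws <- segment_windows(x[1:(60 * 128)], 128, cfg, trial_duration_s = 60)
  expect_true(all(lengths(ws) == 384))
  w2 <- segment_windows(x[1:(6 * 256)], 256,
                        window_config(analysis_span_s = 6), 6)
  expect_length(w2, 2)
  expect_error(segment_windows(x[1:100], 256, cfg, trial_duration_s = 10),
               "exceeds")
})

test_that("feature matrix assembly yields #trials x 10 rows with 36 named columns", {
  cfg <- tiny_protocol(trial_duration_s = 8)
  trials <- simulate_cohort(cfg, master_seed = 13)
  f <- extract_features(trials, windows = window_config(analysis_span_s = 6,
                                                        window_s = 3))
  expect_equal(nrow(f), nrow(trials) * 2)
  expect_true(all(feature_names() %in% names(f)))
  expect_equal(sum(grepl("_f\\d+$", names(f))), 36)
  expect_equal(nrow(f), length(unique(f$trial_index)) * 2)
  expect_error(extract_features(trials[0, ]), "empty")
})

test_that("min-max normalisation fits on training rows only", {
  m <- matrix(c(2, 4, 6, 1, 1, 1), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  p <- minmax_fit(m, cols = c("a", "b"))
  out <- minmax_apply(m, p)
  expect_equal(out[, "a"], c(0, 0.5, 1))
  expect_equal(out[, "b"], c(0, 0, 0))  # constant column maps to 0
  # held-out value at the training maximum maps to exactly 1
  held <- matrix(c(6, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(minmax_apply(held, p)[1, "a"], c(a = 1))
  # held-out values may leave [0, 1]
  held2 <- matrix(c(8, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_gt(minmax_apply(held2, p)[1, "a"], 1)
  # training columns always land in [0, 1]
  set.seed(3)
  r <- matrix(rnorm(200), ncol = 4, dimnames = list(NULL, letters[1:4]))
  rn <- minmax_apply(r, minmax_fit(r, cols = letters[1:4]))
  expect_true(all(rn >= 0 & rn <= 1))
})
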