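# Shared fixtures and independent oracles for the test suite.

# Brute-force implementation of the 12 window statistics, written as plain
# accumulation loops so it shares no code path with the package.
oracle_window_features <- function(x) {
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  sig <- sqrt(ss / (n - 1))
  th1 <- 0
  for (i in 1:(n - 1)) th1 <- th1 + abs(x[i + 1] - x[i])
  th1 <- th1 / (n - 1)
  th2 <- 0
  for (i in 1:(n - 2)) th2 <- th2 + abs(x[i + 2] - x[i])
  th2 <- th2 / (n - 2)
  mn <- x[1]; mx <- x[1]
  for (v in x) { if (v < mn) mn <- v; if (v > mx) mx <- v }
  xs <- sort(x)
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  c(f1 = mu, f2 = sig, f3 = th1,
    f4 = if (sig > 0) th1 / sig else 0,
    f5 = th2, f6 = if (sig > 0) th2 / sig else 0,
    f7 = mn, f8 = mx, f9 = mn / n, f10 = mx / n, f11 = mx - mn, f12 = med)
}

# Gaussian class blobs in `d` dimensions. Class centres sit on distinct
# corners of a scaled hypercube (not on one line), so every class is
# linearly separable from the rest when `spacing >> sd`.
make_blobs <- function(n_per, centers = 4, d = 2, spacing = 3, sd = 1,
                       seed = 1) {
  painsense:::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(centers) - 1, function(k) {
      corner <- spacing * as.integer(intToBits(k))[seq_len(d)]
      sweep(matrix(rnorm(n_per * d, sd = sd), ncol = d), 2, corner, "+")
    }))
    list(x = x, y = rep(paste0("L", seq_len(centers) - 1), each = n_per))
  })
}

# Four informative features planted among 32 pure-noise columns; the class
# rank shifts the informative means by `delta` per level.
planted_dataset <- function(seed, n_per = 60, informative = c(3, 15, 27, 33),
                            delta = 1.5) {
  painsense:::with_seed(seed, {
    y <- rep(paste0("L", 0:3), each = n_per)
    x <- matrix(rnorm(4 * n_per * 36), ncol = 36)
    rank <- as.integer(factor(y)) - 1
    for (j in informative) x[, j] <- x[, j] + rank * delta
    list(x = x, y = y, informative = informative)
  })
}

# A feature tibble with the full 36-column layout but synthetic content;
# cheap stand-in for scenario plumbing tests.
fake_feature_tbl <- function(n_subjects = 3, n_sessions = 2, n_days = 1,
                             n_windows = 5, shift = 2, seed = 1) {
  painsense:::with_seed(seed, {
    grid <- expand.grid(subject = seq_len(n_subjects), day = seq_len(n_days),
                        session = seq_len(n_sessions), level = 0:3)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      m <- matrix(rnorm(n_windows * 36), ncol = 36) + g$level * shift
      colnames(m) <- feature_names()
      tibble::tibble(subject_id = sprintf("S%02d", g$subject),
                     day_index = as.integer(g$day),
                     session_index = as.integer(g$session),
                     trial_index = i, window_index = seq_len(n_windows),
                     level = paste0("L", g$level),
                     tibble::as_tibble(m))
    })
    dplyr::bind_rows(rows)
  })
}

# Small, fast acquisition protocol for generator tests.
tiny_protocol <- function(trial_duration_s = 8, ...) {
  protocol_config(sessions_per_subject = 2L, n_subjects = 2L, n_days = 1L,
                  trial_duration_s = trial_duration_s, ...)
}
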