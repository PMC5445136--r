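#' Windowing configuration
#'
#' The analysis uses the last `analysis_span_s` seconds of each 1-minute
#' trial (allowing for the latency of the pain reaction) and slides a
#' `window_s`-second window in `step_s`-second steps across that span:
#' 10 non-overlapping 3-s windows per trial at defaults.
#'
#' @param analysis_span_s Analysed span at the end of the trial, seconds.
#' @param window_s Window length, seconds.
#' @param step_s Step between window starts, seconds.
#' @param offset_s Start of the analysed span within the trial, seconds;
#'   `NULL` (default) places the span at the end of the trial.
#' @return A `window_config` list.
#' @export
window_config <- function(analysis_span_s = 30, window_s = 3, step_s = 3,
                          offset_s = NULL) {
  stopifnot(analysis_span_s > 0, window_s > 0, step_s > 0,
            window_s <= analysis_span_s)
  structure(list(analysis_span_s = analysis_span_s, window_s = window_s,
                 step_s = step_s, offset_s = offset_s),
            class = "window_config")
}

n_windows <- function(cfg) {
  floor((cfg$analysis_span_s - cfg$window_s) / cfg$step_s) + 1L
}

#' Segment a waveform into sliding windows
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate of `x`, Hz.
#' @param cfg A [window_config()].
#' @param trial_duration_s Total duration represented by `x`, used to place
#'   the span at the end of the trial when `cfg$offset_s` is `NULL`.
#' @return List of numeric windows, each of `window_s * fs` samples.
#' @examples
#' length(segment_windows(sin(1:7680 / 10), fs = 256,
#'                        cfg = window_config(), trial_duration_s = 30))
#' @export
segment_windows <- function(x, fs, cfg = window_config(),
                            trial_duration_s = length(x) / fs) {
  offset <- cfg$offset_s %||% (trial_duration_s - cfg$analysis_span_s)
  if (offset < 0 || offset + cfg$analysis_span_s > trial_duration_s + 1e-9) {
    abort(sprintf("analysis span (%g s at offset %g s) exceeds the %g s trial",
                  cfg$analysis_span_s, offset, trial_duration_s))
  }
  wlen <- round(cfg$window_s * fs)
  starts <- round((offset + (seq_len(n_windows(cfg)) - 1) * cfg$step_s) * fs)
  lapply(starts, function(s0) x[(s0 + 1):(s0 + wlen)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The twelve statistical window features
#'
#' Computes, for one window of `N` samples `X_1..X_N` (`N >= 3`):
#' `f1` mean, `f2` standard deviation (divisor `N - 1`), `f3` mean absolute
#' first difference, `f4 = f3 / f2` (the same statistic on the standardised
#' signal), `f5` mean absolute lag-2 difference (divisor `N - 2`),
#' `f6 = f5 / f2`, `f7` minimum, `f8` maximum, `f9 = f7 / N`,
#' `f10 = f8 / N` (the printed definitions, with `N` the sample count),
#' `f11 = f8 - f7` (range) and `f12` median. On a constant window
#' (`f2 = 0`) the normalised differences `f4` and `f6` are returned as 0.
#'
#' @param x Numeric window with at least 3 finite samples.
#' @return Named numeric vector `f1..f12`.
#' @examples
#' extract_window_features(c(1, 2, 4))
#' @export
extract_window_features <- function(x) {
  n <- length(x)
  if (n < 3) abort("window must contain at least 3 samples")
  if (!all(is.finite(x))) abort("window samples must be finite")
  mu <- mean(x)
  sig <- sqrt(sum((x - mu)^2) / (n - 1))
  th1 <- sum(abs(x[-1] - x[-n])) / (n - 1)
  th2 <- sum(abs(x[-(1:2)] - x[-((n - 1):n)])) / (n - 2)
  mn <- min(x)
  mx <- max(x)
  c(f1 = mu, f2 = sig, f3 = th1,
    f4 = if (sig > 0) th1 / sig else 0,
    f5 = th2,
    f6 = if (sig > 0) th2 / sig else 0,
    f7 = mn, f8 = mx, f9 = mn / n, f10 = mx / n,
    f11 = mx - mn, f12 = median(x))
}

#' Names of the 36 feature columns
#'
#' Channel-major order: `bvp_f1..bvp_f12`, `ecg_f1..ecg_f12`,
#' `scl_f1..scl_f12`.
#'
#' @param channels Channels to include.
#' @return Character vector.
#' @export
feature_names <- function(channels = c("bvp", "ecg", "scl")) {
  as.vector(t(outer(channels, paste0("f", 1:12), paste, sep = "_")))
}

#' Extract the feature matrix of a cohort
#'
#' Preprocesses every trial, segments the analysed span of each channel
#' into sliding windows, and computes the 12 statistical features per
#' channel and window. One row per (trial, window): `#trials x 10` rows at
#' default windowing, 36 feature columns plus label and provenance.
#'
#' @param trials Trial tibble from [simulate_cohort()] or [read_dataset()].
#' @param preprocess A [preprocess_config()]; note the BVP band must be
#'   representable at the trials' sampling rate (see
#'   [default_pipeline_config()]).
#' @param windows A [window_config()].
#' @return A tibble with provenance columns (`subject_id`, `day_index`,
#'   `session_index`, `trial_index`, `window_index`), the `level` label and
#'   the 36 feature columns of [feature_names()].
#' @export
extract_features <- function(trials,
                             preprocess = preprocess_config(bvp_band_hz = c(0.5, 8)),
                             windows = window_config()) {
  if (nrow(trials) == 0) abort("empty trial collection")
  pp <- preprocess_trials(trials, preprocess)
  fs <- pp$fs[1]
  dur <- length(pp$bvp[[1]]) / fs
  nw <- n_windows(windows)
  feats <- vector("list", nrow(pp))
  for (i in seq_len(nrow(pp))) {
    wb <- segment_windows(pp$bvp[[i]], fs, windows, dur)
    we <- segment_windows(pp$ecg[[i]], fs, windows, dur)
    ws <- segment_windows(pp$scl[[i]], pp$scl_fs[i], windows, dur)
    m <- matrix(0, nw, 36)
    for (w in seq_len(nw)) {
      m[w, ] <- c(extract_window_features(wb[[w]]),
                  extract_window_features(we[[w]]),
                  extract_window_features(ws[[w]]))
    }
    colnames(m) <- feature_names()
    feats[[i]] <- tibble::tibble(
      subject_id = pp$subject_id[i], day_index = pp$day_index[i],
      session_index = pp$session_index[i], trial_index = i,
      window_index = seq_len(nw), level = pp$level[i],
      tibble::as_tibble(m)
    )
  }
  dplyr::bind_rows(feats)
}

#' Min-max feature normalisation
#'
#' `minmax_fit()` records per-feature minima and maxima on the training
#' rows only; `minmax_apply()` rescales any matrix with those parameters,
#' `(F - Vmin) / (Vmax - Vmin)`, so training columns lie in `[0, 1]`
#' (held-out rows may fall outside). A constant column maps to 0.
#'
#' @param data Tibble or matrix containing the feature columns.
#' @param cols Feature column names; defaults to every `*_f*` column
#'   present (or all columns of a plain matrix).
#' @return `minmax_fit()`: a `minmax_params` tibble (`feature`, `v_min`,
#'   `v_max`); `minmax_apply()`: `data` with the feature columns rescaled.
#' @export
minmax_fit <- function(data, cols = NULL) {
  m <- feature_block(data, cols)
  structure(tibble::tibble(feature = colnames(m),
                           v_min = apply(m, 2, min),
                           v_max = apply(m, 2, max)),
            class = c("minmax_params", "tbl_df", "tbl", "data.frame"))
}

#' @rdname minmax_fit
#' @param params A `minmax_params` object fitted on training rows.
#' @export
minmax_apply <- function(data, params) {
  m <- feature_block(data, params$feature)
  rng <- params$v_max - params$v_min
  scaled <- sweep(m, 2, params$v_min)
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  if (is.data.frame(data)) {
    data[params$feature] <- tibble::as_tibble(scaled)
    data
  } else {
    scaled
  }
}

# Extract the numeric feature block as a matrix.
feature_block <- function(data, cols = NULL) {
  if (is.matrix(data)) {
    m <- data
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    if (!is.null(cols)) m <- m[, cols, drop = FALSE]
    return(m)
  }
  if (is.null(cols)) {
    cols <- grep("^(bvp|ecg|scl)_f\\d+$", names(data), value = TRUE)
    if (!length(cols)) cols <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("feature columns not found: %s",
                  paste(missing, collapse = ", ")))
  }
  as.matrix(data[cols])
}
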