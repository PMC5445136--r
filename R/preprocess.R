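#' Preprocessing configuration
#'
#' Per-channel signal-conditioning settings. The BVP band edges reproduce
#' the acquisition pipeline's printed design (4th-order Butterworth
#' band-pass, gain 3, cutoffs 30--200 Hz). Note that this literal band
#' exceeds the Nyquist frequency of 256 Hz recordings and removes the
#' ~1--2 Hz pulse wave; [preprocess_bvp()] therefore refuses it at 256 Hz
#' and [default_pipeline_config()] substitutes a pulse-preserving band (see
#' the methods vignette). The ECG high-pass cutoff and the moving-average
#' spans follow standard surface-ECG / electrodermal practice.
#'
#' @param bvp_filter_order Butterworth prototype order for the BVP band-pass.
#' @param bvp_band_hz Length-2 pass band, Hz.
#' @param bvp_gain Linear gain applied after band-pass filtering.
#' @param ecg_highpass_hz High-pass cutoff removing ECG baseline drift, Hz.
#' @param ecg_moving_avg_ms ECG moving-average smoothing span, ms.
#' @param scl_moving_avg_ms SCL moving-average smoothing span, ms.
#' @param scl_downsample_factor Integer decimation factor for SCL.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(bvp_filter_order = 4L,
                              bvp_band_hz = c(30, 200),
                              bvp_gain = 3,
                              ecg_highpass_hz = 0.5,
                              ecg_moving_avg_ms = 50,
                              scl_moving_avg_ms = 500,
                              scl_downsample_factor = 2L) {
  stopifnot(length(bvp_band_hz) == 2, bvp_band_hz[1] > 0,
            bvp_band_hz[1] < bvp_band_hz[2], bvp_filter_order >= 1,
            ecg_highpass_hz > 0, scl_downsample_factor >= 1)
  structure(list(
    bvp_filter_order = as.integer(bvp_filter_order),
    bvp_band_hz = as.numeric(bvp_band_hz),
    bvp_gain = bvp_gain,
    ecg_highpass_hz = ecg_highpass_hz,
    ecg_moving_avg_ms = ecg_moving_avg_ms,
    scl_moving_avg_ms = scl_moving_avg_ms,
    scl_downsample_factor = as.integer(scl_downsample_factor)
  ), class = "preprocess_config")
}

# --- Butterworth IIR design (bilinear transform) ---------------------------
# No DSP design package ships with this stack, so the classic design is
# implemented here: analog Butterworth prototype poles, frequency prewarp,
# lowpass->lowpass/highpass/bandpass transform, bilinear transform.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients `b`, `a` (with `a[1] = 1`) of a
#' Butterworth low-pass, high-pass or band-pass filter designed by bilinear
#' transform with frequency prewarping, so the -3 dB points fall exactly at
#' the requested cutoffs. A band-pass of prototype order `n` has `2n` poles.
#'
#' @param n Prototype order.
#' @param cutoff_hz Cutoff (scalar) or band edges (length 2 for band-pass), Hz.
#' @param fs Sampling rate, Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return List with numeric vectors `b` and `a`.
#' @examples
#' hv <- butter_design(4, c(30, 200), fs = 512, type = "pass")
#' @export
butter_design <- function(n, cutoff_hz, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    abort("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  fs2 <- 2 * fs
  warped <- fs2 * tan(pi * cutoff_hz / fs)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit LP prototype poles

  if (type == "low") {
    poles <- warped * proto
    zeros <- complex(0)
    gain <- warped^n
  } else if (type == "high") {
    if (length(cutoff_hz) != 1) abort("high-pass takes a single cutoff")
    poles <- warped / proto
    zeros <- rep(0 + 0i, n)
    gain <- 1
  } else {
    if (length(cutoff_hz) != 2) abort("band-pass needs two band edges")
    bw <- warped[2] - warped[1]
    w0 <- sqrt(warped[1] * warped[2])
    pl <- proto * bw / 2
    poles <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
    zeros <- rep(0 + 0i, n)
    gain <- bw^n
  }

  # bilinear transform s -> 2 fs (z-1)/(z+1)
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(zd)) * gain_d
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Analytic Butterworth magnitude response
#'
#' Magnitude of the designed digital filter at frequency `f_hz`, evaluated
#' directly from the transfer function on the unit circle. Used as the
#' independent check of the -3 dB property in the test suite.
#'
#' @param coefs List with `b`, `a` as from [butter_design()].
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of magnitudes.
#' @export
filter_magnitude <- function(coefs, f_hz, fs) {
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    zp <- z^(seq_along(coefs$b) - 1)
    za <- z^(seq_along(coefs$a) - 1)
    Mod(sum(coefs$b * zp) / sum(coefs$a * za))
  }, numeric(1))
}

apply_iir <- function(coefs, x) {
  cpp_iir_filter(coefs$b, coefs$a, as.numeric(x))
}

# Causal running mean over a k-sample window with partial windows at the
# left edge, so a constant segment maps to that constant everywhere.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(as.numeric(x))
  s <- cumsum(as.numeric(x))
  n <- length(x)
  y <- numeric(n)
  head_n <- seq_len(min(k - 1L, n))
  y[head_n] <- s[head_n] / head_n
  if (n >= k) {
    i <- k:n
    y[i] <- (s[i] - c(0, s)[i - k + 1L]) / k
  }
  y
}

#' Preprocess a blood volume pulse trace
#'
#' Applies a single forward pass of the configured Butterworth band-pass,
#' then scales by `bvp_gain`. Length is preserved; startup transients are
#' accepted because features are computed on windows well inside the trial.
#'
#' @param raw Numeric waveform.
#' @param fs Sampling rate, Hz.
#' @param cfg A [preprocess_config()].
#' @return Numeric waveform of the same length.
#' @export
preprocess_bvp <- function(raw, fs, cfg = preprocess_config()) {
  hi <- cfg$bvp_band_hz[2]
  if (fs <= 2 * hi) {
    abort(sprintf(
      "BVP band [%g, %g] Hz exceeds the Nyquist frequency (%g Hz at fs = %g Hz); override bvp_band_hz",
      cfg$bvp_band_hz[1], hi, fs / 2, fs))
  }
  coefs <- butter_design(cfg$bvp_filter_order, cfg$bvp_band_hz, fs, "pass")
  cfg$bvp_gain * apply_iir(coefs, raw)
}

#' Preprocess an ECG trace
#'
#' High-pass filters at `ecg_highpass_hz` (2nd-order Butterworth) to remove
#' slow baseline drift, smooths with a moving average over
#' `ecg_moving_avg_ms`, then performs fiducial-anchored baseline
#' correction: R peaks are detected on the smoothed trace, the baseline is
#' sampled at the flattest point (minimum absolute amplitude) between
#' consecutive beats, linearly interpolated across the record, and
#' subtracted. A trace without detectable beats has its median subtracted.
#'
#' @inheritParams preprocess_bvp
#' @return Numeric waveform of the same length.
#' @export
preprocess_ecg <- function(raw, fs, cfg = preprocess_config()) {
  stopifnot(fs > 0)
  coefs <- butter_design(2L, cfg$ecg_highpass_hz, fs, "high")
  y <- apply_iir(coefs, raw)
  y <- moving_average(y, round(cfg$ecg_moving_avg_ms / 1000 * fs))
  y - ecg_baseline(y, fs)
}

# Piecewise-linear baseline through inter-beat fiducial points.
ecg_baseline <- function(y, fs) {
  n <- length(y)
  peaks <- find_peaks(y, min_height = 0.5 * max(abs(y), 1e-12),
                      min_dist = round(0.3 * fs))
  if (length(peaks) < 2) return(rep(median(y), n))
  fid <- integer(length(peaks) - 1)
  for (i in seq_len(length(peaks) - 1)) {
    span <- (peaks[i] + round(0.1 * fs)):(peaks[i + 1] - round(0.1 * fs))
    span <- span[span >= 1 & span <= n]
    if (!length(span)) span <- peaks[i]:peaks[i + 1]
    fid[i] <- span[which.min(abs(y[span]))]
  }
  fid <- unique(fid)
  if (length(fid) < 2) return(rep(median(y), n))
  stats::approx(fid, y[fid], xout = seq_len(n), rule = 2)$y
}

find_peaks <- function(y, min_height, min_dist) {
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Preprocess a skin conductance trace
#'
#' Moving-average smoothing over `scl_moving_avg_ms`, then decimation
#' keeping every `scl_downsample_factor`-th sample.
#'
#' @inheritParams preprocess_bvp
#' @return List with `samples` (length `floor(n / factor)`) and `fs`
#'   (the post-decimation sampling rate).
#' @export
preprocess_scl <- function(raw, fs, cfg = preprocess_config()) {
  stopifnot(fs > 0)
  y <- moving_average(raw, round(cfg$scl_moving_avg_ms / 1000 * fs))
  f <- cfg$scl_downsample_factor
  idx <- seq.int(f, length(y), by = f)
  list(samples = y[idx], fs = fs / f)
}

#' Preprocess every trial of a cohort
#'
#' Applies [preprocess_bvp()], [preprocess_ecg()] and [preprocess_scl()] to
#' each trial record, replacing the waveform list-columns and adding
#' `scl_fs`, the post-decimation SCL sampling rate.
#'
#' @param trials Trial tibble from [simulate_cohort()] / [read_dataset()].
#' @param cfg A [preprocess_config()].
#' @return The trial tibble with conditioned waveforms.
#' @export
preprocess_trials <- function(trials, cfg = preprocess_config()) {
  stopifnot(nrow(trials) > 0)
  fs <- trials$fs[1]
  if (!all(trials$fs == fs)) abort("all trials must share one sampling rate")
  hi <- cfg$bvp_band_hz[2]
  if (fs <= 2 * hi) {
    abort(sprintf(
      "BVP band [%g, %g] Hz is not representable at fs = %g Hz; pass a pulse-band override (e.g. bvp_band_hz = c(0.5, 8)) as done by default_pipeline_config()",
      cfg$bvp_band_hz[1], hi, fs))
  }
  bvp_coefs <- butter_design(cfg$bvp_filter_order, cfg$bvp_band_hz, fs, "pass")
  out <- trials
  out$bvp <- purrr::map(trials$bvp,
                        ~ cfg$bvp_gain * apply_iir(bvp_coefs, .x))
  out$ecg <- purrr::map(trials$ecg, ~ preprocess_ecg(.x, fs, cfg))
  scl <- purrr::map(trials$scl, ~ preprocess_scl(.x, fs, cfg))
  out$scl <- purrr::map(scl, "samples")
  out$scl_fs <- purrr::map_dbl(scl, "fs")
  out
}
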