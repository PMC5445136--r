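#' Plot trial waveforms by stimulus level
#'
#' Displays a window of the three channels for one trial per level
#' (matching the style of stimulus-response figures: BVP, ECG, SCL stacked,
#' one column per level).
#'
#' @param trials Trial tibble; one trial per distinct level is shown.
#' @param seconds Length of the displayed window, seconds (from the end of
#'   the trial, where the stimulus response is established).
#' @return A ggplot object.
#' @export
plot_trial_levels <- function(trials, seconds = 10) {
  picks <- trials |>
    dplyr::group_by(.data$level) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  long <- purrr::pmap_dfr(
    list(picks$level, picks$bvp, picks$ecg, picks$scl, picks$fs),
    function(level, bvp, ecg, scl, fs) {
      n <- length(bvp)
      idx <- max(1, n - round(seconds * fs) + 1):n
      t <- (idx - 1) / fs
      dplyr::bind_rows(
        tibble::tibble(level = level, channel = "BVP (% reflectance)",
                       time_s = t, value = bvp[idx]),
        tibble::tibble(level = level, channel = "ECG (uV)",
                       time_s = t, value = ecg[idx]),
        tibble::tibble(level = level, channel = "SCL (uS)",
                       time_s = t, value = scl[idx])
      )
    })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(channel ~ level, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "generation", y = "best cross-validated accuracy") +
    ggplot2::theme_minimal()
}
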