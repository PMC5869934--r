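# ggplot2 views of trials, spectral estimates and fits.

#' Plot a simulated or recorded stance trial
#'
#' Overlays platform rotation and body sway against time.
#'
#' @param object A `stance_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stance_trial <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("time_s", "ss_deg", "bs_deg")],
    cols = c("ss_deg", "bs_deg"),
    names_to = "signal", values_to = "angle_deg")
  df$signal <- factor(df$signal, levels = c("ss_deg", "bs_deg"),
                      labels = c("platform rotation", "body sway"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$angle_deg,
                                   colour = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "angle (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an identified frequency response
#'
#' Gain, phase and coherence versus frequency on the excited harmonics,
#' with logarithmic frequency and gain axes.
#'
#' @param object An `frf_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frf_estimate <- function(object, ...) {
  df <- tibble::tibble(
    freq_hz = rep(object$freq_hz, 3),
    panel = rep(c("gain", "phase (deg)", "coherence"),
                each = nrow(object)),
    value = c(object$gain, unwrap_phase_deg(object$phase_deg),
              object$coherence))
  df$panel <- factor(df$panel, levels = c("gain", "phase (deg)", "coherence"))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model fit over the identified frequency response
#'
#' @param object An `ic_fit`.
#' @param ... Unused.
#' @return A ggplot object comparing identified and fitted gain and phase.
#' @export
autoplot.ic_fit <- function(object, ...) {
  frf <- object$frf
  df <- tibble::tibble(
    freq_hz = rep(frf$freq_hz, 4),
    panel = rep(rep(c("gain", "phase (deg)"), each = nrow(frf)), 2),
    source = rep(c("identified", "fitted"), each = 2 * nrow(frf)),
    value = c(Mod(frf$response), unwrap_phase_deg(Arg(frf$response) * 180 / pi),
              Mod(frf$fitted), unwrap_phase_deg(Arg(frf$fitted) * 180 / pi)))
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$value,
                                   colour = .data$source)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, colour = NULL,
                  title = format(object$condition)) +
    ggplot2::theme_minimal()
}

# display-only phase unwrapping (the fit uses the wrapped complex ratio)
unwrap_phase_deg <- function(phase_deg) {
  out <- phase_deg
  for (i in seq_along(out)[-1]) {
    d <- out[i] - out[i - 1]
    out[i] <- out[i] - 360 * round(d / 360)
  }
  out
}
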