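# Pink (1/f) noise for sensory/motor disturbance torque.

#' Noise configuration for closed-loop simulations
#'
#' @param amplitude RMS of the disturbance torque, N m. The amplitude is
#'   meant to be held constant across experimental conditions, so that
#'   larger perturbations enjoy a better signal-to-noise ratio.
#' @param seed Integer seed for reproducible noise, or `NULL` to draw from
#'   the session RNG stream.
#' @param spectral_exponent Slope of the power spectral density on log-log
#'   axes; -1 gives pink noise.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(amplitude = 0.6, seed = NULL, spectral_exponent = -1) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || amplitude < 0)
    stop("`amplitude` must be a non-negative number")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
      stop("`seed` must be a single integer")
    seed <- as.integer(seed)
  }
  structure(list(amplitude = amplitude, seed = seed,
                 spectral_exponent = spectral_exponent),
            class = "noise_config")
}

# Internal: plain numeric vector of spectrally shaped noise.
pink_noise_vec <- function(n, fs, amplitude, spectral_exponent = -1, seed = NULL) {
  if (amplitude == 0) return(numeric(n))
  draw <- function() {
    # shape a white Gaussian spectrum by f^(exponent/2) and invert
    nfft <- n
    f <- seq(0, nfft - 1) / nfft * fs
    half <- seq(2, floor(nfft / 2) + 1)  # skip DC
    mag <- f[half]^(spectral_exponent / 2)
    x <- complex(real = stats::rnorm(length(half)),
                 imaginary = stats::rnorm(length(half))) * mag
    spec <- complex(real = numeric(nfft), imaginary = numeric(nfft))
    spec[half] <- x
    # Hermitian symmetry for a real signal
    if (nfft %% 2 == 0) spec[nfft / 2 + 1] <- complex(real = Re(spec[nfft / 2 + 1]), imaginary = 0)
    idx <- seq(2, nfft)
    spec[rev(idx)] <- Conj(spec[idx])
    y <- Re(stats::fft(spec, inverse = TRUE)) / nfft
    y <- y - mean(y)
    y * amplitude / stats::sd(y)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate pink (1/f) noise
#'
#' Produces zero-mean noise whose power spectral density follows
#' `f^spectral_exponent` (pink for -1), scaled to a target RMS amplitude.
#' Generated by shaping a white Gaussian spectrum in the frequency domain,
#' so the realisation is exactly reproducible from the seed.
#'
#' @param n Number of samples.
#' @param fs Sample rate, Hz.
#' @param cfg A [noise_config()].
#' @return A tibble with columns `time_s` and `value` (N m), with attribute
#'   `fs`.
#' @examples
#' nz <- pink_noise(2000, fs = 100, noise_config(amplitude = 1, seed = 1))
#' sd(nz$value)
#' @export
pink_noise <- function(n, fs, cfg = noise_config()) {
  stopifnot(inherits(cfg, "noise_config"))
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("`fs` must be positive")
  y <- pink_noise_vec(as.integer(n), fs, cfg$amplitude,
                      cfg$spectral_exponent, cfg$seed)
  structure(tibble::tibble(time_s = (seq_len(n) - 1) / fs, value = y), fs = fs)
}
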