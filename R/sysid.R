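# Non-parametric identification: periodic spectral averaging, frequency
# response function, coherence, and the even-harmonic nonlinearity screen.
#
# Records are cut into blocks of exactly one perturbation period and
# Fourier-transformed without windowing (blocks are exact periods, so there
# is no leakage at the harmonics). Cross- and auto-spectra are then formed
# per block and averaged: averaging raw coefficients before taking products
# would make the coherence identically 1, so the PSDs are across-block mean
# powers and the CSD the across-block mean of per-block cross-products —
# the standard estimator that decreases with noise and nonlinearity.

# internal: per-block Fourier coefficients at harmonics of 1/period
block_coefficients <- function(y, fs, period, n_blocks) {
  L <- as.integer(round(period * fs))
  expected <- L * n_blocks
  if (length(y) != expected)
    stop(sprintf("record length %d does not equal n_blocks * period * fs = %d samples",
                 length(y), expected))
  blocks <- matrix(y, nrow = L, ncol = n_blocks)
  coef <- stats::mvfft(blocks) / L
  n_harm <- floor(L / 2)
  list(freq_hz = (0:n_harm) / period,
       coef = t(coef[1:(n_harm + 1), , drop = FALSE]))  # n_blocks x harmonics
}

#' Segment a record into period blocks and transform to the frequency domain
#'
#' Cuts a uniformly sampled record into `n_blocks` consecutive blocks of
#' one perturbation period each and returns the discrete Fourier
#' coefficients of every block at the harmonics of `1/period`, together
#' with their across-block mean (the periodic part of the signal).
#'
#' @param y Numeric record, or a `stance_trial` column extracted by name
#'   via `column`.
#' @param fs Sample rate, Hz.
#' @param period Block length, s (one perturbation period).
#' @param n_blocks Number of blocks; `length(y)` must equal
#'   `n_blocks * period * fs` exactly.
#' @return A list with `freq_hz` (harmonics from DC up to the Nyquist),
#'   `coef` (complex matrix, `n_blocks` rows), and `mean_coef` (across-block
#'   mean coefficients). Coefficients are normalised so a cosine of
#'   amplitude A appears with modulus A/2.
#' @export
segment_spectra <- function(y, fs, period, n_blocks) {
  if (!is.numeric(y) || any(!is.finite(y))) stop("`y` must be finite numeric")
  if (n_blocks < 1) stop("`n_blocks` must be at least 1")
  bc <- block_coefficients(y, fs, period, n_blocks)
  bc$mean_coef <- colMeans(bc$coef)
  bc
}

# internal: averaged cross/auto spectra of a trial at all harmonics
cross_spectra <- function(ss, bs, fs, period, n_blocks) {
  S <- block_coefficients(ss, fs, period, n_blocks)
  B <- block_coefficients(bs, fs, period, n_blocks)
  list(freq_hz = S$freq_hz,
       csd = colMeans(Conj(S$coef) * B$coef),
       psd_ss = colMeans(Mod(S$coef)^2),
       psd_bs = colMeans(Mod(B$coef)^2))
}

# harmonic numbers of the excited (odd) and unexcited (even) lines <= f_max
harmonic_sets <- function(period, f_max) {
  m_max <- floor(f_max * period + 1e-9)
  list(odd = seq(1L, m_max, by = 2L),
       even = if (m_max >= 2L) seq(2L, m_max, by = 2L) else integer(0))
}

resolve_trial <- function(x, ss, bs, fs, period) {
  if (inherits(x, "stance_trial")) {
    list(ss = x$ss_deg, bs = x$bs_deg, fs = attr(x, "fs"),
         period = if (is.null(period)) attr(x, "period") else period)
  } else {
    if (is.null(ss) || is.null(bs) || is.null(fs) || is.null(period))
      stop("supply a `stance_trial`, or `ss`, `bs`, `fs` and `period`")
    list(ss = ss, bs = bs, fs = fs, period = period)
  }
}

#' Estimate the frequency response function and coherence of a trial
#'
#' Forms the complex sensitivity of body sway to platform rotation at the
#' excited (odd) harmonics of the perturbation,
#' `H(f) = CSD_ss,bs(f) / PSD_ss(f)`, with the spectra obtained by
#' averaging across period blocks, along with the magnitude-squared
#' coherence `|CSD|^2 / (PSD_ss PSD_bs)` and the even-harmonic power
#' fraction of the sway (a nonlinearity screen).
#'
#' @param x A `stance_trial` from [simulate_closed_loop()] or
#'   [read_trial()]; alternatively pass `ss`, `bs`, `fs`, `period`
#'   explicitly.
#' @param ss,bs Platform rotation and body sway records (same units).
#' @param fs Sample rate, Hz.
#' @param period Perturbation period, s.
#' @param f_max Upper analysis frequency, Hz.
#' @param n_blocks Number of period blocks; default the full record.
#' @return An `frf_estimate`: a tibble with one row per excited frequency
#'   and columns `freq_hz`, `response` (complex), `gain`, `phase_deg`,
#'   `coherence`, `csd`, `psd_ss`, `psd_bs`; attributes `n_blocks`,
#'   `period`, `f_max`, `even_fraction_pct`.
#' @export
estimate_frf <- function(x = NULL, ss = NULL, bs = NULL, fs = NULL,
                         period = NULL, f_max = 2.05, n_blocks = NULL) {
  tr <- resolve_trial(x, ss, bs, fs, period)
  L <- as.integer(round(tr$period * tr$fs))
  if (is.null(n_blocks)) n_blocks <- length(tr$ss) %/% L
  if (length(tr$ss) != length(tr$bs))
    stop("`ss` and `bs` must have the same length")
  cs <- cross_spectra(tr$ss, tr$bs, tr$fs, tr$period, n_blocks)
  hs <- harmonic_sets(tr$period, f_max)
  idx <- hs$odd + 1L
  dead <- which(cs$psd_ss[idx] <= 1e-12 * max(cs$psd_ss[idx]))
  if (length(dead))
    stop(sprintf("perturbation has no power at excited frequency %g Hz",
                 cs$freq_hz[idx[dead[1]]]))
  h <- cs$csd[idx] / cs$psd_ss[idx]
  coh <- Mod(cs$csd[idx])^2 / (cs$psd_ss[idx] * cs$psd_bs[idx])
  coh[cs$psd_bs[idx] <= 1e-12 * max(cs$psd_bs[idx])] <- NA_real_
  even_pct <- even_fraction_from_psd(cs$psd_bs, hs)
  out <- tibble::tibble(
    freq_hz = cs$freq_hz[idx],
    response = h,
    gain = Mod(h),
    phase_deg = Arg(h) * 180 / pi,
    coherence = coh,
    csd = cs$csd[idx],
    psd_ss = cs$psd_ss[idx],
    psd_bs = cs$psd_bs[idx]
  )
  structure(out, class = c("frf_estimate", class(out)),
            n_blocks = n_blocks, period = tr$period, f_max = f_max,
            even_fraction_pct = even_pct)
}

#' Coherence between perturbation and sway at the excited frequencies
#'
#' Magnitude-squared coherence per excited frequency, from block-averaged
#' spectra. With `L` independent blocks and no true relation the estimate
#' is biased upward to about `1/L`; it always lies in `[0, 1]`.
#'
#' @inheritParams estimate_frf
#' @return A tibble with columns `freq_hz` and `coherence` (`NA` where the
#'   sway has no power at a frequency).
#' @export
coherence <- function(x = NULL, ss = NULL, bs = NULL, fs = NULL,
                      period = NULL, f_max = 2.05, n_blocks = NULL) {
  tr <- resolve_trial(x, ss, bs, fs, period)
  L <- as.integer(round(tr$period * tr$fs))
  if (is.null(n_blocks)) n_blocks <- length(tr$ss) %/% L
  if (n_blocks < 2)
    stop("coherence needs at least 2 blocks for a non-degenerate estimate")
  cs <- cross_spectra(tr$ss, tr$bs, tr$fs, tr$period, n_blocks)
  hs <- harmonic_sets(tr$period, f_max)
  idx <- hs$odd + 1L
  coh <- Mod(cs$csd[idx])^2 / (cs$psd_ss[idx] * cs$psd_bs[idx])
  coh[cs$psd_bs[idx] <= 1e-12 * max(cs$psd_bs[idx])] <- NA_real_
  tibble::tibble(freq_hz = cs$freq_hz[idx], coherence = coh)
}

even_fraction_from_psd <- function(psd, hs) {
  tot <- sum(psd[c(hs$odd, hs$even) + 1L])
  if (tot <= 0) stop("sway record has zero power on the analysed harmonics")
  100 * sum(psd[hs$even + 1L]) / tot
}

#' Even-harmonic power fraction of the sway record
#'
#' Percentage of total sway power (over all nonzero harmonics up to
#' `f_max`, DC excluded) that falls on the even harmonics, where the
#' ternary perturbation injects no power. High values indicate nonlinear
#' distortion; linear responses leave the even lines at the noise floor.
#'
#' @param x A `stance_trial`, or pass `bs`, `fs`, `period` explicitly.
#' @param bs Body-sway record.
#' @inheritParams estimate_frf
#' @return Scalar percentage.
#' @export
even_harmonic_fraction <- function(x = NULL, bs = NULL, fs = NULL,
                                   period = NULL, f_max = 2.05,
                                   n_blocks = NULL) {
  if (inherits(x, "stance_trial")) {
    bs <- x$bs_deg; fs <- attr(x, "fs")
    if (is.null(period)) period <- attr(x, "period")
  }
  if (is.null(bs) || is.null(fs) || is.null(period))
    stop("supply a `stance_trial`, or `bs`, `fs` and `period`")
  L <- as.integer(round(period * fs))
  if (is.null(n_blocks)) n_blocks <- length(bs) %/% L
  B <- block_coefficients(bs, fs, period, n_blocks)
  psd <- colMeans(Mod(B$coef)^2)
  even_fraction_from_psd(psd, harmonic_sets(period, f_max))
}
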