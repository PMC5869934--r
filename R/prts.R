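# Pseudorandom ternary sequence (PRTS) perturbation design.
#
# A maximal-length shift register over GF(3) emits a ternary symbol stream
# of period 3^n - 1. Mapped to velocities {-v, 0, +v} and integrated, it
# yields a periodic platform-rotation waveform whose power sits exclusively
# on odd harmonics of the fundamental 1/period: the register sequence is
# antisymmetric over half a period (s[k + P/2] = -s[k] in the signed
# mapping), which cancels all even harmonics.

# Frozen feedback taps for the 4-stage register: a_n = a_{n-1} + a_{n-4}
# (mod 3), i.e. the recurrence of x^4 - x^3 - 1 over GF(3). Verified
# maximal (period 80, all 80 nonzero register states visited once).
PRTS_TAPS_4 <- c(1L, 0L, 0L, 1L)

# Exhaustive search for maximal-length taps for other register sizes.
find_maximal_taps <- function(n_stages) {
  if (n_stages == 4L) return(PRTS_TAPS_4)
  target <- 3L^n_stages - 1L
  grid <- as.matrix(expand.grid(rep(list(0:2), n_stages)))
  # last tap must be nonzero or the recurrence degenerates
  grid <- grid[grid[, n_stages] != 0, , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    taps <- as.integer(grid[i, ])
    s <- c(1L, integer(n_stages - 1))
    n <- 0L
    repeat {
      s <- c(sum(taps * s) %% 3L, s[-n_stages])
      n <- n + 1L
      if (all(s == c(1L, integer(n_stages - 1)))) break
      if (n > target) break
    }
    if (n == target) return(taps)
  }
  stop(sprintf("no maximal-length ternary register of %d stages found", n_stages))
}

#' Generate one period of a pseudorandom ternary sequence
#'
#' Runs a linear-feedback shift register over the three-element field with
#' a primitive feedback polynomial, producing a maximal-length ternary
#' symbol sequence: one period visits every nonzero register state exactly
#' once and therefore contains `3^n_stages - 1` symbols (80 for the default
#' four-stage register).
#'
#' @param n_stages Number of register stages (>= 2); 4 gives the classic
#'   80-state sequence.
#' @param seed_state Initial register contents, a vector of `n_stages`
#'   ternary digits, not all zero. The seed only rotates the sequence.
#' @param taps Feedback coefficients; by default the frozen maximal-length
#'   taps for `n_stages = 4`, or an exhaustive search for other sizes.
#' @return Integer vector of symbols in `{0, 1, 2}` of length
#'   `3^n_stages - 1`, with attributes `taps` and `n_stages`.
#' @examples
#' length(prts_states(4)) # 80
#' @export
prts_states <- function(n_stages = 4L, seed_state = NULL, taps = NULL) {
  if (!is.numeric(n_stages) || length(n_stages) != 1 || n_stages < 2 ||
      n_stages != round(n_stages))
    stop("`n_stages` must be an integer >= 2")
  n_stages <- as.integer(n_stages)
  if (is.null(seed_state)) seed_state <- c(1L, integer(n_stages - 1))
  seed_state <- as.integer(seed_state)
  if (length(seed_state) != n_stages || any(!seed_state %in% 0:2))
    stop("`seed_state` must be ", n_stages, " ternary digits")
  if (all(seed_state == 0L))
    stop("`seed_state` must not be all zero (degenerate register)")
  if (is.null(taps)) taps <- find_maximal_taps(n_stages)
  taps <- as.integer(taps)
  period <- 3L^n_stages - 1L
  out <- integer(period)
  s <- seed_state
  for (k in seq_len(period)) {
    out[k] <- s[n_stages]
    s <- c(sum(taps * s) %% 3L, s[-n_stages])
  }
  structure(out, taps = taps, n_stages = n_stages)
}

#' Integrate a ternary symbol sequence into a platform-rotation waveform
#'
#' Maps the symbols to angular velocities `{0, +v, -v}` (symbol 0 -> 0,
#' 1 -> +v, 2 -> -v), holds each for `dt_state` seconds, integrates
#' cumulatively to a rotation angle, removes the mean over one period, and
#' scales the result so its peak-to-peak amplitude equals `amplitude_pp`
#' degrees.
#'
#' @param states Ternary symbol vector, e.g. from [prts_states()].
#' @param amplitude_pp Peak-to-peak rotation amplitude, degrees (> 0).
#' @param dt_state Duration of each symbol, s (default 0.25 s, giving a
#'   20 s period for the 80-state sequence).
#' @param fs Output sample rate, Hz; `fs * dt_state` must be an integer so
#'   each symbol spans a whole number of samples.
#' @return A `prts_signal`: a tibble with one period of `time_s`,
#'   `velocity_deg_s`, `position_deg`, carrying attributes `states`,
#'   `dt_state`, `period`, `fs`, `amplitude_pp`.
#' @examples
#' sig <- prts_rotation(prts_states(4), amplitude_pp = 1)
#' attr(sig, "period") # 20 s
#' @export
prts_rotation <- function(states, amplitude_pp, dt_state = 0.25, fs = 1000) {
  states <- as.integer(states)
  if (any(!states %in% 0:2)) stop("`states` must contain only 0, 1, 2")
  if (!is.numeric(amplitude_pp) || length(amplitude_pp) != 1 ||
      !is.finite(amplitude_pp) || amplitude_pp <= 0)
    stop("`amplitude_pp` must be a positive number of degrees")
  spp <- fs * dt_state
  if (abs(spp - round(spp)) > 1e-9)
    stop(sprintf("fs * dt_state = %g is not an integer: each symbol must span a whole number of samples", spp))
  spp <- as.integer(round(spp))
  period <- length(states) * dt_state
  vel <- rep(c(0, 1, -1)[states + 1L], each = spp)     # unit-velocity waveform
  # position at each sample instant: integral of the velocity held over the
  # preceding intervals, so pos[k+1] - pos[k] = vel[k] / fs exactly
  pos <- (cumsum(vel) - vel) / fs
  pos <- pos - mean(pos)
  ptp <- max(pos) - min(pos)
  if (ptp > 0) {
    scale <- amplitude_pp / ptp
  } else {
    scale <- 1  # degenerate all-zero sequence: flat zero position
  }
  pos <- pos * scale
  vel <- vel * scale
  n <- length(pos)
  out <- tibble::tibble(time_s = (seq_len(n) - 1) / fs,
                        velocity_deg_s = vel, position_deg = pos)
  structure(out, class = c("prts_signal", class(out)),
            states = states, dt_state = dt_state, period = period,
            fs = fs, amplitude_pp = if (ptp > 0) amplitude_pp else 0)
}

#' Excited (odd-harmonic) analysis frequencies
#'
#' The ternary perturbation carries power only at odd multiples of its
#' fundamental `1/period`; these are the frequencies at which the response
#' is analysed.
#'
#' @param period Perturbation period, s.
#' @param f_max Upper band edge, Hz (inclusive).
#' @return Increasing numeric vector of odd harmonics of `1/period` up to
#'   `f_max`; for a 20 s period and `f_max = 2.05` these are 0.05, 0.15,
#'   ..., 2.05 Hz (21 frequencies).
#' @export
excited_frequencies <- function(period = 20, f_max = 2.05) {
  if (!is.numeric(period) || length(period) != 1 || period <= 0)
    stop("`period` must be positive")
  f0 <- 1 / period
  if (!is.numeric(f_max) || length(f_max) != 1 || f_max < f0 - 1e-12)
    stop("`f_max` must be at least the fundamental 1/period")
  m_max <- floor(f_max / f0 + 1e-9)
  m <- seq(1L, m_max, by = 2L)
  m * f0
}
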