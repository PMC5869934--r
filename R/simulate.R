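# Time-domain closed-loop simulation of the independent-channel model.

# polynomial product, coefficients in ascending powers
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  out
}

#' Closed-loop stability check
#'
#' Verifies that a parameter set yields a stable upright equilibrium:
#' the reflexive stiffness must exceed the gravitational stiffness
#' (`K_P > m g h`), and every root of the closed-loop characteristic
#' polynomial — with the delay replaced by its Pade(2,2) rational
#' approximation — must lie in the left half plane.
#'
#' @param params An [ic_parameters()] object.
#' @return `TRUE` invisibly if stable; otherwise an error.
#' @export
check_stability <- function(params) {
  stopifnot(inherits(params, "ic_parameters"))
  a <- params$anthropometry
  mgh <- grav_stiffness(params)
  if (params$K_P <= mgh)
    stop("unstable parameter set: K_P must exceed the gravitational stiffness m*g*h")
  tau <- params$tau_D
  # Pade(2,2): exp(-tau s) ~ P(s)/Q(s), P(s) = Q(-s)
  Q <- c(1, tau / 2, tau^2 / 12)
  P <- c(1, -tau / 2, tau^2 / 12)
  A <- c(1, params$tau_F)                 # tau_F s + 1
  B <- c(-mgh, 0, a$inertia)              # J s^2 - mgh
  C <- c(params$K_P, params$K_D)          # K_P + K_D s
  char <- polymul(polymul(Q, A), B)
  t2 <- -params$K_F * polymul(polymul(C, P), B)
  t3 <- polymul(polymul(C, P), A)
  n <- max(length(char), length(t2), length(t3))
  pad <- function(x) c(x, numeric(n - length(x)))
  char <- pad(char) + pad(t2) + pad(t3)
  r <- polyroot(char)
  if (any(Re(r) >= -1e-9))
    stop(sprintf("unstable parameter set: closed-loop pole at %.4g + %.4gi",
                 Re(r[which.max(Re(r))]), Im(r[which.max(Re(r))])))
  invisible(TRUE)
}

# Periodic steady-state of the noise-free loop, used to start simulations on
# the periodic orbit: harmonic superposition of the closed-loop response to
# one period of the platform waveform. Returns the initial state vector and
# the pre-trial torque-command buffer.
steady_state_start <- function(params, pos_rad_period, fs, d_samples, f_cut = 10) {
  L <- length(pos_rad_period)
  period <- L / fs
  U <- stats::fft(pos_rad_period) / L
  m_max <- min(floor(f_cut * period), floor(L / 2) - 1)
  m <- seq_len(m_max)
  keep <- m[Mod(U[m + 1]) > 1e-15]
  if (!length(keep)) {
    return(list(state = c(0, 0, 0), buffer = numeric(d_samples)))
  }
  fm <- keep / period
  w <- 2 * pi * fm
  H <- closed_loop_sensitivity(params, fm)
  Th <- H * U[keep + 1]                                   # sway coefficients
  a <- params$anthropometry
  Tq <- (a$inertia * (1i * w)^2 - grav_stiffness(params)) * Th  # torque coefficients
  Tf <- params$K_F / (params$tau_F * 1i * w + 1) * Tq
  sum2re <- function(coef, phase = 1) sum(2 * Re(coef * phase))
  state <- c(sum2re(Th), sum2re(1i * w * Th), sum2re(Tf))
  # buffer entry j (0-based) is the command at pre-trial sample (j - d)*dt,
  # i.e. the steady-state torque at time j*dt (command leads torque by tau_D)
  buffer <- vapply(seq_len(d_samples) - 1, function(j)
    sum(2 * Re(Tq * exp(1i * w * j / fs))), numeric(1))
  list(state = state, buffer = buffer)
}

#' Simulate a perturbed-stance trial
#'
#' Integrates the independent-channel stance loop in the time domain:
#' `J theta'' = m g h theta + T + d(t)` with the torque `T` produced by a PD
#' controller acting, after a lumped delay `tau_D`, on the sensory error
#' `e = W_p (SS - BS) - (1 - W_p) BS + FF(T)` (earth-fixed surround, so the
#' visual and vestibular channels both sense `-BS`), `FF` a first-order
#' low-pass positive torque feedback, and `d(t)` a pink-noise disturbance
#' torque. Integration is fixed-step 4th-order Runge-Kutta at the sample
#' rate with the delay as a sample buffer; the simulation starts on the
#' periodic orbit of the noise-free loop (computed by harmonic
#' superposition) and one additional warm-up period is simulated and
#' discarded before the analysed record begins.
#'
#' @param params An [ic_parameters()] object; checked for closed-loop
#'   stability before integrating.
#' @param perturbation A `prts_signal` from [prts_rotation()].
#' @param noise A [noise_config()]; amplitude 0 gives a noise-free trial.
#' @param n_periods Number of analysed perturbation periods (default 6,
#'   giving a 2 min trial for the 20 s sequence).
#' @param start `"steady"` (default) starts on the periodic orbit;
#'   `"rest"` starts from the upright equilibrium with zero state.
#' @param fall_rad Sway magnitude treated as a fall, rad.
#' @return A `stance_trial`: a tibble with columns `time_s`, `ss_deg`,
#'   `bs_deg`, `torque_nm` (applied, i.e. delayed, torque) and `cmd_nm`
#'   (commanded torque before the delay), with attributes `fs`, `period`,
#'   `n_periods`, `params_true`, `condition`, `noise`, `perturbation`.
#' @export
simulate_closed_loop <- function(params, perturbation,
                                 noise = noise_config(amplitude = 0),
                                 n_periods = 6,
                                 start = c("steady", "rest"),
                                 fall_rad = 0.5) {
  stopifnot(inherits(params, "ic_parameters"),
            inherits(perturbation, "prts_signal"),
            inherits(noise, "noise_config"))
  start <- match.arg(start)
  check_stability(params)
  fs <- attr(perturbation, "fs")
  period <- attr(perturbation, "period")
  Lp <- nrow(perturbation)

  d_real <- params$tau_D * fs
  d <- as.integer(round(d_real))
  if (abs(d_real - d) > 1e-9)
    warning(sprintf("tau_D * fs = %.6g snapped to %d samples", d_real, d))
  if (d < 1)
    stop("tau_D must span at least one sample at this rate (tau_D * fs >= 1)")

  n_total <- (n_periods + 1L) * Lp
  deg2rad <- pi / 180
  pos_rad <- rep(perturbation$position_deg, n_periods + 1L) * deg2rad
  vel_rad <- rep(perturbation$velocity_deg_s, n_periods + 1L) * deg2rad
  nz <- pink_noise_vec(n_total, fs, noise$amplitude, noise$spectral_exponent,
                       noise$seed)

  if (start == "steady") {
    ss0 <- steady_state_start(params, perturbation$position_deg * deg2rad, fs, d)
  } else {
    ss0 <- list(state = c(0, 0, 0), buffer = numeric(d))
  }

  # the integrator buffers only the smooth part of the command; remove the
  # platform feedthrough (evaluated at the buffer's own sample times) from
  # the steady-state command values
  if (d > 0 && length(ss0$buffer)) {
    j <- seq_len(d) - 1L
    idx <- ((j - d) %% Lp) + 1L
    ft <- params$W_p * (params$K_P * perturbation$position_deg[idx] +
                        params$K_D * perturbation$velocity_deg_s[idx]) * deg2rad
    ss0$buffer <- ss0$buffer - ft
  }

  a <- params$anthropometry
  res <- simulate_ic_loop(pos_rad, vel_rad, nz, fs,
                          params$W_p, params$K_P, params$K_D,
                          params$tau_F, params$K_F, d, Lp,
                          a$inertia, grav_stiffness(params),
                          ss0$state, ss0$buffer, fall_rad)
  if (res$fall_at > 0)
    stop(sprintf("fall: |body sway| exceeded %.2g rad at t = %.3f s",
                 fall_rad, (res$fall_at - 1) / fs))

  keep <- (Lp + 1L):n_total
  n <- length(keep)
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1) / fs,
    ss_deg = pos_rad[keep] / deg2rad,
    bs_deg = res$theta[keep] / deg2rad,
    torque_nm = res$torque[keep],
    cmd_nm = res$cmd[keep]
  )
  structure(out, class = c("stance_trial", class(out)),
            fs = fs, period = period, n_periods = n_periods,
            params_true = params, condition = attr(params, "condition"),
            noise = noise, perturbation = perturbation)
}

#' Simulate the full four-condition study
#'
#' Runs one trial per experimental condition (two perturbation amplitudes
#' crossed with eyes open/closed), sharing a single noise amplitude and
#' deriving a distinct sub-seed per condition from the configured seed.
#'
#' @param params_by_condition Named list of [ic_parameters()] objects, each
#'   carrying a `condition` attribute; default [study_parameters()]. All
#'   four conditions must be present, and eyes-closed sets must have
#'   `W_vis = 0`.
#' @param noise A [noise_config()] shared by all conditions.
#' @param fs Sample rate, Hz.
#' @param n_periods Analysed perturbation periods per trial.
#' @return Named list of `stance_trial` objects.
#' @export
generate_study_dataset <- function(params_by_condition = study_parameters(),
                                   noise = noise_config(amplitude = 0.6, seed = 1L),
                                   fs = 1000, n_periods = 6) {
  stopifnot(is.list(params_by_condition))
  conds <- purrr::map(params_by_condition, attr, "condition")
  if (any(purrr::map_lgl(conds, is.null)))
    stop("every parameter set must carry a `condition` attribute")
  key <- purrr::map_chr(conds, ~ paste0(.x$amplitude_deg, "_", .x$eyes))
  need <- c("0.5_open", "1_open", "0.5_closed", "1_closed")
  missing <- setdiff(need, key)
  if (length(missing))
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  for (i in seq_along(params_by_condition)) {
    p <- params_by_condition[[i]]
    if (conds[[i]]$eyes == "closed" && p$W_vis != 0)
      stop(sprintf("condition %s: eyes-closed parameter sets must have W_vis = 0", key[i]))
  }
  states <- prts_states(4)
  purrr::imap(params_by_condition, function(p, nm) {
    i <- match(nm, names(params_by_condition))
    cond <- attr(p, "condition")
    pert <- prts_rotation(states, amplitude_pp = cond$amplitude_deg, fs = fs)
    sub <- noise
    if (!is.null(noise$seed)) sub$seed <- noise$seed + i
    simulate_closed_loop(p, pert, sub, n_periods = n_periods)
  })
}
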