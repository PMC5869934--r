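# Shared fixtures and independent oracles for the test suite.

test_anthro <- function() winter_anthropometry(77.7, 1.79)

robot_anthro <- function() anthropometry(mass = 51, com_height = 0.97, inertia = 40)

# quick valid parameter set on the default body
test_params <- function(W_p = 0.5, kp = 1.6, kd = 0.35, tau_D = 0.15,
                        tau_F = 15, K_F = 8e-4, anthro = test_anthro()) {
  mgh <- grav_stiffness(anthro)
  ic_parameters(anthro, W_p = W_p, K_P = kp * mgh, K_D = kd * mgh,
                tau_D = tau_D, tau_F = tau_F, K_F = K_F)
}

# Independent oracle for the closed-loop sensitivity: direct complex
# arithmetic written from the loop equations, sharing no code with the
# package implementation.
oracle_sensitivity <- function(m, h, J, g, W_p, K_P, K_D, tau_D, tau_F, K_F, f) {
  s <- complex(real = 0, imaginary = 2 * pi * f)
  bd <- 1 / (J * s * s - m * g * h)
  nc <- K_P + K_D * s
  td <- exp(-tau_D * s)
  ff <- K_F / (tau_F * s + 1)
  (W_p * nc * td * bd) / (1 - ff * nc * td + nc * td * bd)
}

# draw a stable physiological parameter set (deterministic given the RNG
# state); resamples until the stability check passes
draw_physio_params <- function(anthro = test_anthro()) {
  mgh <- grav_stiffness(anthro)
  repeat {
    p <- try(ic_parameters(
      anthro,
      W_p = runif(1, 0.2, 0.8),
      K_P = runif(1, 1.2, 2.5) * mgh,
      K_D = runif(1, 0.25, 0.5) * mgh,
      tau_D = round(runif(1, 0.08, 0.25), 3),  # on the 1 kHz sample grid
      tau_F = runif(1, 5, 30),
      K_F = runif(1, 3e-4, 2e-3)), silent = TRUE)
    if (inherits(p, "try-error")) next
    ok <- tryCatch({ check_stability(p); TRUE }, error = function(e) FALSE)
    if (ok) return(p)
  }
}

free_param_vec <- function(p) {
  unlist(ic_parameters_flatten(p)[c("W_p", "K_P", "K_D", "tau_D", "tau_F", "K_F")])
}

# simulate + identify + fit round trip at moderate cost
recover_params <- function(truth, amplitude_pp = 1, fs = 1000,
                           noise_amp = 0, seed = NULL) {
  pert <- prts_rotation(prts_states(4), amplitude_pp = amplitude_pp, fs = fs)
  trial <- simulate_closed_loop(truth, pert,
                                noise_config(amplitude = noise_amp, seed = seed))
  frf <- estimate_frf(trial)
  cond <- condition(amplitude_pp, if (truth$W_vis == 0) "closed" else "open")
  suppressWarnings(fit_ic_model(frf, truth$anthropometry, cond))
}
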