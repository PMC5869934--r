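# Weighted frequency-domain fitting and its diagnostics.

test_that("the prediction error matches hand-evaluated cases", {
  p <- test_params()
  f <- excited_frequencies()
  h <- closed_loop_sensitivity(p, f)
  # perfect model: zero residual
  expect_equal(prediction_error(h, rep(1, 21), p, f), rep(0, 21))
  # magnitude ratio 2 at the DC limit with unit weight: ln 2
  eps <- prediction_error(2 * closed_loop_sensitivity(p, 0), 1, p, 0)
  expect_equal(eps, log(2))
  # pure 90 degree phase mismatch at f = 1: weight 1/2 times pi/2
  h1 <- closed_loop_sensitivity(p, 1)
  eps <- prediction_error(h1 * exp(1i * pi / 2), 1, p, 1)
  expect_equal(eps, pi / 4)
  expect_error(prediction_error(0 + 0i, 1, p, 1), "singularity")
  expect_error(prediction_error(h1, 1.5, p, 1), "0, 1")
})

test_that("the cost is the mean squared residual", {
  expect_equal(fit_cost(rep(0, 5)), 0)
  expect_equal(fit_cost(c(1, 1, 1, 1)), 1)
  expect_equal(fit_cost(c(3, 4)), 12.5)
  expect_error(fit_cost(numeric(0)), "empty")
})

test_that("weights are derived per visual condition", {
  expect_equal(derive_weights(1, condition(0.5, "closed")),
               c(W_vis = 0, W_ves = 0))
  expect_equal(derive_weights(0.3, condition(0.5, "closed")),
               c(W_vis = 0, W_ves = 0.7))
  expect_equal(derive_weights(0.3, condition(0.5, "open")),
               c(W_visves = 0.7))
  expect_error(derive_weights(1.3, condition(0.5, "open")), "0, 1")
})

test_that("VAF matches its closed forms", {
  x <- sin(1:100)
  expect_equal(vaf(x, x), 100)
  expect_equal(vaf(rep(0, 10), rep(2, 10)), 0)
  expect_equal(vaf(rep(1, 10), rep(2, 10)), 75)
  expect_error(vaf(x, rep(0, 100)), "zero power")
})

test_that("standard errors follow the covariance structure", {
  expect_equal(sem_from_jacobian(diag(4), 0), rep(0, 4))
  expect_equal(sem_from_jacobian(diag(3), 4), rep(2, 3))
  withr::local_seed(1)
  J <- matrix(rnorm(60), 20, 3)
  s1 <- sem_from_jacobian(J, 2)
  J2 <- J; J2[, 2] <- 10 * J2[, 2]
  s2 <- sem_from_jacobian(J2, 2)
  expect_equal(s2[2], s1[2] / 10)
  expect_warning(s <- sem_from_jacobian(cbind(J[, 1], J[, 1]), 1),
                 "identifiable")
  expect_true(all(is.na(s)))
})

test_that("parameter comparison is a mean relative difference", {
  p <- test_params()
  expect_equal(compare_parameters(p, p), 0)
  q <- as_ic_parameters(purrr::map_if(ic_parameters_flatten(p), is.numeric,
                                      ~ .x)) # identical rebuild
  expect_equal(compare_parameters(q, p), 0)
  a <- p$anthropometry
  p110 <- ic_parameters(a, W_p = min(1, 1.1 * p$W_p), K_P = 1.1 * p$K_P,
                        K_D = 1.1 * p$K_D, tau_D = 1.1 * p$tau_D,
                        tau_F = 1.1 * p$tau_F, K_F = 1.1 * p$K_F,
                        W_vis = 0, W_ves = 1 - min(1, 1.1 * p$W_p))
  expect_equal(compare_parameters(p110, p), 10, tolerance = 1e-9)
  # asymmetric in its arguments
  expect_false(isTRUE(all.equal(compare_parameters(p110, p),
                                compare_parameters(p, p110))))
  # zero reference parameters are excluded with a warning
  pz <- ic_parameters(a, W_p = 0.5, K_P = 2 * grav_stiffness(a), K_D = 300,
                      tau_D = 0.15, tau_F = 15, K_F = 0)
  expect_warning(compare_parameters(p, pz), "K_F")
})

test_that("fitting the analytic FRF recovers the generator parameters", {
  truth <- test_params(W_p = 0.42, kp = 1.6, kd = 0.38, tau_D = 0.18,
                       tau_F = 12, K_F = 1.2e-3)
  f <- excited_frequencies()
  frf <- tibble::tibble(freq_hz = f,
                        response = closed_loop_sensitivity(truth, f),
                        coherence = rep(1, 21))
  fit <- fit_ic_model(frf, truth$anthropometry, condition(1, "closed"))
  rel <- abs(tidy(fit)$estimate - free_param_vec(truth)) / free_param_vec(truth)
  expect_lt(max(rel), 0.01)
  expect_true(fit$converged)
  # cost at the optimum does not exceed any multi-start initial cost
  expect_true(all(fit$cost <= fit$start_costs + 1e-15))
  # weight bookkeeping
  expect_equal(fit$params$W_p + fit$params$W_vis + fit$params$W_ves, 1)
  expect_equal(fit$params$W_vis, 0)
})

test_that("the fit is invariant to the perturbation amplitude when noise-free", {
  truth <- test_params()
  f1 <- recover_params(truth, amplitude_pp = 0.5, fs = 400)
  f2 <- recover_params(truth, amplitude_pp = 1, fs = 400)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-4)
})

test_that("recovery error in the proprioceptive weight grows with noise", {
  withr::local_seed(14)
  truth <- test_params(W_p = 0.45, kp = 1.5, kd = 0.4, tau_D = 0.17)
  err_at <- function(amp) {
    errs <- vapply(1:10, function(k) {
      fit <- recover_params(truth, fs = 200, noise_amp = amp, seed = 100 + k)
      abs(fit$params$W_p - truth$W_p)
    }, numeric(1))
    median(errs)
  }
  e <- vapply(c(0.15, 0.6, 2.4), err_at, numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("fits report VAF and SEM diagnostics on simulated trials", {
  truth <- test_params()
  pert <- prts_rotation(prts_states(4), 1, fs = 400)
  trial <- simulate_closed_loop(truth, pert,
                                noise_config(amplitude = 0.6, seed = 77))
  frf <- estimate_frf(trial)
  fit <- suppressWarnings(
    fit_ic_model(frf, truth$anthropometry, condition(1, "closed"),
                 trial = trial))
  expect_gt(fit$vaf_pct, 80)
  expect_true(all(tidy(fit)$sem >= 0, na.rm = TRUE))
  g <- glance(fit)
  expect_equal(g$n_freqs, 21)
  expect_equal(g$eyes, "closed")
  expect_s3_class(tidy(fit), "tbl_df")
})
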