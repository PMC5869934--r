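# Coherence- and frequency-weighted fit of the independent-channel model to
# an identified frequency response function, with variance-accounted-for
# and standard-error diagnostics.

# lightweight parameter object for optimizer inner loops (skips validation)
make_params_fast <- function(anthro, W_p, K_P, K_D, tau_D, tau_F, K_F) {
  structure(list(anthropometry = anthro,
                 W_p = W_p, W_vis = 0, W_ves = 1 - W_p,
                 K_P = K_P, K_D = K_D, tau_D = tau_D,
                 tau_F = tau_F, K_F = K_F),
            class = "ic_parameters")
}

#' Weighted frequency-domain prediction error
#'
#' Per-frequency residual between an identified and a model frequency
#' response:
#' \deqn{\varepsilon(f) = \frac{\gamma^2(f)}{1 + f}\,
#'   \left| \log \frac{H_{exp}(f)}{H_{est}(f)} \right|}
#' with the principal-branch complex logarithm, so magnitude and phase
#' mismatch enter on a common logarithmic scale. The weight emphasises low
#' frequencies and frequencies with high coherence.
#'
#' @param frf_exp Complex identified response per frequency.
#' @param coherence Coherence per frequency, in `[0, 1]`.
#' @param params An [ic_parameters()] object giving the model response.
#' @param freqs Frequencies, Hz.
#' @return Numeric residual vector (non-negative).
#' @export
prediction_error <- function(frf_exp, coherence, params, freqs) {
  if (length(frf_exp) != length(freqs) || length(coherence) != length(freqs))
    stop("`frf_exp`, `coherence` and `freqs` must have equal lengths")
  if (any(coherence < 0 | coherence > 1 + 1e-9, na.rm = TRUE))
    stop("`coherence` must lie in [0, 1]")
  coherence <- pmin(coherence, 1)  # tolerate roundoff at the upper bound
  h_est <- closed_loop_sensitivity(params, freqs)
  if (any(Mod(h_est) == 0)) stop("model response is zero at a fit frequency (log singularity)")
  if (any(Mod(frf_exp) == 0)) stop("identified response is zero at a fit frequency (log singularity)")
  w <- coherence / (1 + freqs)
  w * Mod(log(as.complex(frf_exp) / h_est))
}

#' Scalar fit cost
#'
#' Mean squared prediction error, `E = (1/N) e'e`.
#'
#' @param eps Residual vector from [prediction_error()].
#' @return Scalar cost.
#' @export
fit_cost <- function(eps) {
  if (length(eps) == 0) stop("empty residual vector")
  mean(eps^2)
}

#' Sensory weights implied by a proprioceptive weight
#'
#' The three sensory weights sum to one. With eyes closed the visual
#' channel is silent, so the vestibular weight is `1 - W_p`; with eyes
#' open the visual and vestibular contributions cannot be separated from
#' platform-rotation data alone, so their combined weight `1 - W_p` is
#' reported as a single number.
#'
#' @param W_p Proprioceptive weight in `[0, 1]`.
#' @param condition A [condition()] object.
#' @return Named numeric vector: `c(W_vis = 0, W_ves = 1 - W_p)` for eyes
#'   closed, `c(W_visves = 1 - W_p)` for eyes open.
#' @export
derive_weights <- function(W_p, condition) {
  stopifnot(inherits(condition, "stance_condition"))
  if (!is.numeric(W_p) || length(W_p) != 1 || W_p < 0 || W_p > 1)
    stop("`W_p` must lie in [0, 1]")
  if (condition$eyes == "closed") c(W_vis = 0, W_ves = 1 - W_p)
  else c(W_visves = 1 - W_p)
}

#' Variance accounted for between two time series
#'
#' Percentage of the predicted series' power explained, computed as
#' `(1 - sum(|ref - pred|^2) / sum(|pred|^2)) * 100`. Note the denominator
#' is the *predicted* series; identical series give exactly 100%.
#'
#' @param reference Measured (or simulated reference) series.
#' @param prediction Model-predicted series of the same length.
#' @return Scalar percentage (can be negative for very poor predictions).
#' @export
vaf <- function(reference, prediction) {
  if (length(reference) != length(prediction))
    stop("`reference` and `prediction` must have the same length")
  denom <- sum(prediction^2)
  if (denom == 0) stop("prediction has zero power; VAF undefined")
  (1 - sum((reference - prediction)^2) / denom) * 100
}

#' Parameter standard errors from the residual Jacobian
#'
#' Standard error of each estimated parameter from the estimated covariance
#' `P = E (J'J)^-1`, with `J` the Jacobian of the residual vector at the
#' optimum and `E` the mean squared error. These reflect the precision of
#' the estimates given the fitted spectra, not between-trial variability.
#'
#' @param jacobian `N x P` matrix of residual derivatives.
#' @param E Scalar mean squared error at the optimum.
#' @return Numeric vector of standard errors (NA with a warning where
#'   `J'J` is singular, i.e. the parameter is not identifiable).
#' @export
sem_from_jacobian <- function(jacobian, E) {
  jtj <- crossprod(jacobian)
  p <- ncol(jtj)
  cv <- tryCatch(E * solve(jtj), error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(diag(cv)))) {
    warning("J'J is singular: one or more parameters are not identifiable")
    return(rep(NA_real_, p))
  }
  sqrt(pmax(diag(cv), 0))
}

# map between free parameters and the scaled optimizer coordinates
q_from_p <- function(p, mgh) {
  c(p[["W_p"]], p[["K_P"]] / mgh, p[["K_D"]] / mgh, p[["tau_D"]],
    log10(p[["tau_F"]]), 1e3 * p[["K_F"]])
}
p_from_q <- function(q, mgh) {
  c(W_p = q[1], K_P = q[2] * mgh, K_D = q[3] * mgh, tau_D = q[4],
    tau_F = 10^q[5], K_F = q[6] / 1e3)
}

default_fit_bounds <- function(mgh) {
  list(lower = c(W_p = 0, K_P = 1.001 * mgh, K_D = 0, tau_D = 0.05,
                 tau_F = 1, K_F = 0),
       upper = c(W_p = 1, K_P = 10 * mgh, K_D = 5 * mgh, tau_D = 0.4,
                 tau_F = 100, K_F = 0.01))
}

#' Fit the independent-channel model to an identified frequency response
#'
#' Estimates the free parameters (`W_p`, `K_P`, `K_D`, `tau_D`, `tau_F`,
#' `K_F`; anthropometry fixed) by bound-constrained trust-region nonlinear
#' least squares on the coherence/frequency-weighted residual of
#' [prediction_error()], minimising the mean squared error over the
#' analysis band. A deterministic 8-point multi-start grid guards against
#' local optima; the best local optimum is returned with standard errors
#' from the residual Jacobian and, when a trial is supplied, the
#' variance-accounted-for of a noise-free resimulation with the fitted
#' parameters.
#'
#' @param frf An `frf_estimate` from [estimate_frf()] (or any data frame
#'   with columns `freq_hz`, `response`, `coherence`).
#' @param anthro Fixed [anthropometry()].
#' @param condition The experimental [condition()]; eyes-closed fits report
#'   `W_vis = 0`.
#' @param init Optional [ic_parameters()] used as an additional start.
#' @param bounds Optional list with named `lower`/`upper` vectors over the
#'   free parameters.
#' @param trial Optional `stance_trial`; enables the VAF diagnostic.
#' @return An object of class `ic_fit`; see [tidy.ic_fit()] and
#'   [glance.ic_fit()].
#' @export
fit_ic_model <- function(frf, anthro, condition, init = NULL, bounds = NULL,
                         trial = NULL) {
  stopifnot(inherits(anthro, "anthropometry"),
            inherits(condition, "stance_condition"))
  if (!all(c("freq_hz", "response", "coherence") %in% names(frf)))
    stop("`frf` must have columns freq_hz, response, coherence")
  freqs <- frf$freq_hz
  h_exp <- as.complex(frf$response)
  coh <- frf$coherence
  if (any(!is.finite(coh))) stop("coherence contains missing values")
  mgh <- grav_stiffness(anthro)
  if (is.null(bounds)) bounds <- default_fit_bounds(mgh)
  lower_q <- q_from_p(as.list(bounds$lower), mgh)
  upper_q <- q_from_p(as.list(bounds$upper), mgh)
  lower_q[1] <- max(lower_q[1], 1e-6)  # W_p = 0 makes the model identically zero

  # lean residual for the optimizer's inner loop: the anthropometry (and so
  # the body dynamics) is fixed, so precompute everything that does not
  # depend on the free parameters; a degenerate point (W_p at 0, singular
  # loop) must repel the search, not abort the start
  s_vec <- 2i * pi * freqs
  bd_vec <- 1 / (anthro$inertia * s_vec^2 - mgh)
  w_vec <- coh / (1 + freqs)
  big <- rep(1e3, length(freqs))
  eps_fast <- function(W_p, K_P, K_D, tau_D, tau_F, K_F) {
    nctd <- (K_P + K_D * s_vec) * exp(-tau_D * s_vec)
    h <- W_p * nctd * bd_vec /
      (1 - K_F / (tau_F * s_vec + 1) * nctd + nctd * bd_vec)
    out <- w_vec * Mod(log(h_exp / h))
    if (any(!is.finite(out))) big else out
  }
  resid_q <- function(q) {
    p <- p_from_q(q, mgh)
    eps_fast(p[["W_p"]], p[["K_P"]], p[["K_D"]], p[["tau_D"]],
             p[["tau_F"]], p[["K_F"]])
  }

  starts <- purrr::pmap(
    expand.grid(W_p = c(0.3, 0.7), kp = c(1.3, 2.5), tau = c(0.1, 0.2)),
    function(W_p, kp, tau)
      c(W_p = W_p, K_P = kp * mgh, K_D = 0.35 * mgh, tau_D = tau,
        tau_F = 15, K_F = 1e-3))
  if (!is.null(init)) {
    stopifnot(inherits(init, "ic_parameters"))
    starts <- c(starts, list(unlist(ic_parameters_flatten(init)[FREE_PARAM_NAMES])))
  }

  lm_control <- minpack.lm::nls.lm.control(maxiter = 700, maxfev = 5000,
                                           ftol = 1e-12, ptol = 1e-12)
  # iteration-limit chatter from individual starts is expected; convergence
  # is judged from the info code of the accepted optimum
  quiet_lm <- function(...) withCallingHandlers(
    minpack.lm::nls.lm(...),
    warning = function(w) {
      if (grepl("lmdif|lmder|maxiter|maxfev", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  best <- NULL
  start_costs <- numeric(length(starts))
  for (i in seq_along(starts)) {
    q0 <- pmin(pmax(q_from_p(as.list(starts[[i]]), mgh), lower_q), upper_q)
    res <- tryCatch(
      quiet_lm(par = q0, lower = lower_q, upper = upper_q,
               fn = resid_q, control = lm_control),
      error = function(e) NULL)
    if (is.null(res)) { start_costs[i] <- Inf; next }
    start_costs[i] <- fit_cost(res$fvec)
    if (is.null(best) || start_costs[i] < fit_cost(best$fvec)) best <- res
  }
  if (is.null(best))
    stop("no optimisation start converged; check the identified spectra")

  # Polish in coordinates where the weakly identified force-feedback pair is
  # benign: with tau_F * 2*pi*f >> 1 over the fit band only the ratio
  # K_F / tau_F is strongly determined, which makes a long curved valley in
  # the (tau_F, K_F) plane. On (log tau_F, log K_F) axes that valley is a
  # straight line, which the trust-region step traverses directly.
  resid_ll <- function(qq) {
    eps_fast(qq[1], qq[2] * mgh, qq[3] * mgh, qq[4], 10^qq[5], 10^qq[6])
  }
  p_best <- p_from_q(best$par, mgh)
  ll_lower <- c(lower_q[1:4], log10(bounds$lower[["tau_F"]]),
                log10(max(bounds$lower[["K_F"]], 1e-6)))
  ll_upper <- c(upper_q[1:4], log10(bounds$upper[["tau_F"]]),
                log10(bounds$upper[["K_F"]]))
  # polish starts: the stage-1 optimum itself, plus copies slid along the
  # valley floor to interior tau_F values with the identified ratio
  # K_F / tau_F preserved (escapes spurious pinning at the tau_F bound)
  ratio <- max(p_best[["K_F"]], 1e-8) / p_best[["tau_F"]]
  ll_starts <- c(list(c(best$par[1:4], log10(p_best[["tau_F"]]),
                        log10(max(p_best[["K_F"]], 1e-6)))),
                 purrr::map(c(3, 10, 30), function(tf)
                   c(best$par[1:4], log10(tf),
                     log10(min(max(ratio * tf, 1e-6),
                               bounds$upper[["K_F"]])))))
  pol_par <- NULL
  cost_pol <- fit_cost(best$fvec)
  for (s in ll_starts) {
    par_ll <- pmin(pmax(s, ll_lower), ll_upper)
    for (k in 1:2) {
      res <- tryCatch(
        quiet_lm(par = par_ll, lower = ll_lower, upper = ll_upper,
                 fn = resid_ll, control = lm_control),
        error = function(e) NULL)
      if (is.null(res)) break
      improved <- fit_cost(res$fvec) < cost_pol * (1 - 1e-9)
      if (fit_cost(res$fvec) <= cost_pol) {
        cost_pol <- fit_cost(res$fvec)
        pol_par <- res$par
        pol_info <- res$info
      }
      par_ll <- res$par
      if (!improved) break
    }
  }
  if (!is.null(pol_par)) {
    # pol_par carries log10 K_F in slot 6; q uses 1e3 * K_F
    q_hat <- c(pol_par[1:4], pol_par[5], 10^pol_par[6] * 1e3)
    best$info <- pol_info
    best$fvec <- resid_q(q_hat)
  } else {
    q_hat <- best$par
  }
  p_hat <- p_from_q(q_hat, mgh)
  at_bound <- abs(q_hat - lower_q) < 1e-8 | abs(q_hat - upper_q) < 1e-8
  names(at_bound) <- FREE_PARAM_NAMES
  if (any(at_bound))
    warning("estimate pinned at a bound: ",
            paste(FREE_PARAM_NAMES[at_bound], collapse = ", "))

  eps <- resid_q(q_hat)
  E <- fit_cost(eps)

  # Jacobian wrt the original parameters, central differences, rel step 1e-6
  jac <- matrix(0, nrow = length(freqs), ncol = length(p_hat))
  for (k in seq_along(p_hat)) {
    step <- 1e-6 * max(abs(p_hat[k]), 1e-8)
    pp <- p_hat; pm <- p_hat
    pp[k] <- pp[k] + step; pm[k] <- pm[k] - step
    rp <- resid_q(q_from_p(as.list(pp), mgh))
    rm <- resid_q(q_from_p(as.list(pm), mgh))
    jac[, k] <- (rp - rm) / (2 * step)
  }
  sem <- sem_from_jacobian(jac, E)
  names(sem) <- FREE_PARAM_NAMES

  w <- derive_weights(p_hat[["W_p"]], condition)
  if (condition$eyes == "closed") {
    w_vis <- 0; w_ves <- 1 - p_hat[["W_p"]]
  } else {
    w_vis <- (1 - p_hat[["W_p"]]) / 2; w_ves <- w_vis
  }
  params_hat <- ic_parameters(anthro, W_p = p_hat[["W_p"]],
                              K_P = p_hat[["K_P"]], K_D = p_hat[["K_D"]],
                              tau_D = p_hat[["tau_D"]], tau_F = p_hat[["tau_F"]],
                              K_F = p_hat[["K_F"]], W_vis = w_vis, W_ves = w_ves)
  attr(params_hat, "condition") <- condition

  vaf_pct <- NA_real_
  if (!is.null(trial)) {
    pert <- attr(trial, "perturbation")
    if (!is.null(pert)) {
      # the fitted tau_D rarely lands on a whole sample; the snap is expected
      sim <- withCallingHandlers(
        simulate_closed_loop(params_hat, pert, noise_config(amplitude = 0),
                             n_periods = attr(trial, "n_periods")),
        warning = function(w) {
          if (grepl("snapped", conditionMessage(w))) invokeRestart("muffleWarning")
        })
      vaf_pct <- vaf(trial$bs_deg, sim$bs_deg)
    }
  }

  h_fit <- closed_loop_sensitivity(params_hat, freqs)
  frf_tbl <- tibble::tibble(freq_hz = freqs, response = h_exp,
                            coherence = coh, fitted = h_fit,
                            residual = eps)
  structure(list(
    params = params_hat,
    estimates = tibble::tibble(
      term = FREE_PARAM_NAMES,
      estimate = unname(p_hat),
      sem = unname(sem),
      at_bound = unname(at_bound),
      unit = c("", "N m/rad", "N m s/rad", "s", "s", "rad/(N m)")),
    weights = w,
    cost = E,
    vaf_pct = vaf_pct,
    frf = frf_tbl,
    # info 1-4: tolerance met; 6-8: no further improvement possible
    converged = best$info %in% c(1:4, 6:8),
    n_freqs = length(freqs),
    start_costs = start_costs,
    condition = condition,
    anthropometry = anthro
  ), class = "ic_fit")
}

#' @export
print.ic_fit <- function(x, ...) {
  cat(sprintf("<ic_fit> %s | cost E = %.3e | %d frequencies | %s\n",
              format(x$condition), x$cost, x$n_freqs,
              if (x$converged) "converged" else "NOT converged"))
  ng <- normalized_gains(x$params)
  est <- x$estimates
  cat(sprintf("  W_p   = %.3f (SEM %.2g)\n", est$estimate[1], est$sem[1]))
  cat(sprintf("  K_P   = %.1f N m/rad = %.2f mgh (SEM %.2g)\n",
              est$estimate[2], ng[["stiffness"]], est$sem[2]))
  cat(sprintf("  K_D   = %.1f N m s/rad = %.2f mgh s (SEM %.2g)\n",
              est$estimate[3], ng[["damping"]], est$sem[3]))
  cat(sprintf("  tau_D = %.3f s (SEM %.2g)\n", est$estimate[4], est$sem[4]))
  cat(sprintf("  tau_F = %.1f s (SEM %.2g)\n", est$estimate[5], est$sem[5]))
  cat(sprintf("  K_F   = %.2e rad/(N m) (SEM %.2g)\n", est$estimate[6], est$sem[6]))
  if (is.finite(x$vaf_pct)) cat(sprintf("  VAF = %.1f%%\n", x$vaf_pct))
  invisible(x)
}

#' Tidy an independent-channel model fit
#'
#' @param x An `ic_fit` from [fit_ic_model()].
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate`, `sem`, `at_bound`, `unit`.
#' @export
tidy.ic_fit <- function(x, ...) x$estimates

#' One-row summary of an independent-channel model fit
#'
#' @param x An `ic_fit` from [fit_ic_model()].
#' @param ... Unused.
#' @return A tibble with columns `cost`, `vaf_pct`, `n_freqs`, `converged`,
#'   `amplitude_deg`, `eyes`.
#' @export
glance.ic_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, vaf_pct = x$vaf_pct, n_freqs = x$n_freqs,
                 converged = x$converged,
                 amplitude_deg = x$condition$amplitude_deg,
                 eyes = x$condition$eyes)
}

#' Mean relative difference between two parameter sets
#'
#' Mean over the free parameters of `100 |p_a - p_b| / |p_b|`, with `b` the
#' reference set. Parameters whose reference value is zero are excluded
#' with a warning. The metric is asymmetric in its arguments.
#'
#' @param a,b [ic_parameters()] objects (same free-parameter set); `b` is
#'   the reference.
#' @return Scalar percentage.
#' @export
compare_parameters <- function(a, b) {
  stopifnot(inherits(a, "ic_parameters"), inherits(b, "ic_parameters"))
  pa <- unlist(ic_parameters_flatten(a)[FREE_PARAM_NAMES])
  pb <- unlist(ic_parameters_flatten(b)[FREE_PARAM_NAMES])
  keep <- pb != 0
  if (!all(keep))
    warning("excluding zero-valued reference parameter(s): ",
            paste(FREE_PARAM_NAMES[!keep], collapse = ", "))
  mean(100 * abs(pa[keep] - pb[keep]) / abs(pb[keep]))
}
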