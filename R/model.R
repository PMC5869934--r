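# Frequency-domain description of the independent-channel stance loop.
#
# The body is an inverted pendulum linearised about upright,
#   J * theta'' = m*g*h * theta + T,
# so the torque-to-angle transfer is BD(s) = 1 / (J s^2 - m g h). The
# neural controller NC(s) = K_P + K_D s acts on a delayed error signal
# (TD(s) = exp(-tau_D s)) built from weighted sensory channels plus a
# low-pass positive torque feedback FF(s) = K_F / (tau_F s + 1).

#' Frequency response of one loop component
#'
#' Evaluates one of the four blocks of the stance control loop at given
#' frequencies: body dynamics `BD(s) = 1/(J s^2 - m g h)`, neural
#' controller `NC(s) = K_P + K_D s`, lumped delay `TD(s) = exp(-tau_D s)`,
#' or force feedback `FF(s) = K_F/(tau_F s + 1)`, with `s = i 2 pi f`.
#'
#' @param component One of `"BD"`, `"NC"`, `"TD"`, `"FF"`.
#' @param params An [ic_parameters()] object.
#' @param f Frequencies, Hz (non-negative).
#' @return Complex vector, one value per frequency.
#' @examples
#' p <- ic_parameters(anthropometry(51, 0.97, 40), W_p = 0.5, K_P = 1000,
#'                    K_D = 300, tau_D = 0.15, tau_F = 15, K_F = 8e-4)
#' component_response("NC", p, c(0, 0.5, 1))
#' @export
component_response <- function(component, params, f) {
  stopifnot(inherits(params, "ic_parameters"))
  if (!is.character(component) || length(component) != 1 ||
      !component %in% c("BD", "NC", "TD", "FF"))
    stop("`component` must be one of \"BD\", \"NC\", \"TD\", \"FF\"")
  if (!is.numeric(f) || any(!is.finite(f))) stop("`f` must be finite numeric")
  if (any(f < 0)) stop("`f` must be non-negative")
  s <- 2i * pi * f
  a <- params$anthropometry
  switch(component,
    BD = 1 / (a$inertia * s^2 - a$mass * a$g * a$com_height),
    NC = params$K_P + params$K_D * s + 0i,
    TD = exp(-params$tau_D * s),
    FF = params$K_F / (params$tau_F * s + 1)
  )
}

#' Closed-loop sensitivity of body sway to support-surface rotation
#'
#' The transfer function from platform rotation to body-in-space sway of
#' the independent-channel loop:
#' \deqn{H(f) = \frac{W_p \, NC \, TD \, BD}{1 - FF \, NC \, TD + NC \, TD \, BD}}
#' with the component blocks of [component_response()]. Only the
#' proprioceptive channel is driven by the platform; the space-referenced
#' channels (weight `1 - W_p`) and the force feedback shape the denominator.
#'
#' @param params An [ic_parameters()] object.
#' @param freqs Non-empty vector of frequencies, Hz (non-negative).
#' @return Complex vector `H(f)`, same length as `freqs`.
#' @examples
#' a <- anthropometry(51, 0.97, 40)
#' p <- ic_parameters(a, W_p = 0.5, K_P = 2 * grav_stiffness(a), K_D = 300,
#'                    tau_D = 0.15, tau_F = 15, K_F = 0)
#' closed_loop_sensitivity(p, c(0.05, 0.55, 2.05))
#' @export
closed_loop_sensitivity <- function(params, freqs) {
  stopifnot(inherits(params, "ic_parameters"))
  if (!is.numeric(freqs) || length(freqs) == 0 || any(!is.finite(freqs)))
    stop("`freqs` must be a non-empty finite numeric vector")
  if (any(freqs < 0)) stop("`freqs` must be non-negative")
  nc <- component_response("NC", params, freqs)
  td <- component_response("TD", params, freqs)
  bd <- component_response("BD", params, freqs)
  ff <- component_response("FF", params, freqs)
  den <- 1 - ff * nc * td + nc * td * bd
  bad <- which(Mod(den) < 1e-12)
  if (length(bad))
    stop(sprintf("closed-loop denominator is singular at f = %g Hz", freqs[bad[1]]))
  params$W_p * nc * td * bd / den
}

#' Model frequency response as a tibble
#'
#' Convenience wrapper around [closed_loop_sensitivity()] returning a tidy
#' table of gain and phase.
#'
#' @inheritParams closed_loop_sensitivity
#' @return A tibble with columns `freq_hz`, `response` (complex), `gain`,
#'   `phase_deg`.
#' @export
model_frf <- function(params, freqs) {
  h <- closed_loop_sensitivity(params, freqs)
  tibble::tibble(freq_hz = freqs, response = h,
                 gain = Mod(h), phase_deg = Arg(h) * 180 / pi)
}
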