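# Parameter containers for the independent-channel stance model.

# Segment fractions after Winter's anthropometric tables, frozen here so that
# derived anthropometry is deterministic across package versions.
WINTER_FOOT_MASS_FRACTION  <- 0.0145  # one foot, fraction of total body mass
WINTER_COM_HEIGHT_FRACTION <- 0.560   # CoM of body-minus-feet, fraction of stature
WINTER_ANKLE_HEIGHT_FRACTION <- 0.039 # ankle axis height, fraction of stature
WINTER_GYRATION_MULTIPLIER <- 1.12    # radius of gyration about the ankle, multiple of h

#' Anthropometry of a single-link stance model
#'
#' Bundles the mechanical constants of the inverted-pendulum body: the mass
#' of the body excluding the feet, the height of its centre of mass (CoM)
#' above the ankle axis, and the moment of inertia about that axis. These
#' enter the body dynamics `1 / (J s^2 - m g h)` and are held fixed during
#' model fitting.
#'
#' @param mass Body mass excluding the feet, kg.
#' @param com_height CoM height above the ankle axis, m.
#' @param inertia Moment of inertia about the ankle axis, kg m^2.
#' @param g Gravitational acceleration, m/s^2.
#'
#' @return An object of class `anthropometry`: a named list with elements
#'   `mass`, `com_height`, `inertia`, `g`.
#' @examples
#' a <- anthropometry(mass = 51, com_height = 0.97, inertia = 40)
#' grav_stiffness(a)
#' @export
anthropometry <- function(mass, com_height, inertia, g = 9.81) {
  stopifnot(is.numeric(mass), is.numeric(com_height), is.numeric(inertia),
            is.numeric(g), length(mass) == 1, length(com_height) == 1,
            length(inertia) == 1, length(g) == 1)
  if (!is.finite(mass) || mass <= 0) stop("`mass` must be a positive finite number")
  if (!is.finite(com_height) || com_height <= 0) stop("`com_height` must be a positive finite number")
  if (!is.finite(inertia) || inertia <= 0) stop("`inertia` must be a positive finite number")
  if (!is.finite(g) || g <= 0) stop("`g` must be a positive finite number")
  structure(list(mass = mass, com_height = com_height, inertia = inertia, g = g),
            class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> m = %.2f kg, h = %.3f m, J = %.2f kg m^2, g = %.2f m/s^2\n",
              x$mass, x$com_height, x$inertia, x$g))
  cat(sprintf("  gravitational stiffness m*g*h = %.1f N m/rad\n", grav_stiffness(x)))
  invisible(x)
}

#' Gravitational stiffness m*g*h
#'
#' The destabilising torque gradient of the inverted pendulum. The reflexive
#' stiffness of any stabilising controller must exceed it.
#'
#' @param x An `anthropometry` or `ic_parameters` object.
#' @return Scalar, N m/rad.
#' @export
grav_stiffness <- function(x) {
  if (inherits(x, "ic_parameters")) x <- x$anthropometry
  stopifnot(inherits(x, "anthropometry"))
  x$mass * x$g * x$com_height
}

#' Derive stance anthropometry from total body mass and height
#'
#' Uses frozen segment fractions from Winter's anthropometric tables to
#' convert total body mass and stature into the single-link quantities used
#' by the stance model: the feet (1.45% of body mass each) are removed, the
#' CoM of the remaining body is placed at 56.0% of stature with the ankle
#' axis at 3.9% of stature, and the moment of inertia about the ankle uses a
#' radius of gyration of 1.12 times the CoM height.
#'
#' @param total_mass Total body mass, kg.
#' @param total_height Stature, m.
#' @param g Gravitational acceleration, m/s^2.
#' @return An [anthropometry()] object.
#' @examples
#' winter_anthropometry(77.7, 1.79)
#' @export
winter_anthropometry <- function(total_mass, total_height, g = 9.81) {
  if (!is.numeric(total_mass) || length(total_mass) != 1 || !is.finite(total_mass) || total_mass <= 0)
    stop("`total_mass` must be a positive finite number")
  if (!is.numeric(total_height) || length(total_height) != 1 || !is.finite(total_height) || total_height <= 0)
    stop("`total_height` must be a positive finite number")
  m <- total_mass * (1 - 2 * WINTER_FOOT_MASS_FRACTION)
  h <- total_height * (WINTER_COM_HEIGHT_FRACTION - WINTER_ANKLE_HEIGHT_FRACTION)
  J <- m * (WINTER_GYRATION_MULTIPLIER * h)^2
  anthropometry(mass = m, com_height = h, inertia = J, g = g)
}

#' Experimental condition: perturbation amplitude and visual state
#'
#' @param amplitude_deg Peak-to-peak support-surface rotation amplitude,
#'   degrees.
#' @param eyes `"open"` or `"closed"`. With eyes closed the visual channel
#'   carries no information and its weight is zero.
#' @return An object of class `stance_condition`.
#' @export
condition <- function(amplitude_deg, eyes = c("open", "closed")) {
  eyes <- match.arg(eyes)
  if (!is.numeric(amplitude_deg) || length(amplitude_deg) != 1 ||
      !is.finite(amplitude_deg) || amplitude_deg <= 0)
    stop("`amplitude_deg` must be a positive finite number")
  structure(list(amplitude_deg = amplitude_deg, eyes = eyes),
            class = "stance_condition")
}

#' @export
print.stance_condition <- function(x, ...) {
  cat(sprintf("<condition> %.2g deg peak-to-peak, eyes %s\n", x$amplitude_deg, x$eyes))
  invisible(x)
}

#' @export
format.stance_condition <- function(x, ...) {
  sprintf("%g deg, eyes %s", x$amplitude_deg, x$eyes)
}

#' Independent-channel model parameters
#'
#' The full parameter set of the stance control loop: sensory weights
#' (proprioceptive `W_p`, visual `W_vis`, vestibular `W_ves`, summing to
#' one), the PD neural controller gains (`K_P` reflexive stiffness,
#' N m/rad; `K_D` reflexive damping, N m s/rad), the lumped loop delay
#' `tau_D` (s), and the low-pass positive torque feedback (`tau_F` time
#' constant, s; `K_F` gain, rad/(N m)), together with the fixed
#' [anthropometry()].
#'
#' Under earth-fixed visual surround the visual and vestibular channels both
#' sense body-in-space sway, so only `W_p` and the combined space-referenced
#' weight `1 - W_p` matter dynamically; with eyes closed `W_vis` must be 0.
#'
#' @param anthropometry An [anthropometry()] object.
#' @param W_p Proprioceptive weight in `[0, 1]`.
#' @param K_P Reflexive stiffness, N m/rad; must exceed the gravitational
#'   stiffness `m g h` for the closed loop to hold the body upright.
#' @param K_D Reflexive damping, N m s/rad, non-negative.
#' @param tau_D Lumped time delay, s, non-negative.
#' @param tau_F Force-feedback low-pass time constant, s, positive.
#' @param K_F Force-feedback gain, rad/(N m), non-negative.
#' @param W_vis,W_ves Visual and vestibular weights. Default: the remainder
#'   `1 - W_p` is assigned to the vestibular channel (eyes-closed
#'   convention); pass both explicitly for eyes-open splits.
#' @return An object of class `ic_parameters`.
#' @examples
#' a <- anthropometry(51, 0.97, 40)
#' p <- ic_parameters(a, W_p = 0.5, K_P = 2 * grav_stiffness(a),
#'                    K_D = 300, tau_D = 0.15, tau_F = 15, K_F = 8e-4)
#' @export
ic_parameters <- function(anthropometry, W_p, K_P, K_D, tau_D, tau_F, K_F,
                          W_vis = NULL, W_ves = NULL) {
  stopifnot(inherits(anthropometry, "anthropometry"))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("`%s` must be a finite number", nm))
    x
  }
  W_p <- num1(W_p, "W_p"); K_P <- num1(K_P, "K_P"); K_D <- num1(K_D, "K_D")
  tau_D <- num1(tau_D, "tau_D"); tau_F <- num1(tau_F, "tau_F"); K_F <- num1(K_F, "K_F")
  if (W_p < 0 || W_p > 1) stop("`W_p` must lie in [0, 1]")
  if (is.null(W_vis) && is.null(W_ves)) {
    W_vis <- 0
    W_ves <- 1 - W_p
  } else if (is.null(W_vis) || is.null(W_ves)) {
    stop("supply both `W_vis` and `W_ves`, or neither")
  }
  W_vis <- num1(W_vis, "W_vis"); W_ves <- num1(W_ves, "W_ves")
  if (W_vis < 0 || W_ves < 0) stop("sensory weights must be non-negative")
  if (abs(W_p + W_vis + W_ves - 1) > 1e-12)
    stop("sensory weights must sum to one (W_p + W_vis + W_ves = 1)")
  mgh <- grav_stiffness(anthropometry)
  if (K_P <= mgh)
    stop(sprintf("K_P (%.1f) must exceed the gravitational stiffness m*g*h (%.1f N m/rad)",
                 K_P, mgh))
  if (K_D < 0) stop("`K_D` must be non-negative")
  if (tau_D < 0) stop("`tau_D` must be non-negative")
  if (tau_F <= 0) stop("`tau_F` must be positive")
  if (K_F < 0) stop("`K_F` must be non-negative")
  structure(list(anthropometry = anthropometry,
                 W_p = W_p, W_vis = W_vis, W_ves = W_ves,
                 K_P = K_P, K_D = K_D, tau_D = tau_D,
                 tau_F = tau_F, K_F = K_F),
            class = "ic_parameters")
}

#' @export
print.ic_parameters <- function(x, ...) {
  ng <- normalized_gains(x)
  cat("<ic_parameters>\n")
  cat(sprintf("  weights: W_p = %.3f, W_vis = %.3f, W_ves = %.3f\n",
              x$W_p, x$W_vis, x$W_ves))
  cat(sprintf("  K_P = %.1f N m/rad (%.2f mgh), K_D = %.1f N m s/rad (%.2f mgh s)\n",
              x$K_P, ng[["stiffness"]], x$K_D, ng[["damping"]]))
  cat(sprintf("  tau_D = %.3f s, tau_F = %.1f s, K_F = %.2e rad/(N m)\n",
              x$tau_D, x$tau_F, x$K_F))
  invisible(x)
}

#' Controller gains normalised to the gravitational stiffness
#'
#' Expresses the reflexive stiffness and damping relative to `m g h`, which
#' makes gains comparable across bodies of different size.
#'
#' @param params An [ic_parameters()] object.
#' @return Named numeric vector with elements `stiffness` (dimensionless)
#'   and `damping` (s).
#' @export
normalized_gains <- function(params) {
  stopifnot(inherits(params, "ic_parameters"))
  mgh <- grav_stiffness(params)
  c(stiffness = params$K_P / mgh, damping = params$K_D / mgh)
}

# Names of the parameters estimated by the fit (anthropometry stays fixed).
FREE_PARAM_NAMES <- c("W_p", "K_P", "K_D", "tau_D", "tau_F", "K_F")

#' Flatten model parameters to a named list
#'
#' Serialises an [ic_parameters()] object (with its anthropometry) to a flat
#' named list suitable for YAML/JSON storage; [as_ic_parameters()] inverts
#' the mapping.
#'
#' @param params An [ic_parameters()] object.
#' @return Flat named list of numerics.
#' @export
ic_parameters_flatten <- function(params) {
  stopifnot(inherits(params, "ic_parameters"))
  a <- params$anthropometry
  list(mass = a$mass, com_height = a$com_height, inertia = a$inertia, g = a$g,
       W_p = params$W_p, W_vis = params$W_vis, W_ves = params$W_ves,
       K_P = params$K_P, K_D = params$K_D, tau_D = params$tau_D,
       tau_F = params$tau_F, K_F = params$K_F)
}

#' Rebuild model parameters from a flat named list
#'
#' @param x Flat named list as produced by [ic_parameters_flatten()].
#' @return An [ic_parameters()] object.
#' @export
as_ic_parameters <- function(x) {
  need <- c("mass", "com_height", "inertia", "W_p", "W_vis", "W_ves",
            "K_P", "K_D", "tau_D", "tau_F", "K_F")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing parameter fields: ", paste(missing, collapse = ", "))
  g <- if (!is.null(x$g)) x$g else 9.81
  ic_parameters(anthropometry(x$mass, x$com_height, x$inertia, g),
                W_p = x$W_p, K_P = x$K_P, K_D = x$K_D, tau_D = x$tau_D,
                tau_F = x$tau_F, K_F = x$K_F,
                W_vis = x$W_vis, W_ves = x$W_ves)
}

#' Study-style parameter sets for the four perturbation conditions
#'
#' Returns physiologically plausible independent-channel parameter sets for
#' the 2 x 2 design (0.5 and 1 degree peak-to-peak support-surface rotation,
#' eyes open and closed), encoding the sensory-reweighting pattern reported
#' across posturography studies: the proprioceptive weight falls with
#' increasing perturbation amplitude and with eyes open, while the reflexive
#' stiffness rises slightly with amplitude.
#'
#' @param anthro Fixed [anthropometry()]; defaults to the Winter-derived
#'   body of a 77.7 kg, 1.79 m adult.
#' @return Named list of four [ic_parameters()] objects with names
#'   `"0.5_open"`, `"1_open"`, `"0.5_closed"`, `"1_closed"`, each carrying a
#'   `condition` attribute.
#' @export
study_parameters <- function(anthro = winter_anthropometry(77.7, 1.79)) {
  mgh <- grav_stiffness(anthro)
  spec <- list(
    "0.5_open"   = list(W_p = 0.35, kp = 1.45, kd = 0.35, tau_D = 0.16, amp = 0.5, eyes = "open"),
    "1_open"     = list(W_p = 0.25, kp = 1.55, kd = 0.35, tau_D = 0.16, amp = 1.0, eyes = "open"),
    "0.5_closed" = list(W_p = 0.55, kp = 1.35, kd = 0.40, tau_D = 0.17, amp = 0.5, eyes = "closed"),
    "1_closed"   = list(W_p = 0.45, kp = 1.45, kd = 0.40, tau_D = 0.17, amp = 1.0, eyes = "closed")
  )
  purrr::imap(spec, function(s, nm) {
    if (s$eyes == "closed") {
      w_vis <- 0
      w_ves <- 1 - s$W_p
    } else {
      # earth-fixed surround: both space-referenced channels see -BS,
      # so the split is dynamically irrelevant; report an even split
      w_vis <- (1 - s$W_p) / 2
      w_ves <- (1 - s$W_p) / 2
    }
    p <- ic_parameters(anthro, W_p = s$W_p, K_P = s$kp * mgh, K_D = s$kd * mgh,
                       tau_D = s$tau_D, tau_F = 15, K_F = 8e-4,
                       W_vis = w_vis, W_ves = w_ves)
    attr(p, "condition") <- condition(s$amp, s$eyes)
    p
  })
}
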