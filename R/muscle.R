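# Hill-type muscle-tendon unit with the two DMD personalization knobs:
# an active-force scale sigma (weakness) and a passive force-length curve
# shift s (contracture). The total fiber force is
#
#   F = F_max * (sigma * a * f_L(l~) * f_V(v~) + f_pass(l~; s)) * cos(penn)
#
# where l~ and v~ are fiber length and velocity normalized to optimal fiber
# length (and to maximal shortening velocity), f_L is a Gaussian-sum active
# force-length curve, f_V a Hill force-velocity curve with a saturating
# eccentric branch, and f_pass an exponential passive curve whose onset sits
# at normalized length 1 - s: weakness scales only the active term, a
# contracture only translates the passive curve.

#' Muscle-tendon parameter set
#'
#' @param name muscle label
#' @param f_max maximal isometric force, N
#' @param l_opt optimal fiber length, m
#' @param l_slack tendon slack length, m
#' @param penn_opt pennation angle at optimal fiber length, rad, in `[0, pi/3)`
#' @param v_max maximal shortening velocity in optimal fiber lengths per second
#' @param active_scale weakness scale sigma = MVIC_DMD / MVIC_TD in `[0, 1]`
#' @param passive_shift contracture shift s in `[0, 0.6]` (normalized length)
#' @param tendon_shape dimensionless tendon-curve stiffness parameter
#' @param rigid_tendon logical; if TRUE the tendon is inextensible
#' @return list of class `muscle_params`
#' @export
muscle_params <- function(name = "muscle", f_max = 1000, l_opt = 0.1,
                          l_slack = 0.2, penn_opt = 0, v_max = 10,
                          active_scale = 1, passive_shift = 0,
                          tendon_shape = 35, rigid_tendon = TRUE) {
  if (f_max <= 0) stop_field("f_max", "must be > 0")
  if (l_opt <= 0) stop_field("l_opt", "must be > 0")
  if (l_slack <= 0) stop_field("l_slack", "must be > 0")
  if (v_max <= 0) stop_field("v_max", "must be > 0")
  if (active_scale < 0 || active_scale > 1) {
    stop_field("active_scale", "sigma must lie in [0, 1]")
  }
  if (passive_shift < 0 || passive_shift > 0.6) {
    stop_field("passive_shift", "shift must lie in [0, 0.6]")
  }
  if (penn_opt < 0 || penn_opt >= pi / 3) {
    stop_field("penn_opt", "must lie in [0, pi/3)")
  }
  structure(list(name = name, f_max = f_max, l_opt = l_opt,
                 l_slack = l_slack, penn_opt = penn_opt, v_max = v_max,
                 active_scale = active_scale, passive_shift = passive_shift,
                 tendon_shape = tendon_shape, rigid_tendon = rigid_tendon),
            class = "muscle_params")
}

#' Active force-length multiplier
#'
#' Gaussian-sum bell curve, normalized to equal exactly 1 at optimal fiber
#' length and decaying toward 0 away from it.
#'
#' @param lm_norm normalized fiber length(s), > 0
#' @return multiplier in `[0, 1]`
#' @export
active_force_length <- function(lm_norm) {
  if (any(lm_norm <= 0)) stop_field("lm_norm", "must be > 0")
  cpp_active_fl(as.numeric(lm_norm))
}

#' Passive force-length multiplier with contracture shift
#'
#' `passive_force_length(l, s)` equals the baseline exponential curve
#' evaluated at `l + s`: a pure translation of the curve to shorter fiber
#' lengths, so passive force starts to develop at normalized length `1 - s`.
#'
#' @param lm_norm normalized fiber length(s), > 0
#' @param shift contracture shift s in `[0, 0.6]`
#' @return non-negative multiplier
#' @export
passive_force_length <- function(lm_norm, shift = 0) {
  if (any(lm_norm <= 0)) stop_field("lm_norm", "must be > 0")
  if (shift < 0 || shift > 0.6) stop_field("shift", "must lie in [0, 0.6]")
  cpp_passive_fl(as.numeric(lm_norm), shift)
}

#' Force-velocity multiplier
#'
#' Equals 1 at zero fiber velocity, decays to ~0 at maximal shortening
#' (`vm_norm = -1`), and saturates toward 1.5 for fast lengthening.
#'
#' @param vm_norm normalized fiber velocity(ies); negative = shortening
#' @return non-negative multiplier
#' @export
force_velocity <- function(vm_norm) cpp_force_vel(as.numeric(vm_norm))

#' Muscle force from parameters and state
#'
#' @param params a [muscle_params()]
#' @param state list with `a` (activation in `[0,1]`), `lm_norm` (> 0) and
#'   `vm_norm`
#' @return fiber force along the tendon, N
#' @export
muscle_force <- function(params, state) {
  stopifnot(inherits(params, "muscle_params"))
  if (state$a < 0 || state$a > 1) stop_field("a", "must lie in [0, 1]")
  if (state$lm_norm <= 0) stop_field("lm_norm", "must be > 0")
  cpp_muscle_force(params$f_max, params$l_opt, params$penn_opt,
                   params$active_scale, params$passive_shift,
                   state$a, state$lm_norm, state$vm_norm)
}

#' Smooth excitation-activation coupling rate
#'
#' First-order dynamics with a faster activation than deactivation time
#' constant; the regime switch is blended with a tanh so the rate is
#' differentiable everywhere (needed by the trajectory optimizer).
#'
#' @param excitation neural excitation(s) in `[0, 1]`
#' @param activation current activation(s) in `[0, 1]`
#' @param tau_act activation time constant, s
#' @param tau_deact deactivation time constant, s
#' @param blend tanh blend sharpness
#' @return da/dt, 1/s
#' @export
activation_dynamics <- function(excitation, activation, tau_act = 0.015,
                                tau_deact = 0.060, blend = 2) {
  if (any(excitation < 0 | excitation > 1)) {
    stop_field("excitation", "must lie in [0, 1]")
  }
  if (any(activation < 0 | activation > 1)) {
    stop_field("activation", "must lie in [0, 1]")
  }
  cpp_act_rate(as.numeric(excitation), as.numeric(activation),
               tau_act, tau_deact, blend)
}

#' Fiber length from musculotendon length by fiber-tendon equilibrium
#'
#' In rigid-tendon mode the fiber length follows kinematically from
#' `lmt - l_slack` (with the constant-thickness pennation correction). In
#' elastic-tendon mode the normalized fiber length solves the static
#' equilibrium between tendon force and the fiber force projected on the
#' tendon, found by bisection on `[0.3, 1.8]`.
#'
#' @param params a [muscle_params()]
#' @param lmt musculotendon length, m
#' @param a activation in `[0, 1]`
#' @return normalized fiber length
#' @export
fiber_equilibrium <- function(params, lmt, a = 0) {
  stopifnot(inherits(params, "muscle_params"))
  res <- cpp_fiber_equilibrium(params$f_max, params$l_opt, params$l_slack,
                               params$penn_opt, params$active_scale,
                               params$passive_shift, params$tendon_shape,
                               lmt, a, params$rigid_tendon)
  if (!res$converged) {
    stop(sprintf("no fiber-tendon equilibrium in [0.3, 1.8] for muscle `%s`",
                 params$name), call. = FALSE)
  }
  res$lm_norm
}

#' Smoothed Bhargava-style metabolic energy rate of one muscle
#'
#' Sum of activation heat, maintenance heat, shortening/lengthening heat,
#' positive contractile work and a basal rate, with every conditional
#' (shortening vs lengthening, work sign) replaced by a tanh blend of the
#' given sharpness. `smooth = FALSE` evaluates the underlying piecewise
#' model with hard switches.
#'
#' @param params a [muscle_params()]
#' @param state list with `a`, `lm_norm`, `vm_norm`
#' @param excitation neural excitation in `[0, 1]`
#' @param sharpness tanh sharpness of the conditional approximations
#' @param smooth logical; FALSE gives the piecewise reference model
#' @return metabolic power, W
#' @export
metabolic_rate <- function(params, state, excitation = state$a,
                           sharpness = 100, smooth = TRUE) {
  stopifnot(inherits(params, "muscle_params"))
  cpp_metabolic_rate(params$f_max, params$l_opt, params$v_max,
                     params$active_scale, params$passive_shift,
                     state$a, excitation, state$lm_norm, state$vm_norm,
                     sharpness, smooth)
}
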