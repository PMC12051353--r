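# R surface over the compiled planar mechanics: muscle geometry, contact,
# passive joint torques, inverse/forward dynamics, mass matrix, energy.

#' Musculotendon lengths and moment arms at a posture
#'
#' Muscle paths are affine in the coordinates: `lmt = lref - sum_j r_j q_j`
#' with constant (anatomical-position) moment arms `r_j`; positive moment arm
#' produces positive generalized torque for positive muscle force.
#'
#' @param model a `planar_model`
#' @param q coordinate vector (12, radians/metres)
#' @return list with `lmt` (named vector, m) and `moment_arms`
#'   (muscle x coordinate matrix, m)
#' @export
muscle_geometry <- function(model, q) {
  stopifnot(length(q) == length(COORD_NAMES))
  mu <- model$muscles
  marm <- t(vapply(seq_len(nrow(mu)), function(i) muscle_arm_row(mu[i, ]),
                   numeric(length(COORD_NAMES))))
  rownames(marm) <- paste(mu$name, mu$side, sep = "_")
  lmt <- mu$lref - as.numeric(marm %*% q)
  list(lmt = setNames(lmt, rownames(marm)), moment_arms = marm)
}

#' Hunt-Crossley contact force of one sphere
#'
#' Normal force `k * delta^(3/2) * (1 + 3/2 c ddot)` with the penetration
#' delta smoothed (C-infinity) over a 1 mm band and the dissipation factor
#' smoothly clamped to be non-negative; friction is smoothed Coulomb
#' (tanh of slip velocity) times the normal force. Zero force when the
#' sphere is above the ground beyond the smoothing band.
#'
#' @param center_y sphere center height, m
#' @param radius sphere radius, m
#' @param vx,vy sphere center velocity, m/s
#' @param stiffness contact stiffness k, N/m^1.5
#' @param dissipation velocity coefficient c, s/m
#' @param friction Coulomb friction coefficient
#' @param v_smooth friction smoothing velocity, m/s
#' @param ground_y ground height, m
#' @return list with `fx`, `fy` (N)
#' @export
hunt_crossley_force <- function(center_y, radius, vx = 0, vy = 0,
                                stiffness = 3e5, dissipation = 2,
                                friction = 0.8, v_smooth = 0.05,
                                ground_y = 0) {
  pen <- radius - (center_y - ground_y)
  # sqrt-smoothed positive part with a tanh cutoff killing the far tail
  d <- 0.5 * (pen + sqrt(pen^2 + 1e-3^2)) *
    (0.5 + 0.5 * tanh(pen / 1e-3 + 5))
  vfac <- 1 + 1.5 * dissipation * (-vy)
  vfac <- 0.5 * (vfac + sqrt(vfac^2 + 0.1^2))
  fy <- stiffness * d^1.5 * vfac
  fx <- -friction * fy * tanh(vx / v_smooth)
  list(fx = fx, fy = fy)
}

#' Exponential passive joint torque
#'
#' Double-exponential well with damping:
#' `T = k1l exp(k2l (q_low - q)) - k1h exp(k2h (q - q_high)) - damping qdot`,
#' near zero inside `[q_low, q_high]` at rest and restoring outside.
#'
#' @param q joint angle, rad
#' @param qdot joint velocity, rad/s
#' @param k1_low,k2_low low-side stiffness coefficients (N m, 1/rad)
#' @param q_low,q_high onset angles, rad
#' @param k1_high,k2_high high-side stiffness coefficients
#' @param damping damping coefficient, N m s/rad
#' @return torque, N m
#' @export
passive_joint_torque <- function(q, qdot = 0, k1_low = 2, k2_low = 5,
                                 q_low = -0.3, k1_high = 2, k2_high = 5,
                                 q_high = 0.3, damping = 0.2) {
  if (q_low >= q_high) stop_field("q_low", "must be below q_high")
  k1_low * exp(k2_low * (q_low - q)) - k1_high * exp(k2_high * (q - q_high)) -
    damping * qdot
}

#' All contact-sphere forces at a state
#' @param model a `planar_model`
#' @param q,qdot coordinate and velocity vectors
#' @return data.frame with per-sphere forces and application points
#' @export
contact_forces <- function(model, q, qdot = numeric(length(q))) {
  out <- cpp_contact(pack_model(model), q, qdot)
  data.frame(name = model$contact$name, fx = out[, 2], fy = out[, 3],
             px = out[, 4], py = out[, 5], center_y = out[, 6])
}

#' Inverse dynamics of the planar skeleton
#'
#' Generalized applied forces required to realize the accelerations `qddot`
#' at state `(q, qdot)`, via a planar recursive Newton-Euler pass; gravity
#' and contact forces can be included or excluded.
#'
#' @param model a `planar_model`
#' @param q,qdot,qddot coordinate, velocity and acceleration vectors
#' @param gravity include gravity
#' @param contact include foot-ground contact forces
#' @return generalized force vector (N, N, then N m)
#' @export
inverse_dynamics <- function(model, q, qdot, qddot, gravity = TRUE,
                             contact = TRUE) {
  setNames(as.numeric(cpp_inverse_dynamics(pack_model(model), q, qdot,
                                           qddot, gravity, contact)),
           COORD_NAMES)
}

#' Joint-space mass matrix
#' @param model a `planar_model`
#' @param q coordinate vector
#' @return symmetric positive-definite 12 x 12 matrix
#' @export
mass_matrix <- function(model, q) {
  M <- cpp_mass_matrix(pack_model(model), q)
  dimnames(M) <- list(COORD_NAMES, COORD_NAMES)
  M
}

#' Forward dynamics of the planar skeleton
#'
#' Solves `M(q) qddot = tau_applied + tau_muscle + tau_passive - bias` for
#' the accelerations, where the bias collects velocity, gravity and contact
#' terms. Coordinates listed in `locked` are held at zero acceleration
#' (their rows/columns are eliminated), which turns the model into a reduced
#' mechanism such as a pinned double pendulum.
#'
#' @param model a `planar_model`
#' @param q,qdot state vectors
#' @param activations muscle activation vector (defaults to all zero)
#' @param tau_applied extra generalized forces (defaults to zero)
#' @param gravity,contact,muscles,passive include the respective terms
#' @param locked character vector of coordinate names to freeze
#' @return named acceleration vector
#' @export
forward_dynamics <- function(model, q, qdot,
                             activations = NULL, tau_applied = NULL,
                             gravity = TRUE, contact = TRUE, muscles = TRUE,
                             passive = TRUE, locked = character(0)) {
  pk <- pack_model(model)
  nq <- length(COORD_NAMES)
  if (is.null(tau_applied)) tau_applied <- numeric(nq)
  tau <- tau_applied
  if (muscles) {
    if (is.null(activations)) activations <- numeric(nrow(model$muscles))
    ms <- cpp_muscle_state(pk, q, qdot, activations)
    tau <- tau + ms$torque
  }
  if (passive) tau <- tau + cpp_passive_torques(pk, q, qdot)
  bias <- cpp_inverse_dynamics(pk, q, qdot, numeric(nq), gravity, contact)
  M <- cpp_mass_matrix(pk, q)
  free <- setdiff(seq_len(nq), match(locked, COORD_NAMES))
  qddot <- numeric(nq)
  qddot[free] <- solve(M[free, free, drop = FALSE],
                       (tau - bias)[free])
  setNames(qddot, COORD_NAMES)
}

#' Mechanical energy of the skeleton
#' @param model a `planar_model`
#' @param q,qdot state vectors
#' @return list with `kinetic`, `potential`, `total` (J)
#' @export
mechanical_energy <- function(model, q, qdot) {
  cpp_mech_energy(pack_model(model), q, qdot)
}

#' World positions of the body frames and centers of mass
#' @param model a `planar_model`
#' @param q coordinate vector
#' @return data.frame per segment: origin, orientation, center of mass
#' @export
body_kinematics <- function(model, q) {
  nq <- length(COORD_NAMES)
  out <- cpp_kinematics(pack_model(model), q, numeric(nq), numeric(nq))$body
  data.frame(segment = model$segments$name, px = out[, 1], py = out[, 2],
             phi = out[, 3], comx = out[, 4], comy = out[, 5])
}
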