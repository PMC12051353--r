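# Planar skeletal mechanics: muscle geometry, contact, passive torques,
# mass matrix, inverse/forward dynamics, energy conservation.

test_that("muscle geometry is affine with the documented sign convention", {
  m <- default_planar_model()
  q0 <- numeric(12)
  geo0 <- muscle_geometry(m, q0)
  expect_equal(unname(geo0$lmt),
               m$muscles$lref, tolerance = 1e-12)  # reference posture
  # iliopsoas r_hip = +0.05: hip flexion of 0.1 rad shortens it by 5 mm
  q1 <- q0; q1[5] <- 0.1
  geo1 <- muscle_geometry(m, q1)
  expect_equal(geo1$lmt[["iliopsoas_r"]] - geo0$lmt[["iliopsoas_r"]],
               -0.005, tolerance = 1e-12)
  # biarticular gastrocnemius spans knee and ankle
  q2 <- q0; q2[7] <- 0.2   # knee_r
  q3 <- q0; q3[9] <- 0.2   # ankle_r
  expect_false(geo0$lmt[["gastroc_r"]] ==
                 muscle_geometry(m, q2)$lmt[["gastroc_r"]])
  expect_false(geo0$lmt[["gastroc_r"]] ==
                 muscle_geometry(m, q3)$lmt[["gastroc_r"]])
})

test_that("Hunt-Crossley contact vanishes far from the ground, matches the
           closed-form static penetration, and friction is odd in slip", {
  f <- hunt_crossley_force(center_y = 1, radius = 0.02)
  expect_lt(abs(f$fy), 1e-6)
  expect_lt(abs(f$fx), 1e-6)

  # static equilibrium under a large weight: penetration from root finding
  # matches the closed form of the contact law, k delta^1.5 vfac0 = W, with
  # vfac0 the (constant) static value of the smoothed dissipation clamp
  W <- 2000; k <- 1e5; r <- 0.02
  vfac0 <- 0.5 * (1 + sqrt(1 + 0.1^2))
  resid <- function(y) hunt_crossley_force(y, r, stiffness = k)$fy - W
  ystar <- uniroot(resid, c(-0.2, r), tol = 1e-14)$root
  delta <- r - ystar
  # closed form of the smoothed law: the effective depth D solves
  # k D^1.5 vfac0 = W, and the raw penetration is D minus the first-order
  # smoothing-band offset eps^2/(4 D)
  D <- (W / (k * vfac0))^(2 / 3)
  expect_equal(delta, D - 1e-6 / (4 * D), tolerance = 1e-6)

  fp <- hunt_crossley_force(0.005, r, vx = 0.3, stiffness = k)
  fm <- hunt_crossley_force(0.005, r, vx = -0.3, stiffness = k)
  expect_equal(fp$fx, -fm$fx, tolerance = 1e-12)
  expect_lt(fp$fx, 0)
})

test_that("passive joint torque has a neutral zone, exponential walls and
           additive damping", {
  expect_lt(abs(passive_joint_torque(0, 0)), 0.5)
  q <- 0.3 + 0.2
  expected <- 2 * exp(5 * (-0.3 - q)) - 2 * exp(5 * (q - 0.3))
  expect_equal(passive_joint_torque(q, 0), expected, tolerance = 1e-12)
  expect_lt(passive_joint_torque(q, 0), 0)  # restoring
  expect_equal(passive_joint_torque(0.1, 1) - passive_joint_torque(0.1, 0),
               -0.2, tolerance = 1e-12)
  expect_error(passive_joint_torque(0, q_low = 1, q_high = 0), "q_low")
})

test_that("mass matrix is symmetric positive definite across random
           states", {
  m <- default_planar_model()
  pk <- dmdgait:::pack_model(m)
  set.seed(12)
  for (i in 1:200) {
    q <- rnorm(12, 0, 0.5); q[2] <- runif(1, 0.5, 1.2)
    M <- dmdgait:::cpp_mass_matrix(pk, q)
    expect_lt(max(abs(M - t(M))), 1e-10)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("forward and inverse dynamics are mutually consistent and linear
           in applied forces", {
  m <- default_planar_model()
  set.seed(3)
  q <- rnorm(12, 0, 0.3); q[2] <- 0.9
  qd <- rnorm(12, 0, 0.5)
  a <- runif(20, 0, 0.5)
  tau <- rnorm(12, 0, 10)
  qdd <- forward_dynamics(m, q, qd, activations = a, tau_applied = tau)
  req <- inverse_dynamics(m, q, qd, qdd)
  pk <- dmdgait:::pack_model(m)
  tau_mus <- as.numeric(dmdgait:::cpp_muscle_state(pk, q, qd, a)$torque)
  tau_pas <- as.numeric(dmdgait:::cpp_passive_torques(pk, q, qd))
  expect_equal(unname(req), tau + tau_mus + tau_pas, tolerance = 1e-9)
  # linearity: doubling applied torques at zero velocity doubles the
  # acceleration change
  qd0 <- numeric(12)
  a0 <- forward_dynamics(m, q, qd0, tau_applied = numeric(12),
                         muscles = FALSE, passive = FALSE, contact = FALSE)
  a1 <- forward_dynamics(m, q, qd0, tau_applied = tau,
                         muscles = FALSE, passive = FALSE, contact = FALSE)
  a2 <- forward_dynamics(m, q, qd0, tau_applied = 2 * tau,
                         muscles = FALSE, passive = FALSE, contact = FALSE)
  expect_equal(unname(a2 - a0), unname(2 * (a1 - a0)), tolerance = 1e-8)
})

test_that("a pinned frictionless double pendulum conserves mechanical
           energy to 1e-6 relative over one second", {
  m <- default_planar_model()
  locked <- setdiff(dmdgait:::COORD_NAMES, c("hip_r", "knee_r"))
  q0 <- numeric(12); q0[2] <- 2.0; q0[5] <- 0.8; q0[7] <- 0.3
  qd0 <- numeric(12)
  deriv <- function(t, y, p) {
    qdd <- forward_dynamics(m, y[1:12], y[13:24], muscles = FALSE,
                            passive = FALSE, contact = FALSE,
                            locked = locked)
    list(c(y[13:24], qdd))
  }
  out <- deSolve::ode(c(q0, qd0), c(0, 1), deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  E0 <- mechanical_energy(m, q0, qd0)$total
  Ef <- mechanical_energy(m, out[2, 2:13], out[2, 14:25])$total
  expect_lt(abs(Ef - E0) / abs(E0), 1e-6)
})

test_that("a static standing posture found by root finding is in
           equilibrium under forward dynamics", {
  m <- default_planar_model()
  # posture family: pelvis height y and a symmetric hip angle (feet shift
  # fore/aft); nested root finding solves the pelvis vertical-force and
  # tilt-moment residuals of the floating base
  resid_at <- function(y, hip) {
    q <- numeric(12); q[2] <- y; q[5] <- hip; q[6] <- hip
    inverse_dynamics(m, q, numeric(12), numeric(12))
  }
  y_for <- function(hip) {
    uniroot(function(y) resid_at(y, hip)[["pelvis_ty"]],
            c(0.80, 0.89), tol = 1e-12, extendInt = "upX")$root
  }
  hip_star <- uniroot(function(hip)
    resid_at(y_for(hip), hip)[["pelvis_tilt"]],
    c(-0.3, 0.3), tol = 1e-12, extendInt = "yes")$root
  y_star <- y_for(hip_star)
  r_final <- resid_at(y_star, hip_star)
  expect_lt(abs(r_final[["pelvis_ty"]]), 1e-4)
  expect_lt(abs(r_final[["pelvis_tilt"]]), 1e-4)
  q <- numeric(12); q[2] <- y_star; q[5] <- hip_star; q[6] <- hip_star
  tau <- inverse_dynamics(m, q, numeric(12), numeric(12))
  tau[1:3] <- 0  # no actuation at the floating base
  qdd <- forward_dynamics(m, q, numeric(12), tau_applied = tau,
                          muscles = FALSE, passive = FALSE)
  expect_lt(max(abs(qdd)), 1e-3)
})

test_that("contact force and passive torque are smooth: central-difference
           derivatives converge under step refinement", {
  fd2 <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
  # contact normal force as a function of center height near grazing
  fc <- function(y) hunt_crossley_force(y, 0.02, vy = -0.1)$fy
  for (y0 in c(0.021, 0.02, 0.019)) {
    d1 <- fd2(fc, y0, 1e-4)
    d2 <- fd2(fc, y0, 1e-5)
    d3 <- fd2(fc, y0, 1e-6)
    expect_lt(abs(d3 - d2), abs(d2 - d1) + 1e-6 * abs(d2) + 1e-9)
  }
  ft <- function(q) passive_joint_torque(q, 0.3)
  for (q0 in c(-0.31, 0, 0.29)) {
    d2 <- fd2(ft, q0, 1e-5); d3 <- fd2(ft, q0, 1e-6)
    expect_equal(d3, d2, tolerance = 1e-5)
  }
})

test_that("the default model is left/right symmetric and mirrored states
           give mirrored dynamics", {
  m <- default_planar_model()
  expect_true(model_is_symmetric(m))
  set.seed(8)
  q <- rnorm(12, 0, 0.3); q[2] <- 0.9
  qswap <- c(1, 2, 3, 4, 6, 5, 8, 7, 10, 9, 12, 11)
  qm <- q[qswap]
  tau <- inverse_dynamics(m, q, numeric(12), numeric(12))
  taum <- inverse_dynamics(m, qm, numeric(12), numeric(12))
  expect_equal(unname(taum), unname(tau[qswap]), tolerance = 1e-9)
})
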