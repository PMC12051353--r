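# Hill-type muscle curves, activation dynamics, fiber-tendon equilibrium,
# and the smoothed metabolic model.

# Independent R evaluation of the Gaussian-sum active force-length curve
# from its published coefficients (normalized to 1 at optimal length).
afl_oracle <- function(l) {
  b1 <- c(0.814483478343008, 0.433004984392647, 0.100)
  b2 <- c(1.055033428970575, 0.716775413397760, 1.000)
  b3 <- c(0.162384573599574, -0.029947116970696, 0.353553390593274)
  b4 <- c(0.063303448465465, 0.200356847296188, 0.000)
  raw <- function(x) {
    sum(b1 * exp(-0.5 * ((x - b2) / (b3 + b4 * x))^2))
  }
  vapply(l, raw, numeric(1)) / raw(1)
}

test_that("active force-length peaks at 1 exactly and decays off-optimum", {
  expect_equal(active_force_length(1), 1)
  expect_lt(active_force_length(0.3), 0.05)
  expect_equal(active_force_length(c(0.8, 1.2, 1.5)),
               afl_oracle(c(0.8, 1.2, 1.5)), tolerance = 1e-12)
  expect_error(active_force_length(-0.1), "lm_norm")
})

test_that("passive curve onset sits at 1 - shift and the shift is a pure
           translation", {
  expect_lt(passive_force_length(1.0, 0), 1e-3)
  expect_lt(passive_force_length(0.67, 0.33), 1e-3)
  # exact translation identity on a grid of lengths
  l <- seq(0.6, 1.6, by = 0.02)
  expect_equal(passive_force_length(l, 0.2), passive_force_length(l + 0.2, 0),
               tolerance = 1e-15)
  # strictly increasing beyond onset, non-negative everywhere
  f <- passive_force_length(seq(1.0, 1.6, by = 0.01), 0)
  expect_true(all(diff(f) > 0))
  expect_true(all(passive_force_length(seq(0.5, 1.6, 0.01), 0.3) >= 0))
  expect_error(passive_force_length(1, 0.7), "shift")
})

test_that("passive force is non-decreasing in the shift at fixed length", {
  l <- c(0.8, 1.0, 1.2, 1.4)
  shifts <- seq(0, 0.6, by = 0.1)
  for (li in l) {
    v <- vapply(shifts, function(s) passive_force_length(li, s), numeric(1))
    expect_true(all(diff(v) >= 0))
  }
})

# Independent R evaluation of the blended Hill force-velocity curve.
fv_oracle <- function(v) {
  sp <- function(x, e) 0.5 * (x + sqrt(x^2 + e^2))
  raw <- function(x) {
    w <- 0.5 - 0.5 * tanh(x / 0.05)
    vc <- -sp(-x, 0.02)
    vc <- -1 + sp(vc + 1, 0.02)
    fc <- (1 + vc) / (1 - vc / 0.25)
    fe <- 1 + 0.5 * x / (sqrt(x^2 + 1e-4) + 0.16)
    w * fc + (1 - w) * fe
  }
  vapply(v, raw, numeric(1)) / raw(0)
}

test_that("force-velocity is 1 isometric, ~0 at max shortening, bounded
           eccentric", {
  expect_equal(force_velocity(0), 1)
  expect_lt(force_velocity(-1), 0.01)
  expect_equal(force_velocity(0.5), fv_oracle(0.5), tolerance = 1e-12)
  expect_lt(max(force_velocity(seq(0, 3, 0.1))), 1.55)
  v <- seq(-1, 0, 0.05)
  expect_true(all(diff(force_velocity(v)) > 0))  # decreasing with shortening
})

test_that("muscle force composes active and passive parts with the weakness
           scale acting only on the active term", {
  p <- muscle_params(f_max = 1000, l_opt = 0.1, l_slack = 0.2)
  st <- list(a = 0, lm_norm = 1, vm_norm = 0)
  expect_lt(muscle_force(p, st), 0.5)   # no activation at passive onset
  st2 <- list(a = 1, lm_norm = 1, vm_norm = 0)
  expect_equal(muscle_force(p, st2), 1000, tolerance = 1e-3)
  # sigma linearity: active part scales exactly with sigma
  p5 <- muscle_params(f_max = 1000, active_scale = 0.5, passive_shift = 0.2)
  p1 <- muscle_params(f_max = 1000, active_scale = 1.0, passive_shift = 0.2)
  st3 <- list(a = 0.7, lm_norm = 1.1, vm_norm = -0.2)
  passive <- 1000 * passive_force_length(1.1, 0.2)
  expect_equal(muscle_force(p5, st3) - passive,
               0.5 * (muscle_force(p1, st3) - passive), tolerance = 1e-10)
  # the shift leaves the active term untouched
  pa <- muscle_params(f_max = 1000, passive_shift = 0)
  pb <- muscle_params(f_max = 1000, passive_shift = 0.4)
  act_a <- muscle_force(pa, st3) - 1000 * passive_force_length(1.1, 0)
  act_b <- muscle_force(pb, st3) - 1000 * passive_force_length(1.1, 0.4)
  expect_equal(act_a, act_b, tolerance = 1e-10)
})

test_that("activation dynamics is in equilibrium at e = a and approaches the
           first-order rates in the two regimes", {
  expect_equal(activation_dynamics(0.4, 0.4), 0)
  r_up <- activation_dynamics(1, 0)
  expect_equal(r_up, 1 / 0.015, tolerance = 0.02)
  r_down <- activation_dynamics(0, 1)
  expect_lt(r_down, 0)
  expect_equal(abs(r_down), 1 / 0.060, tolerance = 0.10)
  # closed-form check of the blended expression
  blend_oracle <- function(e, a, ta = 0.015, td = 0.060, b = 2) {
    w <- 0.5 + 0.5 * tanh(b * (e - a))
    (e - a) * (w / ta + (1 - w) / td)
  }
  for (pair in list(c(0.8, 0.2), c(0.1, 0.9), c(0.5, 0.45))) {
    expect_equal(activation_dynamics(pair[1], pair[2]),
                 blend_oracle(pair[1], pair[2]), tolerance = 1e-12)
  }
  expect_error(activation_dynamics(1.2, 0), "excitation")
})

test_that("rigid-tendon fiber length is kinematic and the elastic-tendon
           equilibrium matches a bisection oracle", {
  p <- muscle_params(f_max = 2000, l_opt = 0.1, l_slack = 0.25)
  expect_equal(fiber_equilibrium(p, 0.35, a = 0.5), 1, tolerance = 1e-12)

  # independent bisection oracle over lm_norm in [0.3, 1.8]
  oracle <- function(p, lmt, a) {
    res <- function(lmn) {
      ltn <- (lmt - lmn * p$l_opt) / p$l_slack
      ften <- p$f_max * (0.2 * exp(p$tendon_shape * (ltn - 0.995)) - 0.25)
      ffib <- p$f_max * (p$active_scale * a * active_force_length(lmn) +
                           passive_force_length(lmn, p$passive_shift))
      ften - ffib
    }
    uniroot(res, c(0.3, 1.8), tol = 1e-12)$root
  }
  set.seed(31)
  n_ok <- 0
  for (i in 1:100) {
    p <- muscle_params(f_max = runif(1, 500, 5000),
                       l_opt = runif(1, 0.05, 0.15),
                       l_slack = runif(1, 0.1, 0.35),
                       active_scale = runif(1, 0.2, 1),
                       passive_shift = runif(1, 0, 0.5),
                       rigid_tendon = FALSE)
    a <- runif(1)
    lmt <- p$l_slack + p$l_opt * runif(1, 0.95, 1.3)
    ref <- tryCatch(oracle(p, lmt, a), error = function(e) NULL)
    if (is.null(ref)) next   # no sign change in the admissible range
    expect_equal(fiber_equilibrium(p, lmt, a), ref, tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 50)
})

test_that("metabolic rate reduces to the basal term at rest and matches the
           piecewise model away from the smoothing switches", {
  p <- muscle_params(f_max = 3000, l_opt = 0.1)
  mmass <- 1058.7 * p$l_opt * p$f_max / 2.5e5
  rest <- metabolic_rate(p, list(a = 0, lm_norm = 1, vm_norm = 0),
                         excitation = 0)
  expect_equal(rest, 1.2 * mmass, tolerance = 1e-12)

  for (vm in c(-0.6, -0.2, 0.2, 0.6)) {
    st <- list(a = 0.6, lm_norm = 1.05, vm_norm = vm)
    sm <- metabolic_rate(p, st, excitation = 0.6, sharpness = 100)
    pw <- metabolic_rate(p, st, excitation = 0.6, smooth = FALSE)
    expect_equal(sm, pw, tolerance = 1e-6)
  }

  # homogeneity: doubling f_max doubles every term at fixed normalized state
  p2 <- muscle_params(f_max = 6000, l_opt = 0.1)
  st <- list(a = 0.4, lm_norm = 0.95, vm_norm = -0.3)
  expect_equal(metabolic_rate(p2, st), 2 * metabolic_rate(p, st),
               tolerance = 1e-12)
})
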