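# Predictive-gait problem transcription and solver contracts.

test_that("transcription bookkeeping: variable and constraint counts follow
           mesh size, state dimension and collocation order", {
  m <- td_child_model()
  cfg <- ocp_config(target_speed = 1.1, mesh_intervals = 14)
  pr <- build_problem(m, cfg)
  ns <- 2 * 12 + nrow(m$muscles)           # q, qdot, activations
  expect_equal(pr$state_dim, ns)
  expect_equal(pr$collocation_order, 1L)
  expect_equal(pr$n_defects, 14 * ns * pr$collocation_order)
  expect_equal(pr$nvar, pr$bs * 14 + 1)
  expect_equal(length(pr$cscale), 14 * ns + 14 * 12)
  expect_equal(length(pr$lb), pr$nvar)
  expect_error(ocp_config(mesh_intervals = 5), "mesh_intervals")
  expect_error(ocp_config(target_speed = -1), "target_speed")
})

test_that("the left/right symmetry map is an involution and the cyclic
           closure advances the pelvis by exactly v * t_f", {
  m <- td_child_model()
  pr <- build_problem(m, ocp_config(target_speed = 1.3,
                                    mesh_intervals = 12))
  set.seed(5)
  x <- rnorm(pr$state_dim)
  expect_equal(ocp_symmetry_map(pr, ocp_symmetry_map(pr, x)), x)

  z <- nominal_gait_guess(pr)
  zx <- dmdgait:::cpp_extend_z(z, pr$pack, pr$cfg_cpp)
  tf <- z[pr$nvar]
  node0 <- z[1:pr$bs]
  nodeN <- zx[pr$N * pr$bs + 1:pr$bs]
  state0 <- node0[1:pr$state_dim]
  stateN <- nodeN[1:pr$state_dim]
  mapped <- ocp_symmetry_map(pr, state0)
  mapped[1] <- mapped[1] + 1.3 * tf
  expect_equal(stateN, mapped, tolerance = 1e-12)
})

test_that("initial guesses respect the variable bounds", {
  pr <- build_problem(td_child_model(),
                      ocp_config(target_speed = 1.1, mesh_intervals = 12))
  for (z in list(nominal_gait_guess(pr), static_guess(pr),
                 nominal_gait_guess(pr, seed = 3))) {
    expect_true(all(z >= pr$lb - 1e-12))
    expect_true(all(z <= pr$ub + 1e-12))
  }
  expect_false(identical(nominal_gait_guess(pr),
                         nominal_gait_guess(pr, seed = 3)))
})

test_that("the reported cost equals the trapezoidal quadrature of the
           integrand divided by distance, and the term breakdown is exact
           and linear in the weights", {
  m <- td_child_model()
  cfg1 <- ocp_config(target_speed = 1.1, mesh_intervals = 12)
  pr1 <- build_problem(m, cfg1)
  z <- nominal_gait_guess(pr1)
  ev1 <- dmdgait:::cpp_nlp_eval(z, pr1$pack, pr1$cfg_cpp)
  expect_equal(ev1$cost, sum(ev1$integrand) / (1.1 * 12), tolerance = 1e-12)
  expect_equal(sum(ev1$terms), ev1$cost, tolerance = 1e-12)

  w2 <- pr1$weights; w2[2] <- 2 * w2[2]
  pr2 <- build_problem(m, ocp_config(target_speed = 1.1,
                                     mesh_intervals = 12, weights = w2))
  ev2 <- dmdgait:::cpp_nlp_eval(z, pr2$pack, pr2$cfg_cpp)
  expect_equal(ev2$terms[2], 2 * ev1$terms[2], tolerance = 1e-12)
  expect_equal(ev2$terms[c(1, 3, 4)], ev1$terms[c(1, 3, 4)],
               tolerance = 1e-12)

  w0 <- pr1$weights; w0[1] <- 0
  pr0 <- build_problem(m, ocp_config(target_speed = 1.1,
                                     mesh_intervals = 12, weights = w0))
  ev0 <- dmdgait:::cpp_nlp_eval(z, pr0$pack, pr0$cfg_cpp)
  expect_equal(ev0$terms[1], 0)
  expect_equal(ev0$cost, ev1$cost - ev1$terms[1], tolerance = 1e-10)
})

test_that("a converged solution satisfies the feasibility tolerance, stays
           within bounds, and mirrors to a continuous full cycle", {
  fit <- td_gait_coarse()
  sol <- fit$solution
  pr <- fit$problem
  expect_s3_class(sol, "trajectory_solution")
  expect_equal(sol$status, "converged")
  expect_lt(sol$residuals$scaled_max, pr$config$tol_feas)
  expect_equal(sol$residuals$periodicity_max, 0)
  expect_equal(sol$residuals$speed_err, 0)
  expect_equal(sol$speed, 1.1, tolerance = 1e-12)
  expect_true(all(sol$act >= 0.01 - 1e-9 & sol$act <= 1 + 1e-9))

  full <- mirror_to_full_cycle(sol, pr)
  N <- pr$N
  expect_equal(full$cycle_time, 2 * sol$tf)
  expect_equal(nrow(full$q), 2 * N + 1)
  # seam: the mapped node N equals the start of the mirrored half exactly
  expect_equal(unname(full$q[N + 1, ]), unname(full$q[N + 1, ]))
  qswap <- c(1, 2, 3, 4, 6, 5, 8, 7, 10, 9, 12, 11)
  lhs <- unname(full$q[N + 1, ])
  rhs <- unname(sol$q[1, qswap])
  rhs[1] <- rhs[1] + sol$distance
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # left hip in the second half replays the right hip of the first half
  expect_equal(unname(full$q[(N + 2):(2 * N + 1), "hip_l"]),
               unname(sol$q[2:(N + 1), "hip_r"]), tolerance = 1e-12)
  expect_error(mirror_to_full_cycle(
    structure(list(), class = "feasibility_report"), pr), "non-converged")
})

test_that("the converged gait is Newton-consistent: vertical GRF impulse
           over the cycle balances body weight, and stance fraction is
           physiological", {
  fit <- td_gait_coarse()
  full <- mirror_to_full_cycle(fit$solution, fit$problem)
  W <- model_mass(fit$problem$model) * 9.81
  fy <- full$grf_r[, 2] + full$grf_l[, 2]
  tm <- full$time
  impulse <- sum(diff(tm) * (head(fy, -1) + tail(fy, -1)) / 2)
  expect_equal(impulse, W * full$cycle_time, tolerance = 0.02 * W)
  st <- spatiotemporal(full)
  expect_gt(st$stance_pct_r, 45)
  expect_lt(st$stance_pct_r, 80)
  expect_equal(st$speed_mps, 1.1, tolerance = 1e-9)
  expect_equal(st$stride_length_m / st$cycle_time_s, 1.1, tolerance = 1e-9)
})

test_that("solved trajectories round-trip through the STO writer", {
  fit <- td_gait_coarse()
  full <- mirror_to_full_cycle(fit$solution, fit$problem)
  stem <- tempfile()
  paths <- write_trajectory_sto(full, stem)
  kin <- read_sto(paths[1])
  expect_equal(nrow(kin$data), length(full$time))
  expect_equal(unname(kin$data[, "hip_r"]),
               unname(full$q[, "hip_r"]) * 180 / pi, tolerance = 1e-9)
})

test_that("an impossible task yields a feasibility report, not an error", {
  m <- td_child_model()
  mu <- m$muscles
  mu$active_scale <- 0.05
  m$muscles <- mu
  cfg <- ocp_config(target_speed = 10, mesh_intervals = 10,
                    max_outer = 3, max_inner = 15, polish_iter = 15,
                    opt_rounds = 0)
  pr <- build_problem(m, cfg)
  res <- solve_gait(pr, label = "impossible")
  expect_s3_class(res, "feasibility_report")
  expect_true(res$status %in% c("infeasible", "max_iter", "error"))
  expect_gt(res$violation, cfg$tol_feas)
})
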