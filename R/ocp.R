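# Predictive gait trajectory optimization.
#
# The half-gait-cycle problem is transcribed by trapezoidal direct
# collocation with implicit skeletal dynamics: states are coordinates,
# velocities and muscle activations; controls are excitations and joint
# accelerations u_a; the skeletal equations of motion enter as algebraic
# path constraints M(q) u_a + bias = tau at every node. The task
# constraints — periodicity with left/right symmetry and the imposed average
# pelvis forward speed — hold by construction of the cyclic transcription
# (node N is the symmetry image of node 0 advanced by v * t_f); half-cycle
# duration is free. The cost is the distance-normalized integral of
# w1*sum(Edot^2) + w2*sum(a^2) + w3*sum(u_a^2) + w4*sum(Tp^2), an exact sum
# of squares, so the NLP is solved as constrained nonlinear least squares:
# a Gauss-Newton augmented-Lagrangian outer loop with sparse colored-FD
# Jacobians and an annealed kinematic-tracking homotopy, followed by a
# Levenberg-Marquardt feasibility polish and reduced-gradient optimality
# refinement on the constraint manifold. Infeasibility is a reported
# outcome, not an error.

#' Configuration of the predictive gait problem
#'
#' @param target_speed imposed average pelvis forward speed, m/s
#' @param mesh_intervals number of collocation intervals over the half cycle
#'   (>= 10)
#' @param weights optional numeric `c(w1, w2, w3, w4)` for the metabolic,
#'   activation, joint-acceleration and passive-torque cost terms; if NULL,
#'   package defaults with w1 and w4 normalized by body mass squared are
#'   applied at build time
#' @param tol_feas scaled constraint-violation tolerance declaring
#'   convergence
#' @param max_outer maximum augmented-Lagrangian outer iterations
#' @param max_inner maximum L-BFGS iterations per outer iteration
#' @param sharpness tanh sharpness for the smoothed metabolic conditionals
#' @param init_source `"nominal"` (parametric TD half-cycle hot start) or
#'   `"static"` (quasi-static standing fallback)
#' @param tau_act,tau_deact activation/deactivation time constants, s
#' @param track_w0 initial weight of the kinematic-tracking homotopy term
#'   that pulls early iterations toward the hot start (annealed to zero)
#' @param polish_iter maximum iterations of the final feasibility polish
#' @param opt_rounds rounds of reduced-gradient optimality refinement on the
#'   constraint manifold after feasibility is reached
#' @return list of class `ocp_config`
#' @export
ocp_config <- function(target_speed = 1.2, mesh_intervals = 20,
                       weights = NULL, tol_feas = 2e-4, max_outer = 12,
                       max_inner = 60, sharpness = 20,
                       init_source = c("nominal", "static"),
                       tau_act = 0.015, tau_deact = 0.060, track_w0 = 30,
                       polish_iter = 300, opt_rounds = 25) {
  if (target_speed <= 0) stop_field("target_speed", "must be > 0")
  if (mesh_intervals < 10) stop_field("mesh_intervals", "must be >= 10")
  if (!is.null(weights)) {
    if (length(weights) != 4 || any(weights < 0)) {
      stop_field("weights", "need 4 non-negative values")
    }
  }
  structure(list(target_speed = target_speed,
                 mesh_intervals = as.integer(mesh_intervals),
                 weights = weights, tol_feas = tol_feas,
                 max_outer = max_outer, max_inner = max_inner,
                 sharpness = sharpness,
                 init_source = match.arg(init_source),
                 tau_act = tau_act, tau_deact = tau_deact,
                 track_w0 = track_w0, polish_iter = polish_iter,
                 opt_rounds = opt_rounds),
            class = "ocp_config")
}

# left/right coordinate and muscle swap maps (1-based)
QSWAP <- c(1, 2, 3, 4, 6, 5, 8, 7, 10, 9, 12, 11)

mswap_indices <- function(model) {
  mu <- model$muscles
  idx <- seq_len(nrow(mu))
  for (i in idx) {
    if (mu$side[i] == "r") {
      idx[i] <- which(mu$name == mu$name[i] & mu$side == "l")
    } else if (mu$side[i] == "l") {
      idx[i] <- which(mu$name == mu$name[i] & mu$side == "r")
    }
  }
  idx
}

#' Left/right symmetry map on the collocation state vector
#'
#' Exchanges right and left coordinates, velocities and muscle activations;
#' applying it twice is the identity.
#'
#' @param problem an `ocp_problem`
#' @param state state vector `c(q, qdot, act)` of length 2*nq + nmus
#' @return mapped state vector
#' @export
ocp_symmetry_map <- function(problem, state) {
  nq <- problem$nq; nm <- problem$nm
  stopifnot(length(state) == 2 * nq + nm)
  msw <- problem$mswap
  c(state[QSWAP], state[nq + QSWAP], state[2 * nq + msw])
}

standing_pelvis_height <- function(model) {
  s <- model$segments
  lt <- -s$jy[s$name == "shank_r"]
  ls <- -s$jy[s$name == "hindfoot_r"]
  ct <- model$contact
  heel <- ct[ct$name == "heel_r", ]
  lt + ls - heel$y + heel$radius
}

#' Build the discretized predictive-gait problem
#'
#' Transcribes the half-gait-cycle optimal control problem for a model into
#' the NLP solved by [solve_gait()]: decision variables (states, controls and
#' free half-cycle duration, `3*nq + 2*nmus` per node plus `t_f`), trapezoidal
#' defect constraints, skeletal-dynamics path constraints, the
#' periodicity-with-symmetry map and the average-speed constraint, with
#' variable bounds and constraint scaling.
#'
#' @param model a `planar_model`
#' @param config an [ocp_config()]
#' @return list of class `ocp_problem`
#' @export
build_problem <- function(model, config) {
  validate_model(model)
  stopifnot(inherits(config, "ocp_config"))
  pack <- pack_model(model)
  nq <- length(COORD_NAMES)
  nm <- nrow(model$muscles)
  N <- config$mesh_intervals
  bs <- 3 * nq + 2 * nm
  # cyclic transcription: free nodes 0..N-1 plus t_f; node N is the symmetry
  # image of node 0 with the pelvis advanced by target_speed * t_f, so
  # periodicity and average speed hold by construction
  nvar <- bs * N + 1
  mass <- model_mass(model)

  weights <- config$weights
  if (is.null(weights)) {
    weights <- c(1 / mass^2, 10, 2e-5, 2 / mass^2)
  }

  # constraint scaling (trapezoidal defects, dynamics path)
  ns <- 2 * nq + nm
  sc_def <- c(rep(N / 0.5, nq), rep(N / 0.5 / 10, nq), rep(N / 0.5, nm))
  sc_path <- c(1 / (mass * model$gravity), 1 / (mass * model$gravity),
               rep(1 / 50, nq - 2))
  cscale <- c(rep(sc_def, N), rep(sc_path, N))
  ctype <- c(rep(c(rep("defect_q", nq), rep("defect_qdot", nq),
                   rep("defect_act", nm)), N),
             rep("dynamics", nq * N))

  # per-node bounds
  H <- standing_pelvis_height(model)
  qlb <- c(-0.5, 0.60 * H, -0.8, -0.6, rep(-0.8, 2), rep(-0.15, 2),
           rep(-1.0, 2), rep(-0.3, 2))
  qub <- c(4.0, 1.15 * H, 0.8, 0.6, rep(1.8, 2), rep(2.3, 2),
           rep(0.9, 2), rep(0.7, 2))
  qdlb <- c(-1, -2, rep(-25, 10)); qdub <- c(4, 2, rep(25, 10))
  ualb <- c(-100, -100, rep(-500, 10)); uaub <- c(100, 100, rep(500, 10))
  node_lb <- c(qlb, qdlb, rep(0.01, nm), rep(0.01, nm), ualb)
  node_ub <- c(qub, qdub, rep(1, nm), rep(1, nm), uaub)
  lb <- c(rep(node_lb, N), 0.2)
  ub <- c(rep(node_ub, N), 1.0)
  lb[1] <- 0; ub[1] <- 0  # pelvis x fixed at 0 at the first node

  msw <- mswap_indices(model)
  cfg_cpp <- list(N = N, v_target = config$target_speed,
                  weights = weights, sharp = config$sharpness,
                  tau_act = config$tau_act, tau_deact = config$tau_deact,
                  act_blend = 2, cscale = cscale,
                  qswap = as.integer(QSWAP - 1L),
                  mswap = as.integer(msw - 1L),
                  mass_total = mass)

  structure(list(model = model, config = config, pack = pack,
                 cfg_cpp = cfg_cpp, N = N, nq = nq, nm = nm, bs = bs,
                 nvar = nvar, lb = lb, ub = ub, cscale = cscale,
                 constraint_types = ctype, mswap = msw, weights = weights,
                 n_defects = ns * N,
                 state_dim = ns, collocation_order = 1L,
                 pelvis_height = H),
            class = "ocp_problem")
}

# Periodic Gaussian bump helper for the nominal joint-angle curves.
gait_bump <- function(phi, center, width) {
  phi <- phi %% 1
  exp(-((phi - center) / width)^2) + exp(-((phi - 1 - center) / width)^2) +
    exp(-((phi + 1 - center) / width)^2)
}

#' Nominal typically developing half-cycle initial guess
#'
#' Generates a kinematic hot start from closed-form nominal TD joint-angle
#' curves (harmonics and bumps reproducing the usual sagittal gait pattern),
#' with velocities and accelerations by finite differences and uniform low
#' muscle activation. Optionally perturbs the guess with seeded noise for
#' local-minimum robustness checks.
#'
#' @param problem an `ocp_problem`
#' @param tf0 initial half-cycle duration guess, s
#' @param seed optional integer; adds reproducible random perturbation
#' @param perturb perturbation amplitude as a fraction of the bound range
#' @return decision-variable vector
#' @export
nominal_gait_guess <- function(problem, tf0 = 0.40, seed = NULL,
                               perturb = 0.01) {
  N <- problem$N; nq <- problem$nq; nm <- problem$nm; bs <- problem$bs
  v <- problem$config$target_speed
  H <- problem$pelvis_height
  lam <- problem$model$height_m / generic_anthropometry()$height_m
  tk <- seq(0, 1, length.out = N + 1)    # half-cycle fraction
  h <- tf0 / N
  deg <- pi / 180

  angles <- function(phi) {
    hip <- deg * (8 + 22 * cos(2 * pi * phi))
    knee <- deg * (8 + 10 * gait_bump(phi, 0.15, 0.10) +
                     52 * gait_bump(phi, 0.72, 0.12))
    ankle <- deg * (-6 * gait_bump(phi, 0.05, 0.05) +
                      10 * gait_bump(phi, 0.45, 0.18) -
                      22 * gait_bump(phi, 0.63, 0.07))
    mt <- deg * 2 * gait_bump(phi, 0.45, 0.15)
    list(hip = hip, knee = knee, ankle = ankle, mt = mt)
  }
  phir <- tk * 0.5
  phil <- tk * 0.5 + 0.5
  r <- angles(phir); l <- angles(phil)

  q <- matrix(0, N + 1, nq)
  q[, 1] <- v * tk * tf0
  q[, 2] <- H * (0.975 + 0.008 * cos(4 * pi * phir))
  q[, 3] <- deg * 8
  q[, 4] <- 0
  q[, 5] <- r$hip; q[, 6] <- l$hip
  q[, 7] <- r$knee; q[, 8] <- l$knee
  q[, 9] <- r$ankle; q[, 10] <- l$ankle
  q[, 11] <- r$mt; q[, 12] <- l$mt

  fd <- function(x) {
    n <- nrow(x)
    d <- x
    d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / (2 * h)
    d[1, ] <- (x[2, ] - x[1, ]) / h
    d[n, ] <- (x[n, ] - x[n - 1, ]) / h
    d
  }
  qd <- fd(q)
  ua <- fd(qd)

  z <- numeric(problem$nvar)
  for (k in 0:(N - 1)) {
    off <- k * bs
    z[off + 1:nq] <- q[k + 1, ]
    z[off + nq + 1:nq] <- qd[k + 1, ]
    z[off + 2 * nq + 1:nm] <- 0.1
    z[off + 2 * nq + nm + 1:nm] <- 0.1
    z[off + 2 * nq + 2 * nm + 1:nq] <- ua[k + 1, ]
  }
  z[problem$nvar] <- tf0
  if (!is.null(seed)) {
    z <- with_seed(seed, {
      rng <- (problem$ub - problem$lb) * perturb
      rng[!is.finite(rng)] <- 0
      z + rnorm(length(z)) * rng
    })
  }
  clamp(z, problem$lb, problem$ub)
}

#' Transfer a decision vector between mesh resolutions
#'
#' Linearly interpolates the per-node states and controls of a solution (or
#' guess) from one problem's mesh onto another's, for mesh-continuation warm
#' starts (solve coarse, refine fine).
#'
#' @param z decision vector on `problem_from`'s mesh
#' @param problem_from,problem_to `ocp_problem`s for the same model family
#' @return decision vector on `problem_to`'s mesh
#' @export
refine_mesh <- function(z, problem_from, problem_to) {
  stopifnot(problem_from$bs == problem_to$bs)
  N1 <- problem_from$N; N2 <- problem_to$N; bs <- problem_from$bs
  t1 <- (0:(N1 - 1)) / N1
  t2 <- (0:(N2 - 1)) / N2
  zm <- matrix(z[seq_len(bs * N1)], nrow = bs)
  out <- matrix(0, bs, N2)
  for (s in seq_len(bs)) {
    out[s, ] <- approx(t1, zm[s, ], xout = t2, rule = 2)$y
  }
  clamp(c(as.numeric(out), z[length(z)]), problem_to$lb, problem_to$ub)
}

#' Quasi-static standing fallback initial guess
#' @param problem an `ocp_problem`
#' @param tf0 initial half-cycle duration, s
#' @return decision-variable vector
#' @export
static_guess <- function(problem, tf0 = 0.40) {
  N <- problem$N; nq <- problem$nq; nm <- problem$nm; bs <- problem$bs
  v <- problem$config$target_speed
  z <- numeric(problem$nvar)
  tk <- seq(0, 1, length.out = N + 1)
  for (k in 0:(N - 1)) {
    off <- k * bs
    q <- numeric(nq)
    q[1] <- v * tk[k + 1] * tf0
    q[2] <- problem$pelvis_height * 0.98
    q[5:8] <- 0.1
    z[off + 1:nq] <- q
    z[off + nq + 1] <- v
    z[off + 2 * nq + 1:(2 * nm)] <- 0.1
  }
  z[problem$nvar] <- tf0
  clamp(z, problem$lb, problem$ub)
}

# raw (unscaled) residual classes of a scaled constraint vector; the
# periodicity-with-symmetry map and the average-speed constraint hold by
# construction of the cyclic transcription, so their residuals are exactly 0
residual_summary <- function(problem, c_scaled) {
  raw <- c_scaled / problem$cscale
  ct <- problem$constraint_types
  list(
    scaled_max = max(abs(c_scaled)),
    defect_max = max(abs(raw[startsWith(ct, "defect")])),
    dynamics_max = max(abs(raw[ct == "dynamics"])),
    periodicity_max = 0,
    speed_err = 0)
}

#' Solve the predictive gait problem
#'
#' Augmented-Lagrangian outer loop over box-constrained L-BFGS, then a
#' sparse Levenberg-Marquardt feasibility polish on the constraint manifold.
#' A solve that cannot reach the feasibility tolerance returns a
#' `feasibility_report` (a scientific outcome mirroring loss of ambulation
#' under severe impairment) rather than raising an error.
#'
#' @param problem an `ocp_problem`
#' @param guess decision-variable vector; default [nominal_gait_guess()]
#' @param label variant label recorded in the result
#' @param verbose print progress
#' @return a `trajectory_solution` on convergence, else a
#'   `feasibility_report`
#' @export
solve_gait <- function(problem, guess = NULL, label = "variant",
                       verbose = FALSE) {
  stopifnot(inherits(problem, "ocp_problem"))
  res <- tryCatch(
    solve_gait_impl(problem, guess, label, verbose),
    error = function(e) {
      structure(list(label = label, status = "error",
                     violation = Inf, iterations = 0L,
                     note = paste("solver crash:", conditionMessage(e))),
                class = "feasibility_report")
    })
  res
}

solve_gait_impl <- function(problem, guess, label, verbose) {
  cfg <- problem$config
  pack <- problem$pack
  ccpp <- problem$cfg_cpp
  if (is.null(guess)) {
    guess <- if (cfg$init_source == "nominal") nominal_gait_guess(problem)
             else static_guess(problem)
  }
  z <- clamp(guess, problem$lb, problem$ub)
  track_ref <- z
  m <- length(problem$cscale)
  lam <- numeric(m)
  mu <- 100
  eta <- 0.1   # multiplier-update acceptance curve (LANCELOT-style)
  total_inner <- 0L
  z_best <- z
  cinf_best <- Inf

  for (outer in seq_len(cfg$max_outer)) {
    # kinematic-tracking homotopy: strong pull toward the hot start early,
    # annealed to zero so the final iterations solve the pure problem
    track_w <- cfg$track_w0 * 0.25^(outer - 1)
    if (track_w < 1e-3 * cfg$track_w0) track_w <- 0
    inner <- gn_lm_inner(problem, z, lam, mu, maxit = cfg$max_inner,
                         track_w = track_w, track_ref = track_ref,
                         verbose = verbose)
    z <- inner$z
    total_inner <- total_inner + inner$iterations
    cvec <- inner$c
    cinf <- max(abs(cvec))
    if (verbose) {
      message(sprintf(
        "GN-AL outer %d: cost %.4g, |c|_inf %.3g, mu %.1g, track %.3g",
        outer, inner$cost, cinf, mu, track_w))
    }
    if (track_w == 0 && cinf < cinf_best) {
      cinf_best <- cinf
      z_best <- z
    }
    if (cinf < cfg$tol_feas && track_w == 0) break
    if (cinf <= eta) {
      lam <- lam + mu * cvec
      eta <- max(eta * 0.25, cfg$tol_feas)
    } else {
      mu <- min(mu * 5, 1e7)
    }
  }

  pol <- polish_feasibility(problem, z_best, verbose,
                            max_iter = cfg$polish_iter)
  z <- pol$z
  ev <- cpp_nlp_eval(z, pack, ccpp)
  cinf <- max(abs(ev$constraints))

  if (cinf > cfg$tol_feas) {
    status <- if (cinf > 1e-3) "infeasible" else "max_iter"
    return(structure(list(label = label, status = status, violation = cinf,
                          iterations = total_inner,
                          note = sprintf(
                            "no gait satisfying all constraints found (final scaled violation %.3g)",
                            cinf),
                          z = z),
                     class = "feasibility_report"))
  }
  z <- optimize_on_manifold(problem, z, rounds = cfg$opt_rounds,
                            verbose = verbose)
  ev <- cpp_nlp_eval(z, pack, ccpp)
  build_solution(problem, z, ev, label, total_inner)
}

# Levenberg-Marquardt inner solve of the augmented-Lagrangian least-squares
# subproblem min 0.5*||rho(z)||^2 with rho = [sqrt(mu)(c + lam/mu); cost
# residuals], sparse colored-FD Jacobians, bound-active variables frozen and
# steps projected into the box.
gn_lm_inner <- function(problem, z, lam, mu, maxit = 60, track_w = 0,
                        track_ref = z, verbose = FALSE) {
  pack <- problem$pack; ccpp <- problem$cfg_cpp
  lb <- problem$lb; ub <- problem$ub
  sqmu <- sqrt(mu)
  lamshift <- lam / mu
  fdstep <- 1e-6
  nu <- 1e-4
  jac <- cpp_gn_jac(z, pack, ccpp, lamshift, sqmu, fdstep, track_w, track_ref)
  f0 <- jac$obj
  iterations <- 0L
  for (it in seq_len(maxit)) {
    iterations <- it
    J <- Matrix::sparseMatrix(i = jac$i + 1L, j = jac$j + 1L, x = jac$v,
                              dims = c(jac$m, jac$n))
    g <- as.numeric(Matrix::crossprod(J, jac$rho))
    atlo <- z <= lb + 1e-12
    athi <- z >= ub - 1e-12
    free <- which(!((atlo & g > 0) | (athi & g < 0)))
    Jf <- J[, free, drop = FALSE]
    gf <- g[free]
    A <- Matrix::crossprod(Jf)
    dA <- pmax(Matrix::diag(A), 1e-8)
    accepted <- FALSE
    for (try in 1:8) {
      step <- tryCatch(
        as.numeric(Matrix::solve(A + nu * Matrix::Diagonal(x = dA), -gf)),
        error = function(e) NULL)
      if (!is.null(step)) {
        zt <- z
        zt[free] <- zt[free] + step
        zt <- clamp(zt, lb, ub)
        evt <- cpp_gn_eval(zt, pack, ccpp, lamshift, sqmu, track_w, track_ref)
        if (is.finite(evt$obj) && evt$obj < f0) {
          z <- zt
          f0 <- evt$obj
          nu <- max(nu / 5, 1e-10)
          accepted <- TRUE
          break
        }
      }
      nu <- nu * 10
      if (nu > 1e10) break
    }
    if (!accepted) break
    jac <- cpp_gn_jac(z, pack, ccpp, lamshift, sqmu, fdstep, track_w,
                      track_ref)
    f0 <- jac$obj
    if (verbose && it %% 10 == 0) {
      message(sprintf("  LM %d: obj %.6g, |c|_inf %.3g, nu %.1g",
                      it, f0, max(abs(jac$c)), nu))
    }
    if (max(abs(g)) < 1e-10) break
  }
  list(z = z, c = jac$c, cost = jac$cost, iterations = iterations)
}

# Reduced-gradient optimality refinement on the constraint manifold:
# project the cost gradient onto the tangent space of the constraints, take
# a line-searched descent step, restore feasibility with a short polish, and
# accept only feasible cost decreases. Equalizes the optimality of solves
# that the augmented-Lagrangian phase leaves at different depths.
optimize_on_manifold <- function(problem, z, rounds = 25, verbose = FALSE) {
  pack <- problem$pack; ccpp <- problem$cfg_cpp
  lb <- problem$lb; ub <- problem$ub
  tol <- problem$config$tol_feas
  mcon <- length(problem$cscale)
  zeros <- numeric(mcon)
  cost_now <- cpp_nlp_eval(z, pack, ccpp)$cost
  alpha <- 0.1
  for (r in seq_len(rounds)) {
    jac <- cpp_gn_jac(z, pack, ccpp, zeros, 1, 1e-6, 0, z)
    J <- Matrix::sparseMatrix(i = jac$i + 1L, j = jac$j + 1L, x = jac$v,
                              dims = c(jac$m, jac$n))
    Jc <- J[seq_len(mcon), , drop = FALSE]
    Jf <- J[-seq_len(mcon), , drop = FALSE]
    gradf <- 2 * as.numeric(Matrix::crossprod(
      Jf, jac$rho[-seq_len(mcon)]))
    # project out the constraint normals
    A <- Matrix::tcrossprod(Jc) +
      Matrix::Diagonal(mcon, 1e-8)
    lamhat <- tryCatch(
      as.numeric(Matrix::solve(A, as.numeric(Jc %*% gradf))),
      error = function(e) NULL)
    if (is.null(lamhat)) break
    d <- -(gradf - as.numeric(Matrix::crossprod(Jc, lamhat)))
    dn <- sqrt(sum(d^2))
    if (dn < 1e-10) break
    d <- d / dn
    improved <- FALSE
    while (alpha > 1e-4) {
      zt <- clamp(z + alpha * d, lb, ub)
      pol <- polish_feasibility(problem, zt, max_iter = 25)
      evt <- cpp_nlp_eval(pol$z, pack, ccpp)
      if (max(abs(evt$constraints)) < tol && evt$cost < cost_now - 1e-10) {
        z <- pol$z
        cost_now <- evt$cost
        improved <- TRUE
        alpha <- min(alpha * 1.5, 1)
        break
      }
      alpha <- alpha / 2
    }
    if (verbose) {
      message(sprintf("  manifold %d: cost %.5g, alpha %.3g", r, cost_now,
                      alpha))
    }
    if (!improved) break
  }
  z
}

# Sparse Levenberg-Marquardt iteration minimizing ||c(z)||^2, with
# bound-active variables frozen and steps projected into the box.
polish_feasibility <- function(problem, z, verbose = FALSE, max_iter = 300) {
  pack <- problem$pack; ccpp <- problem$cfg_cpp
  lb <- problem$lb; ub <- problem$ub
  fdstep <- 1e-5
  nu <- 1e-7
  ev <- cpp_nlp_eval(z, pack, ccpp)
  cc <- ev$constraints
  f0 <- 0.5 * sum(cc^2)
  cinf <- max(abs(cc))
  J <- NULL
  since_refresh <- 0L
  for (it in seq_len(max_iter)) {
    if (cinf < 0.5 * problem$config$tol_feas) break
    if (is.null(J) || since_refresh >= 4L) {
      jac <- cpp_nlp_jac(z, pack, ccpp, fdstep, centered = TRUE)
      J <- Matrix::sparseMatrix(i = jac$i + 1L, j = jac$j + 1L, x = jac$v,
                                dims = c(jac$m, jac$n))
      since_refresh <- 0L
    }
    g <- as.numeric(Matrix::crossprod(J, cc))
    atlo <- z <= lb + 1e-12; athi <- z >= ub - 1e-12
    free <- which(!((atlo & g > 0) | (athi & g < 0)))
    Jf <- J[, free, drop = FALSE]
    A <- Matrix::crossprod(Jf)
    dA <- pmax(Matrix::diag(A), 1e-8)
    accepted <- FALSE
    for (try in 1:10) {
      step <- tryCatch(
        as.numeric(Matrix::solve(A + nu * Matrix::Diagonal(x = dA),
                                 -g[free])),
        error = function(e) NULL)
      if (!is.null(step)) {
        zt <- z
        zt[free] <- zt[free] + step
        zt <- clamp(zt, lb, ub)
        evt <- cpp_nlp_eval(zt, pack, ccpp)
        ft <- 0.5 * sum(evt$constraints^2)
        if (is.finite(ft) && ft < f0) {
          z <- zt; f0 <- ft; cc <- evt$constraints
          cinf <- max(abs(cc))
          nu <- max(nu / 5, 1e-10)
          accepted <- TRUE
          since_refresh <- since_refresh + 1L
          break
        }
      }
      nu <- nu * 10
      if (nu > 1e8) break
    }
    if (verbose && it %% 20 == 0) {
      message(sprintf("  polish %d: |c|_inf %.3g, nu %.1g", it, cinf, nu))
    }
    if (!accepted) {
      if (since_refresh == 0L) break  # fresh Jacobian and still no step
      J <- NULL                       # retry once with a fresh Jacobian
    }
  }
  list(z = z, cinf = cinf)
}

build_solution <- function(problem, z, ev, label, iterations) {
  N <- problem$N; nq <- problem$nq; nm <- problem$nm; bs <- problem$bs
  tf <- z[problem$nvar]
  zx <- cpp_extend_z(z, problem$pack, problem$cfg_cpp)
  grab <- function(offset, len) {
    t(vapply(0:N, function(k) zx[k * bs + offset + seq_len(len)],
             numeric(len)))
  }
  q <- grab(0, nq); qd <- grab(nq, nq)
  act <- grab(2 * nq, nm); exc <- grab(2 * nq + nm, nm)
  ua <- grab(2 * nq + 2 * nm, nq)
  colnames(q) <- colnames(qd) <- colnames(ua) <- COORD_NAMES
  mu <- problem$model$muscles
  colnames(act) <- colnames(exc) <- paste(mu$name, mu$side, sep = "_")
  outs <- cpp_traj_outputs(z, problem$pack, problem$cfg_cpp)
  colnames(outs$tau_muscle) <- colnames(outs$tau_passive) <- COORD_NAMES
  colnames(outs$grf_r) <- colnames(outs$grf_l) <- c("fx", "fy")
  structure(list(
    label = label, status = "converged",
    time = seq(0, tf, length.out = N + 1),
    tf = tf, distance = ev$distance,
    q = q, qdot = qd, act = act, exc = exc, ua = ua,
    cost = ev$cost, breakdown = setNames(ev$terms, c(
      "metabolic", "activation", "acceleration", "passive_torque")),
    grf_r = outs$grf_r, grf_l = outs$grf_l,
    tau_muscle = outs$tau_muscle, tau_passive = outs$tau_passive,
    metabolic_rate = outs$metabolic_rate,
    residuals = residual_summary(problem, ev$constraints),
    iterations = iterations, z = z,
    speed = ev$distance / tf), class = "trajectory_solution")
}

#' @export
print.trajectory_solution <- function(x, ...) {
  cat(sprintf(
    "<trajectory_solution> %s: converged; tf %.3f s, speed %.4f m/s, J %.4g\n",
    x$label, x$tf, x$speed, x$cost))
  cat(sprintf("  residuals: scaled %.2g, periodicity %.2g, speed %.2g m/s\n",
              x$residuals$scaled_max, x$residuals$periodicity_max,
              x$residuals$speed_err))
  invisible(x)
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf("<feasibility_report> %s: %s (violation %.3g after %d iter)\n  %s\n",
              x$label, x$status, x$violation, x$iterations, x$note))
  invisible(x)
}

#' Mirror a converged half-cycle solution to a full gait cycle
#'
#' The second half is the first half with left and right quantities
#' exchanged and the pelvis advanced by the traveled distance; by the
#' periodicity-with-symmetry constraint the two halves join continuously at
#' the seam.
#'
#' @param solution a converged `trajectory_solution`
#' @param problem the `ocp_problem` it came from
#' @return list of class `full_cycle` with 2N+1 samples over `[0, 2 t_f]`
#' @export
mirror_to_full_cycle <- function(solution, problem) {
  if (!inherits(solution, "trajectory_solution")) {
    stop("cannot mirror a non-converged result", call. = FALSE)
  }
  N <- problem$N
  msw <- problem$mswap
  d <- solution$distance
  second <- function(M, swap_cols, shift = NULL) {
    M2 <- M[2:(N + 1), swap_cols, drop = FALSE]
    if (!is.null(shift)) M2[, shift] <- M2[, shift] + d
    colnames(M2) <- colnames(M)
    rbind(M, M2)
  }
  q_full <- second(solution$q, QSWAP, shift = 1)
  qd_full <- second(solution$qdot, QSWAP)
  ua_full <- second(solution$ua, QSWAP)
  act_full <- second(solution$act, msw)
  exc_full <- second(solution$exc, msw)
  tau_m <- second(solution$tau_muscle, QSWAP)
  tau_p <- second(solution$tau_passive, QSWAP)
  grf_r_full <- rbind(solution$grf_r, solution$grf_l[2:(N + 1), , drop = FALSE])
  grf_l_full <- rbind(solution$grf_l, solution$grf_r[2:(N + 1), , drop = FALSE])
  structure(list(
    label = solution$label,
    time = seq(0, 2 * solution$tf, length.out = 2 * N + 1),
    cycle_time = 2 * solution$tf, distance = 2 * d,
    speed = solution$speed,
    q = q_full, qdot = qd_full, ua = ua_full,
    act = act_full, exc = exc_full,
    tau_muscle = tau_m, tau_passive = tau_p,
    grf_r = grf_r_full, grf_l = grf_l_full,
    metabolic_rate = c(solution$metabolic_rate,
                       solution$metabolic_rate[2:(N + 1)]),
    mass_kg = model_mass(problem$model)), class = "full_cycle")
}
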