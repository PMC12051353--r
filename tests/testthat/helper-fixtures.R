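# Shared fixtures. Gait solves are expensive, so the typically developing
# reference simulation is solved once per test run and cached; dependent
# tests reuse it.

.fixture_env <- new.env(parent = emptyenv())

td_summary_fixture <- function() {
  if (is.null(.fixture_env$td_summary)) {
    .fixture_env$td_summary <-
      summarize_group(generate_cohort(builtin_profiles()$TD, 50, seed = 2))
  }
  .fixture_env$td_summary
}

td_child_model <- function() {
  if (is.null(.fixture_env$td_model)) {
    .fixture_env$td_model <-
      personalize_model(default_planar_model(), td_summary_fixture())
  }
  .fixture_env$td_model
}

# Reference-quality TD gait solve shared across the suite: 25 mesh
# intervals, reached by mesh continuation from a 12-interval solve.
td_gait_fixture <- function() {
  if (is.null(.fixture_env$td_gait)) {
    m <- td_child_model()
    cfg12 <- ocp_config(target_speed = 1.2, mesh_intervals = 12,
                        track_w0 = 3)
    pr12 <- build_problem(m, cfg12)
    s12 <- solve_gait(pr12, label = "td12")
    cfg25 <- ocp_config(target_speed = 1.2, mesh_intervals = 25,
                        track_w0 = 1)
    pr25 <- build_problem(m, cfg25)
    guess <- if (inherits(s12, "trajectory_solution")) {
      refine_mesh(s12$z, pr12, pr25)
    } else NULL
    sol <- solve_gait(pr25, guess = guess, label = "td_reference")
    .fixture_env$td_gait <- list(problem = pr25, solution = sol)
  }
  .fixture_env$td_gait
}

# Faster mesh used for the directional variant solves.
td_gait_coarse <- function() {
  if (is.null(.fixture_env$td_coarse)) {
    cfg <- ocp_config(target_speed = 1.1, mesh_intervals = 12,
                      track_w0 = 3)
    pr <- build_problem(td_child_model(), cfg)
    sol <- solve_gait(pr, label = "td_coarse")
    .fixture_env$td_coarse <- list(problem = pr, solution = sol)
  }
  .fixture_env$td_coarse
}

# Directional-comparison chain: all variants share one deeply optimized TD
# start so differences between solves reflect the model change, not the
# depth of the local optimum. Solved once and cached.
directional_chain <- function() {
  if (!is.null(.fixture_env$chain)) return(.fixture_env$chain)
  coarse <- td_gait_coarse()
  prb <- coarse$problem
  deep <- solve_gait(prb, guess = coarse$solution$z, label = "td_deep")
  stopifnot(inherits(deep, "trajectory_solution"))
  zstar <- deep$z
  sets <- list(
    pf07 = impairment_set(sigma = c(soleus = 0.7, gastroc = 0.7),
                          label = "pf07"),
    pf04 = impairment_set(sigma = c(soleus = 0.4, gastroc = 0.4),
                          label = "pf04"),
    pf04s = impairment_set(sigma = c(soleus = 0.4, gastroc = 0.4),
                           shift = c(soleus = 0.5, gastroc = 0.5),
                           contractures_included = TRUE, label = "pf04s"))
  # severity continuation: each variant warm starts from the previous
  # severity's solution, so every comparison is between adjacent optima
  chain <- list(base = list(problem = prb,
                            solution = solve_gait(prb, guess = zstar,
                                                  label = "base")))
  prev <- zstar
  for (lab in names(sets)) {
    chain[[lab]] <- solve_variant(sets[[lab]], guess = prev)
    if (inherits(chain[[lab]]$solution, "trajectory_solution")) {
      prev <- chain[[lab]]$solution$z
    }
  }
  # midfoot-break comparison in the flexion-pattern context: a model with
  # proximal-dominant weakness and contractures, with and without the foot
  # deformity; the deformed variant warm starts from its parent's solution
  # so the small model change is evaluated against the matching optimum
  sig3 <- c(glut_max = 0.45, iliopsoas = 0.6, hamstrings = 0.5,
            rectus_fem = 0.5, vasti = 0.45, gastroc = 0.55, soleus = 0.55,
            tib_ant = 0.55, back_ext = 0.45, abdominal = 0.45)
  sh3 <- c(soleus = 0.4, gastroc = 0.4, hamstrings = 0.3, iliopsoas = 0.3)
  zbase <- if (inherits(chain$base$solution, "trajectory_solution")) {
    chain$base$solution$z
  } else zstar
  chain$d3_wc <- solve_variant(
    impairment_set(sigma = sig3, shift = sh3, contractures_included = TRUE,
                   label = "d3_wc"), guess = zbase)
  if (inherits(chain$d3_wc$solution, "trajectory_solution")) {
    chain$d3_wcm <- solve_variant(
      impairment_set(sigma = sig3, shift = sh3, midfoot_break = TRUE,
                     contractures_included = TRUE, label = "d3_wcm"),
      guess = chain$d3_wc$solution$z)
  }
  .fixture_env$chain <- chain
  chain
}

solve_variant <- function(set, target_speed = 1.1, mesh_intervals = 12,
                          guess = NULL, label = set$label, ...) {
  mdl <- apply_impairments(td_child_model(), set)
  cfg <- ocp_config(target_speed = target_speed,
                    mesh_intervals = mesh_intervals, track_w0 = 3, ...)
  pr <- build_problem(mdl, cfg)
  sol <- solve_gait(pr, guess = guess, label = label)
  list(problem = pr, solution = sol)
}

features_of <- function(fit) {
  full <- mirror_to_full_cycle(fit$solution, fit$problem)
  dmdgait:::gait_features(time_normalize(full))
}
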