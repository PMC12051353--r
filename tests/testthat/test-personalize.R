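# Personalization: anthropometric scaling, excess-mass redistribution,
# weakness factors, contracture shifts, foot deformity, experiment plans.

test_that("manual-muscle-test scores convert to deficits relative to 5", {
  expect_equal(mmt_to_deficit(5), 0)
  expect_equal(mmt_to_deficit(0), 1)
  expect_equal(mmt_to_deficit(3), 0.4)
  expect_error(mmt_to_deficit(6), "score")
})

test_that("identity scaling leaves the generic model unchanged", {
  g <- default_planar_model()
  spec <- scaling_spec(g$height_m, model_mass(g),
                       expected_td_mass_kg = model_mass(g))
  expect_equal(scale_model(g, spec), g, tolerance = 1e-12)
})

test_that("geometric-similarity scaling: lengths ~ lambda, forces ~
           lambda^2, inertias ~ mass ratio x lambda^2", {
  g <- default_planar_model()
  lam <- 0.8
  h <- lam * g$height_m
  em <- expected_td_mass(h)
  spec <- scaling_spec(h, em, expected_td_mass_kg = em)
  m <- scale_model(g, spec)
  rho <- em / model_mass(g)
  expect_equal(m$muscles$f_max, g$muscles$f_max * lam^2, tolerance = 1e-12)
  expect_equal(m$muscles$l_opt, g$muscles$l_opt * lam, tolerance = 1e-12)
  expect_equal(m$segments$jy, g$segments$jy * lam, tolerance = 1e-12)
  expect_equal(m$segments$mass, g$segments$mass * rho, tolerance = 1e-12)
  expect_equal(m$segments$inertia, g$segments$inertia * rho * lam^2,
               tolerance = 1e-12)
  expect_equal(m$contact$radius, g$contact$radius * lam, tolerance = 1e-12)
  expect_equal(model_mass(m), em, tolerance = 1e-9)
})

test_that("excess mass splits 2/3 to trunk+pelvis, 1/3 to thighs+shanks,
           none to the feet, conserving total mass", {
  g <- default_planar_model()
  em <- model_mass(g)
  spec <- scaling_spec(g$height_m, em + 9, expected_td_mass_kg = em)
  m <- redistribute_excess_mass(g, spec)
  s0 <- g$segments; s1 <- m$segments
  trunk <- s1$name %in% c("pelvis", "torso")
  legs <- s1$name %in% c("thigh_r", "thigh_l", "shank_r", "shank_l")
  feet <- grepl("foot", s1$name)
  expect_equal(sum(s1$mass[trunk] - s0$mass[trunk]), 6, tolerance = 1e-9)
  expect_equal(sum(s1$mass[legs] - s0$mass[legs]), 3, tolerance = 1e-9)
  expect_equal(s1$mass[feet], s0$mass[feet])
  expect_equal(sum(s1$mass), em + 9, tolerance = (em + 9) * 1e-9)
  # zero excess: identity; negative excess: error advising the TD path
  spec0 <- scaling_spec(g$height_m, em, expected_td_mass_kg = em)
  expect_identical(redistribute_excess_mass(g, spec0), g)
  specn <- scaling_spec(g$height_m, em - 1, expected_td_mass_kg = em)
  expect_error(redistribute_excess_mass(g, specn), "TD")
})

test_that("weakness factors apply group deficits uniformly with the
           biarticular-mean rule and the 0.01 floor", {
  s <- summarize_group(generate_cohort(builtin_profiles()$DMD2, 30, seed = 5))
  s$strength$mid <- rep(0, nrow(s$strength))
  sig <- weakness_factors(s, "mean")
  expect_true(all(abs(sig - 1) < 1e-12))

  s$strength$mid[s$strength$measure == "plantar_flex"] <- 0.6
  s$strength$mid[s$strength$measure == "knee_flex"] <- 0.2
  sig <- weakness_factors(s, "mean")
  expect_equal(unname(sig["soleus"]), 0.4)
  expect_equal(unname(sig["gastroc"]), mean(c(0.4, 0.8)))
  expect_equal(unname(sig["foot_intrinsic"]), 1)

  s$strength$mid <- rep(1, nrow(s$strength))
  sig <- weakness_factors(s, "mean")
  expect_true(all(sig[names(sig) != "foot_intrinsic"] == 0.01))
})

test_that("contracture shift estimator: ordinal map, ROM conversion, and
           averaging of the two paths", {
  expect_equal(estimate_contracture_shift(stiffness_score = 2), 0.33)
  expect_equal(estimate_contracture_shift(stiffness_score = 0), 0)
  expect_equal(estimate_contracture_shift(stiffness_score = 3), 0.5)
  s_rom <- estimate_contracture_shift(20, 0.05, 0.10)
  expect_equal(s_rom, 20 * pi / 180 * 0.05 / 0.10, tolerance = 1e-12)
  expect_equal(s_rom, 0.17453, tolerance = 1e-4)
  s_both <- estimate_contracture_shift(20, 0.05, 0.10, stiffness_score = 1)
  expect_equal(s_both, (s_rom + 0.17) / 2, tolerance = 1e-12)
  expect_error(estimate_contracture_shift(), "ROM deficit and/or")
  expect_error(estimate_contracture_shift(-5, 0.05, 0.1), "rom_deficit")
  expect_error(estimate_contracture_shift(stiffness_score = 1.5), "ordinal")
  # cap at 0.6
  expect_equal(estimate_contracture_shift(90, 0.06, 0.05), 0.6)
})

test_that("shift estimates are order-preserving in ROM deficit and score", {
  roms <- seq(0, 40, by = 5)
  v <- vapply(roms, function(r) estimate_contracture_shift(r, 0.05, 0.1, 2),
              numeric(1))
  expect_true(all(diff(v) >= 0))
  sc <- vapply(0:3, function(s) estimate_contracture_shift(10, 0.05, 0.1, s),
               numeric(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("impairments apply symmetrically, idempotently, and validate
           muscle names", {
  g <- default_planar_model()
  expect_equal(apply_impairments(g, impairment_set()), g)
  set <- impairment_set(sigma = c(soleus = 0.4), shift = c(gastroc = 0.2))
  m <- apply_impairments(g, set)
  sol <- m$muscles[m$muscles$name == "soleus", ]
  expect_equal(sol$active_scale, c(0.4, 0.4))
  gas <- m$muscles[m$muscles$name == "gastroc", ]
  expect_equal(gas$passive_shift, c(0.2, 0.2))
  expect_true(model_is_symmetric(m))
  expect_equal(apply_impairments(m, set), m)
  bad <- impairment_set(sigma = c(biceps = 0.4))
  expect_error(apply_impairments(g, bad), "biceps")
})

test_that("foot deformity lowers foot geometry by 10% and halves intrinsic
           strength, leaving the rest untouched", {
  g <- default_planar_model()
  m <- apply_foot_deformity(g)
  heel0 <- g$contact[g$contact$name == "heel_r", ]
  heel1 <- m$contact[m$contact$name == "heel_r", ]
  expect_equal(heel1$y, 0.9 * heel0$y)
  expect_equal(heel1$x, heel0$x)
  intr <- m$muscles[m$muscles$name == "foot_intrinsic", "active_scale"]
  expect_equal(intr, c(0.5, 0.5))
  # non-foot segments unchanged
  expect_equal(m$segments[m$segments$name == "thigh_r", ],
               g$segments[g$segments$name == "thigh_r", ])
  expect_equal(sum(m$segments$mass), sum(g$segments$mass))
})

test_that("experiment plans: six DMD variants, a seventh midfoot-break
           variant for DMD3, one unimpaired TD reference", {
  profs <- builtin_profiles()
  d1 <- summarize_group(generate_cohort(profs$DMD1, 30, seed = 4))
  plan1 <- build_experiment_plan(d1)
  expect_length(plan1, 6)
  expect_false(any(vapply(plan1, `[[`, logical(1), "midfoot_break")))
  expect_equal(sum(vapply(plan1, `[[`, logical(1), "contractures_included")),
               3)
  expect_false(anyDuplicated(names(plan1)) > 0)

  d3 <- summarize_group(generate_cohort(profs$DMD3, 30, seed = 4))
  plan3 <- build_experiment_plan(d3)
  expect_length(plan3, 7)
  expect_equal(sum(vapply(plan3, `[[`, logical(1), "midfoot_break")), 1)

  td <- summarize_group(generate_cohort(profs$TD, 30, seed = 4))
  plant <- build_experiment_plan(td)
  expect_length(plant, 1)
  expect_null(plant[[1]]$sigma)
})

test_that("the TD plan's personalized model equals the scaled generic model
           exactly (identity personalization)", {
  g <- default_planar_model()
  td <- summarize_group(generate_cohort(builtin_profiles()$TD, 30, seed = 4))
  plan <- build_experiment_plan(td)
  m1 <- personalize_model(g, td, plan[[1]])
  # the TD variant is the anthropometric pipeline with no impairments at all
  m2 <- personalize_model(g, td)
  expect_identical(m1, m2)
  expect_true(all(m1$muscles$active_scale == 1))
  expect_true(all(m1$muscles$passive_shift == 0))
  expect_true(model_is_symmetric(m1))
})

test_that("all produced sigma and shift respect parameter bounds for random
           group summaries (property)", {
  profs <- builtin_profiles()
  for (seed in 1:4) {
    grp <- c("DMD1", "DMD2", "DMD3")[seed %% 3 + 1]
    s <- summarize_group(generate_cohort(profs[[grp]], 60, seed = seed))
    for (sev in c("minus1sd", "mean", "plus1sd")) {
      sig <- weakness_factors(s, sev)
      sh <- contracture_shifts(s, sev)
      expect_true(all(sig >= 0.01 & sig <= 1))
      expect_true(all(sh >= 0 & sh <= 0.6))
      m <- personalize_model(default_planar_model(), s,
                             impairment_set(sigma = sig, shift = sh))
      expect_silent(validate_model(m))
    }
  }
})
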