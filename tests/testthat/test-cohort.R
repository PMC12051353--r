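# Synthetic-cohort generation and group summaries.

test_that("degenerate zero-variance profile yields all-zero impairments", {
  prof <- builtin_profiles()$TD
  coh <- generate_cohort(prof, 5, seed = 1)
  str_cols <- grep("^str_", names(coh), value = TRUE)
  rom_cols <- grep("^rom_", names(coh), value = TRUE)
  stiff_cols <- grep("^stiff_", names(coh), value = TRUE)
  expect_true(all(coh[str_cols] == 0))
  expect_true(all(coh[rom_cols] == 0))
  expect_true(all(coh[stiff_cols] == 0))
  expect_false(any(coh$midfoot_break))
})

test_that("identical seed reproduces the cohort exactly", {
  prof <- builtin_profiles()$DMD2
  a <- generate_cohort(prof, 25, seed = 42)
  b <- generate_cohort(prof, 25, seed = 42)
  expect_identical(a, b)
  c2 <- generate_cohort(prof, 25, seed = 43)
  expect_false(identical(a, c2))
})

test_that("truncated-normal sampling recovers the profile mean (LLN)", {
  prof <- builtin_profiles()$DMD1
  prof$strength$mean[prof$strength$measure == "hip_ext"] <- 0.40
  prof$strength$sd[prof$strength$measure == "hip_ext"] <- 0.10
  coh <- generate_cohort(prof, 2000, seed = 7)
  expect_lt(abs(mean(coh$str_hip_ext) - 0.40), 0.01)
})

test_that("invalid profiles are rejected with the offending field named", {
  prof <- builtin_profiles()$DMD1
  prof$strength$sd[3] <- -0.1
  expect_error(generate_cohort(prof, 5, seed = 1), "sd")
  prof2 <- builtin_profiles()$DMD1
  prof2$stiffness_probs[2, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generate_cohort(prof2, 5, seed = 1), "sum to 1")
})

test_that("generated records satisfy the clinical-record invariants for
           random profiles (property)", {
  base <- builtin_profiles()$DMD3
  with_seed <- dmdgait:::with_seed
  with_seed(99, {
    for (rep in 1:5) {
      prof <- base
      prof$strength$mean <- runif(nrow(prof$strength), 0, 1)
      prof$strength$sd <- runif(nrow(prof$strength), 0, 0.5)
      prof$rom$mean <- runif(nrow(prof$rom), 0, 40)
      prof$rom$sd <- runif(nrow(prof$rom), 0, 15)
      coh <- generate_cohort(prof, 40, seed = rep)
      expect_silent(validate_cohort(coh))
    }
  })
})

test_that("summarize_group matches hand arithmetic (n-1 sample SD)", {
  coh <- generate_cohort(builtin_profiles()$DMD1, 2, seed = 1)
  coh$str_knee_ext <- c(0.3, 0.5)
  s <- summarize_group(coh)
  row <- s$strength[s$strength$measure == "knee_ext", ]
  expect_equal(row$mean, 0.4)
  expect_equal(row$sd, sqrt(0.02), tolerance = 1e-12)
  expect_equal(row$minus1sd, 0.4 - sqrt(0.02), tolerance = 1e-12)
  expect_equal(row$plus1sd, 0.4 + sqrt(0.02), tolerance = 1e-12)
})

test_that("identical records give zero SD and equal severity levels;
           high means clip at 1", {
  coh <- generate_cohort(builtin_profiles()$DMD1, 3, seed = 1)
  coh$str_hip_ext <- rep(0.37, 3)
  s <- summarize_group(coh)
  row <- s$strength[s$strength$measure == "hip_ext", ]
  expect_equal(row$sd, 0)
  expect_equal(unname(unlist(row[c("minus1sd", "mid", "plus1sd")])),
               rep(0.37, 3))
  coh$str_hip_ext <- c(0.85, 0.95, 1.0)
  s2 <- summarize_group(coh)
  row2 <- s2$strength[s2$strength$measure == "hip_ext", ]
  expect_equal(row2$plus1sd, 1.0)
})

test_that("summarize_group rejects tiny or mixed-group inputs", {
  coh <- generate_cohort(builtin_profiles()$DMD1, 2, seed = 1)
  expect_error(summarize_group(coh[1, ]), "at least 2")
  coh$group[2] <- "DMD2"
  expect_error(summarize_group(coh), "mix")
})

test_that("severity levels are monotone and summaries recover profile means
           within 3 SD / sqrt(n) (parameter recovery, n = 500)", {
  for (grp in c("DMD1", "DMD2", "DMD3")) {
    prof <- builtin_profiles()[[grp]]
    coh <- generate_cohort(prof, 500, seed = 11)
    s <- summarize_group(coh)
    expect_true(all(s$strength$minus1sd <= s$strength$mid + 1e-12))
    expect_true(all(s$strength$mid <= s$strength$plus1sd + 1e-12))
    expect_true(all(s$stiffness$minus1sd <= s$stiffness$mid))
    expect_true(all(s$stiffness$mid <= s$stiffness$plus1sd))
    for (i in seq_len(nrow(prof$strength))) {
      m <- prof$strength$mean[i]
      sd_i <- prof$strength$sd[i]
      # truncation pulls the sample mean slightly off the nominal mean;
      # bound only applies away from the hard clip at the interval ends
      if (m > 3 * sd_i && m < 1 - 3 * sd_i) {
        expect_lt(abs(s$strength$mean[i] - m), 3 * sd_i / sqrt(500) + 1e-9)
      }
    }
  }
})

test_that("built-in profiles encode the distal- vs proximal-dominant
           structure of the three DMD gait-pattern groups", {
  p <- builtin_profiles()
  get_mean <- function(prof, ms) {
    prof$strength$mean[prof$strength$measure == ms]
  }
  # DMD2 (tiptoeing): plantar-flexor deficit dominates hip extensors
  expect_gt(get_mean(p$DMD2, "plantar_flex"), get_mean(p$DMD2, "hip_ext"))
  # DMD3 (flexion pattern): proximal extensor deficits dominate
  expect_gt(get_mean(p$DMD3, "hip_ext"), get_mean(p$DMD3, "plantar_flex"))
  expect_equal(p$DMD3$midfoot_break_prevalence, 1)
  expect_equal(p$TD$midfoot_break_prevalence, 0)
})

test_that("expected TD body mass follows the allometric height^3 rule", {
  ga <- generic_anthropometry()
  expect_equal(expected_td_mass(ga$height_m), ga$mass_kg, tolerance = 1e-12)
  expect_equal(expected_td_mass(ga$height_m / 2), ga$mass_kg / 8,
               tolerance = 1e-12)
  expect_error(expected_td_mass(-1), "height")
})
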