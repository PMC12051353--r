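# Model personalization: anthropometric scaling with excess-mass
# redistribution, weakness factors from strength deficits, contracture shifts
# from ROM deficits and ordinal stiffness scores, foot deformity, and the
# six/seven-model experiment plan per group.

# Ordinal clinical-stiffness score (0-3) -> passive-curve shift.
STIFFNESS_SHIFT_MAP <- c(`0` = 0, `1` = 0.17, `2` = 0.33, `3` = 0.5)

# Muscle -> strength measure(s); biarticular muscles average their two
# joint-function groups' sigma.
WEAKNESS_MAP <- list(
  glut_max = "hip_ext",
  iliopsoas = "hip_flex",
  hamstrings = c("hip_ext", "knee_flex"),
  rectus_fem = c("hip_flex", "knee_ext"),
  vasti = "knee_ext",
  gastroc = c("knee_flex", "plantar_flex"),
  soleus = "plantar_flex",
  tib_ant = "dorsiflex",
  back_ext = "back",
  abdominal = "abdominal")

# Muscle -> (ROM test, moment arm at the tested joint, optimal fiber length,
# stiffness-score group). The knee-flexed ankle test personalizes the soleus
# and the knee-extended test the gastrocnemius.
CONTRACTURE_MAP <- list(
  iliopsoas = list(rom = "hip_ext_thomas", arm = 0.05, l_opt = 0.10,
                   score = "hip_flexors"),
  rectus_fem = list(rom = NULL, arm = NA, l_opt = NA,
                    score = "rectus_femoris"),
  hamstrings = list(rom = "popliteal_angle", arm = 0.03, l_opt = 0.10,
                    score = "hamstrings"),
  gastroc = list(rom = "ankle_df_knee_ext", arm = 0.05, l_opt = 0.06,
                 score = "plantar_flex_knee_ext"),
  soleus = list(rom = "ankle_df_knee_flex", arm = 0.05, l_opt = 0.05,
                score = "plantar_flex_knee_flex"))

SIGMA_FLOOR <- 0.01
SHIFT_CAP <- 0.6

#' Scaling specification for anthropometric model scaling
#'
#' @param height_m target stature, m
#' @param target_mass_kg measured body mass, kg
#' @param expected_td_mass_kg expected mass of a typically developing child
#'   of the same stature, kg
#' @param trunk_pelvis_fraction fraction of the excess mass assigned to the
#'   trunk and pelvis segments (remainder goes to thighs and shanks)
#' @return list of class `scaling_spec`
#' @export
scaling_spec <- function(height_m, target_mass_kg,
                         expected_td_mass_kg = expected_td_mass(height_m),
                         trunk_pelvis_fraction = 2 / 3) {
  if (height_m <= 0) stop_field("height_m", "must be > 0")
  if (target_mass_kg <= 0) stop_field("target_mass_kg", "must be > 0")
  if (expected_td_mass_kg <= 0) stop_field("expected_td_mass_kg", "must be > 0")
  if (trunk_pelvis_fraction < 0 || trunk_pelvis_fraction > 1) {
    stop_field("trunk_pelvis_fraction", "must lie in [0, 1]")
  }
  structure(list(height_m = height_m, target_mass_kg = target_mass_kg,
                 expected_td_mass_kg = expected_td_mass_kg,
                 trunk_pelvis_fraction = trunk_pelvis_fraction,
                 leg_fraction = 1 - trunk_pelvis_fraction),
            class = "scaling_spec")
}

#' Scale the generic model to a child's anthropometry
#'
#' Geometric-similarity scaling: every length (segment geometry, center of
#' mass offsets, contact-sphere centers and radii, muscle optimal fiber and
#' tendon slack lengths, moment arms) scales with lambda =
#' height / generic height; segment masses scale with the mass ratio
#' expected-TD-mass / generic mass so the pre-redistribution total equals the
#' expected TD mass; inertias scale with mass x length^2; muscle maximal
#' isometric forces with lambda^2 (cross-sectional area); passive joint
#' torque magnitudes with mass ratio x lambda (weight x lever arm).
#'
#' @param generic a `planar_model` (the generic adult model)
#' @param spec a [scaling_spec()]
#' @return scaled `planar_model` (mass = expected TD mass; excess mass not
#'   yet redistributed — see [redistribute_excess_mass()])
#' @export
scale_model <- function(generic, spec) {
  validate_model(generic)
  stopifnot(inherits(spec, "scaling_spec"))
  lambda <- spec$height_m / generic$height_m
  rho <- spec$expected_td_mass_kg / model_mass(generic)
  m <- generic
  s <- m$segments
  s$jx <- s$jx * lambda; s$jy <- s$jy * lambda
  s$comx <- s$comx * lambda; s$comy <- s$comy * lambda
  s$mass <- s$mass * rho
  s$inertia <- s$inertia * rho * lambda^2
  m$segments <- s
  mu <- m$muscles
  mu$f_max <- mu$f_max * lambda^2
  mu$l_opt <- mu$l_opt * lambda
  mu$l_slack <- mu$l_slack * lambda
  arm_cols <- grep("^r_", names(mu))
  mu[, arm_cols] <- mu[, arm_cols] * lambda
  mu$lref <- mu$l_opt + mu$l_slack
  m$muscles <- mu
  ct <- m$contact
  ct$x <- ct$x * lambda; ct$y <- ct$y * lambda; ct$radius <- ct$radius * lambda
  m$contact <- ct
  p <- m$passive
  p$k1_low <- p$k1_low * rho * lambda
  p$k1_high <- p$k1_high * rho * lambda
  p$damping <- p$damping * rho * lambda
  m$passive <- p
  m$height_m <- spec$height_m
  m$mass_kg <- spec$expected_td_mass_kg
  m
}

#' Redistribute excess body mass over trunk/pelvis and leg segments
#'
#' The mass above the TD expectation is split 2/3 over the trunk and pelvis
#' segments and 1/3 over the thighs and shanks (apportioned proportionally to
#' their scaled masses); the feet gain nothing. Segment inertias scale with
#' the segment's mass gain.
#'
#' @param model a scaled `planar_model`
#' @param spec the [scaling_spec()] used for scaling
#' @return model with total mass equal to `spec$target_mass_kg`
#' @export
redistribute_excess_mass <- function(model, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  excess <- spec$target_mass_kg - spec$expected_td_mass_kg
  if (excess < 0) {
    stop(paste("target mass below the TD expectation; use the TD scaling",
               "path (no redistribution) instead"), call. = FALSE)
  }
  if (excess == 0) return(model)
  s <- model$segments
  trunk <- s$name %in% c("pelvis", "torso")
  legs <- s$name %in% c("thigh_r", "thigh_l", "shank_r", "shank_l")
  add <- numeric(nrow(s))
  add[trunk] <- spec$trunk_pelvis_fraction * excess *
    s$mass[trunk] / sum(s$mass[trunk])
  add[legs] <- spec$leg_fraction * excess * s$mass[legs] / sum(s$mass[legs])
  ratio <- (s$mass + add) / s$mass
  s$inertia <- s$inertia * ratio
  s$mass <- s$mass + add
  model$segments <- s
  model$mass_kg <- sum(s$mass)
  model
}

#' Manual-muscle-test score to strength deficit
#' @param score integer MMT score in 0-5
#' @return deficit fraction `1 - score/5`
#' @export
mmt_to_deficit <- function(score) {
  if (any(!score %in% 0:5)) stop_field("score", "must be in 0..5")
  1 - score / 5
}

#' Weakness factors (sigma per muscle) from a group summary
#'
#' sigma = 1 - deficit at the chosen severity level, applied uniformly to all
#' muscles of the joint-function group; biarticular muscles take the mean of
#' their two groups' sigma; clipped to `[0.01, 1]`. Intrinsic foot muscles
#' are not strength-tested and keep sigma = 1.
#'
#' @param summary a `group_summary`
#' @param severity `"minus1sd"`, `"mean"` or `"plus1sd"`
#' @return named numeric vector of sigma per muscle name
#' @export
weakness_factors <- function(summary, severity = "mean") {
  stopifnot(inherits(summary, "group_summary"))
  deficits <- summary_level(summary$strength, severity)
  sig <- vapply(names(WEAKNESS_MAP), function(mus) {
    groups <- WEAKNESS_MAP[[mus]]
    if (!all(groups %in% names(deficits))) {
      stop(sprintf("summary lacks strength group `%s`",
                   setdiff(groups, names(deficits))[1]), call. = FALSE)
    }
    mean(1 - deficits[groups])
  }, numeric(1))
  sig <- clamp(sig, SIGMA_FLOOR, 1)
  c(sig, foot_intrinsic = 1)
}

#' Estimate a contracture shift from ROM deficit and/or stiffness score
#'
#' The ROM path converts the end-range joint-angle deficit (degrees) to a
#' fiber-length change through the anatomical-position moment arm, normalized
#' to optimal fiber length: `s_rom = deficit * pi/180 * arm / l_opt`. The
#' ordinal path maps clinical stiffness scores 0-3 to shifts 0, 0.17, 0.33,
#' 0.5. When both are available the estimates are averaged. The result is
#' clipped to `[0, 0.6]`.
#'
#' @param rom_deficit_deg ROM deficit in degrees (>= 0), or NULL
#' @param moment_arm_m anatomical-position moment arm, m (ROM path)
#' @param l_opt_m optimal fiber length, m (ROM path)
#' @param stiffness_score integer 0-3, or NULL
#' @return shift s (normalized optimal fiber length)
#' @export
estimate_contracture_shift <- function(rom_deficit_deg = NULL,
                                       moment_arm_m = NULL, l_opt_m = NULL,
                                       stiffness_score = NULL) {
  ests <- numeric(0)
  if (!is.null(rom_deficit_deg)) {
    if (rom_deficit_deg < 0) stop_field("rom_deficit_deg", "must be >= 0")
    if (is.null(moment_arm_m) || moment_arm_m <= 0) {
      stop_field("moment_arm_m", "must be > 0 for the ROM path")
    }
    if (is.null(l_opt_m) || l_opt_m <= 0) {
      stop_field("l_opt_m", "must be > 0 for the ROM path")
    }
    ests <- c(ests, rom_deficit_deg * pi / 180 * moment_arm_m / l_opt_m)
  }
  if (!is.null(stiffness_score)) {
    if (!stiffness_score %in% 0:3) {
      stop_field("stiffness_score",
                 "must be integral on the 0-3 point ordinal scale")
    }
    ests <- c(ests, STIFFNESS_SHIFT_MAP[[as.character(stiffness_score)]])
  }
  if (!length(ests)) {
    stop("need a ROM deficit and/or a stiffness score", call. = FALSE)
  }
  clamp(mean(ests), 0, SHIFT_CAP)
}

#' Contracture shifts per muscle from a group summary
#'
#' Applies [estimate_contracture_shift()] muscle by muscle using the package
#' pairing table: iliopsoas from the Thomas test + hip-flexor score, rectus
#' femoris from its score only, hamstrings from the popliteal angle + score,
#' gastrocnemius from the knee-extended and soleus from the knee-flexed ankle
#' dorsiflexion test + matching plantar-flexor scores. Other muscles get 0.
#'
#' @param summary a `group_summary`
#' @param severity `"minus1sd"`, `"mean"` or `"plus1sd"`
#' @return named numeric vector of shifts per muscle name
#' @export
contracture_shifts <- function(summary, severity = "mean") {
  stopifnot(inherits(summary, "group_summary"))
  rom <- summary_level(summary$rom, severity)
  scores <- summary_level(summary$stiffness, severity)
  shifts <- setNames(numeric(length(c(LEG_MUSCLES, TRUNK_MUSCLES))),
                     c(LEG_MUSCLES, TRUNK_MUSCLES))
  for (mus in names(CONTRACTURE_MAP)) {
    mp <- CONTRACTURE_MAP[[mus]]
    shifts[mus] <- estimate_contracture_shift(
      rom_deficit_deg = if (is.null(mp$rom)) NULL else rom[[mp$rom]],
      moment_arm_m = if (is.null(mp$rom)) NULL else mp$arm,
      l_opt_m = if (is.null(mp$rom)) NULL else mp$l_opt,
      stiffness_score = scores[[mp$score]])
  }
  shifts
}

#' Impairment set: the per-muscle personalization of one model variant
#'
#' @param sigma named vector, sigma per muscle name in `[0.01, 1]`
#' @param shift named vector, passive shift per muscle name in `[0, 0.6]`
#' @param midfoot_break logical; apply the foot-deformity operation
#' @param severity_label `"minus1sd"`, `"mean"` or `"plus1sd"`
#' @param contractures_included logical bookkeeping flag
#' @param label variant label
#' @return list of class `impairment_set`
#' @export
impairment_set <- function(sigma = NULL, shift = NULL, midfoot_break = FALSE,
                           severity_label = "mean",
                           contractures_included = FALSE,
                           label = "variant") {
  if (!is.null(sigma) && (any(sigma < 0) || any(sigma > 1))) {
    stop_field("sigma", "must lie in [0, 1]")
  }
  if (!is.null(shift) && (any(shift < 0) || any(shift > SHIFT_CAP))) {
    stop_field("shift", "must lie in [0, 0.6]")
  }
  structure(list(sigma = sigma, shift = shift,
                 midfoot_break = midfoot_break,
                 severity_label = match.arg(severity_label, severity_levels),
                 contractures_included = contractures_included,
                 label = label),
            class = "impairment_set")
}

#' Apply an impairment set to a model, symmetrically
#'
#' Sets each named muscle's active scale (sigma) and passive shift (s)
#' identically on the left and right sides; the input model is not modified.
#' With an empty set the returned model is identical to the input.
#'
#' @param model a `planar_model`
#' @param set an [impairment_set()]
#' @return personalized `planar_model`
#' @export
apply_impairments <- function(model, set) {
  stopifnot(inherits(set, "impairment_set"))
  mu <- model$muscles
  assign_one <- function(values, col) {
    for (nm in names(values)) {
      rows <- mu$name == nm
      if (!any(rows)) {
        stop(sprintf("unknown muscle `%s` in impairment set", nm),
             call. = FALSE)
      }
      mu[rows, col] <<- values[[nm]]
    }
  }
  if (!is.null(set$sigma)) assign_one(set$sigma, "active_scale")
  if (!is.null(set$shift)) assign_one(set$shift, "passive_shift")
  model$muscles <- mu
  if (set$midfoot_break) model <- apply_foot_deformity(model)
  model
}

#' Apply the midfoot-break foot deformity
#'
#' Reduces the height of the foot segments by 10% (vertical coordinates of
#' foot-segment geometry: in-frame joint heights, center-of-mass heights and
#' contact-sphere center heights are multiplied by 0.9) and halves the
#' strength of the intrinsic foot muscles. Everything else is unchanged.
#'
#' @param model a `planar_model`
#' @return deformed `planar_model`
#' @export
apply_foot_deformity <- function(model) {
  feet <- c("hindfoot_r", "hindfoot_l", "forefoot_r", "forefoot_l")
  s <- model$segments
  foot_rows <- s$name %in% feet
  if (!any(foot_rows)) stop_field("model", "has no foot segments")
  s$comy[foot_rows] <- 0.9 * s$comy[foot_rows]
  # in-frame height of joints carried by a foot segment (midtarsal)
  joint_on_foot <- !is.na(s$parent) & s$parent %in% feet
  s$jy[joint_on_foot] <- 0.9 * s$jy[joint_on_foot]
  model$segments <- s
  ct <- model$contact
  ct_rows <- ct$segment %in% feet
  ct$y[ct_rows] <- 0.9 * ct$y[ct_rows]
  model$contact <- ct
  mu <- model$muscles
  intr <- mu$name == "foot_intrinsic"
  if (!any(intr)) stop_field("model", "has no intrinsic foot muscles")
  mu$active_scale[intr] <- 0.5 * mu$active_scale[intr]
  model$muscles <- mu
  model
}

#' Build the experiment plan for a group
#'
#' DMD groups get six variants: weakness only at the three severity levels
#' (one SD below the mean, the mean, one SD above) and weakness plus
#' contractures at the same levels. A group presenting a midfoot break
#' (DMD3) gets a seventh variant: mean weakness + mean contractures +
#' midfoot break. TD gets a single unimpaired variant.
#'
#' @param summary a `group_summary`
#' @return named list of [impairment_set()]s, in simulation order
#' @export
build_experiment_plan <- function(summary) {
  stopifnot(inherits(summary, "group_summary"))
  if (summary$group == "TD") {
    td <- impairment_set(label = "td_reference")
    return(setNames(list(td), "td_reference"))
  }
  plan <- list()
  for (sev in severity_levels) {
    sig <- weakness_factors(summary, sev)
    lab <- paste0("weak_", sev)
    plan[[lab]] <- impairment_set(sigma = sig, severity_label = sev,
                                  contractures_included = FALSE, label = lab)
    lab2 <- paste0("weakcontr_", sev)
    plan[[lab2]] <- impairment_set(sigma = sig,
                                   shift = contracture_shifts(summary, sev),
                                   severity_label = sev,
                                   contractures_included = TRUE, label = lab2)
  }
  if (isTRUE(summary$midfoot_break)) {
    lab <- "weakcontr_midfoot_mean"
    plan[[lab]] <- impairment_set(
      sigma = weakness_factors(summary, "mean"),
      shift = contracture_shifts(summary, "mean"),
      midfoot_break = TRUE, severity_label = "mean",
      contractures_included = TRUE, label = lab)
  }
  plan
}

#' Personalize the generic model for one variant of a group
#'
#' Scales the generic model to the group's anthropometry, redistributes the
#' excess body mass, and applies the impairment set (and, when flagged, the
#' foot deformity). With the TD summary and an empty set this returns the
#' scaled generic model unchanged.
#'
#' @param generic the generic `planar_model`
#' @param summary a `group_summary`
#' @param set an [impairment_set()]; default none
#' @return personalized `planar_model`
#' @export
personalize_model <- function(generic, summary, set = impairment_set()) {
  spec <- scaling_spec(summary$height_m, summary$mass_kg,
                       summary$expected_td_mass_kg)
  m <- scale_model(generic, spec)
  if (spec$target_mass_kg > spec$expected_td_mass_kg) {
    m <- redistribute_excess_mass(m, spec)
  }
  apply_impairments(m, set)
}
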