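# Synthetic clinical cohort: generation, summaries, built-in group profiles.
#
# The generator emulates the structure of a clinical DMD gait-lab database:
# per-session instrumented strength deficits (fractions of a typically
# developing reference), passive range-of-motion deficits (degrees), ordinal
# muscle-stiffness scores (0-3), manual-muscle-test derived trunk deficits,
# anthropometry with excess body mass, and self-selected gait speed.

STRENGTH_MEASURES <- c("hip_ext", "hip_flex", "hip_abd", "knee_ext",
                       "knee_flex", "plantar_flex", "dorsiflex",
                       "abdominal", "back")
ROM_MEASURES <- c("hip_ext_thomas", "popliteal_angle", "ankle_df_knee_ext",
                  "ankle_df_knee_flex", "hip_add")
STIFFNESS_GROUPS <- c("hip_flexors", "rectus_femoris", "hamstrings",
                      "plantar_flex_knee_ext", "plantar_flex_knee_flex",
                      "hip_abductors")
GROUP_LEVELS <- c("TD", "DMD1", "DMD2", "DMD3")

# Allometric coefficient for the expected typically developing body mass,
# mass_TD = c * height^3; derived from the generic model anthropometry.
td_mass_coefficient <- function() {
  gm <- generic_anthropometry()
  gm$mass_kg / gm$height_m^3
}

#' Expected typically developing body mass for a stature
#'
#' Geometric-similarity expectation `mass = c * height^3`, with the package
#' coefficient `c` derived from the generic model anthropometry. Stands in for
#' a reference-population mass-on-height regression.
#'
#' @param height_m stature in metres (> 0)
#' @return expected body mass in kg
#' @export
expected_td_mass <- function(height_m) {
  if (any(height_m <= 0)) stop_field("height_m", "must be > 0")
  td_mass_coefficient() * height_m^3
}

#' Construct a group profile for the synthetic-cohort generator
#'
#' A profile holds, per clinical measure, the mean and SD used by the
#' truncated-normal sampler, category probabilities for the ordinal stiffness
#' scores, anthropometry (height; excess mass above the TD expectation), gait
#' speed, and the prevalence of a midfoot break. The numeric defaults of
#' [builtin_profiles()] are synthetic stand-ins shaped by the qualitative
#' severity ordering of the three DMD gait-pattern groups, not measured data.
#'
#' @param group one of `"TD"`, `"DMD1"`, `"DMD2"`, `"DMD3"`
#' @param strength named list/vector pairs: per strength measure `c(mean, sd)`
#'   of the deficit fraction in `[0, 1]`
#' @param rom per ROM test `c(mean, sd)` of the deficit in degrees (>= 0)
#' @param stiffness_probs matrix (rows = stiffness muscle groups, 4 columns)
#'   of category probabilities for scores 0-3; rows must sum to 1
#' @param height_m `c(mean, sd)` stature in metres
#' @param excess_mass_kg `c(mean, sd)` body mass above the TD expectation
#' @param gait_speed_mps `c(mean, sd)` self-selected walking speed
#' @param midfoot_break_prevalence probability in `[0, 1]`
#' @return object of class `group_profile`
#' @export
group_profile <- function(group, strength, rom, stiffness_probs,
                          height_m, excess_mass_kg, gait_speed_mps,
                          midfoot_break_prevalence = 0) {
  group <- match.arg(group, GROUP_LEVELS)
  strength <- do.call(rbind, lapply(STRENGTH_MEASURES, function(m) {
    v <- strength[[m]]
    if (is.null(v)) stop_field(paste0("strength$", m), "missing")
    data.frame(measure = m, mean = v[1], sd = v[2])
  }))
  rom <- do.call(rbind, lapply(ROM_MEASURES, function(m) {
    v <- rom[[m]]
    if (is.null(v)) stop_field(paste0("rom$", m), "missing")
    data.frame(measure = m, mean = v[1], sd = v[2])
  }))
  stiffness_probs <- as.matrix(stiffness_probs)
  if (!all(rownames(stiffness_probs) %in% STIFFNESS_GROUPS) ||
      nrow(stiffness_probs) != length(STIFFNESS_GROUPS)) {
    stop_field("stiffness_probs", "must have one row per stiffness group")
  }
  stiffness_probs <- stiffness_probs[STIFFNESS_GROUPS, , drop = FALSE]
  prof <- structure(list(
    group = group, strength = strength, rom = rom,
    stiffness_probs = stiffness_probs,
    height_m = height_m, excess_mass_kg = excess_mass_kg,
    gait_speed_mps = gait_speed_mps,
    midfoot_break_prevalence = midfoot_break_prevalence
  ), class = "group_profile")
  validate_profile(prof)
  prof
}

validate_profile <- function(profile) {
  if (!inherits(profile, "group_profile")) {
    stop_field("profile", "must be a `group_profile`")
  }
  for (tab in c("strength", "rom")) {
    df <- profile[[tab]]
    if (any(df$sd < 0)) {
      stop_field(paste0(tab, "$sd"),
                 paste("negative SD for", df$measure[df$sd < 0][1]))
    }
  }
  if (any(profile$strength$mean < 0 | profile$strength$mean > 1)) {
    stop_field("strength$mean", "deficit means must lie in [0, 1]")
  }
  if (any(profile$rom$mean < 0)) {
    stop_field("rom$mean", "ROM deficit means must be >= 0")
  }
  sp <- profile$stiffness_probs
  if (ncol(sp) != 4 || any(sp < 0)) {
    stop_field("stiffness_probs", "needs 4 non-negative columns (scores 0-3)")
  }
  bad <- abs(rowSums(sp) - 1) > 1e-8
  if (any(bad)) {
    stop_field("stiffness_probs",
               paste("probabilities must sum to 1 for",
                     rownames(sp)[bad][1]))
  }
  for (fld in c("height_m", "excess_mass_kg", "gait_speed_mps")) {
    v <- profile[[fld]]
    if (length(v) != 2 || v[2] < 0) stop_field(fld, "needs c(mean, sd >= 0)")
  }
  if (profile$height_m[1] <= 0) stop_field("height_m", "mean must be > 0")
  if (profile$gait_speed_mps[1] <= 0) {
    stop_field("gait_speed_mps", "mean must be > 0")
  }
  p <- profile$midfoot_break_prevalence
  if (p < 0 || p > 1) stop_field("midfoot_break_prevalence", "must be in [0,1]")
  invisible(profile)
}

#' Built-in synthetic group profiles
#'
#' Four profiles: `TD` (no impairment), `DMD1` (mildly affected: uniform low
#' deficits), `DMD2` (tiptoeing pattern: distal-dominant, plantar-flexor
#' deficits and stiffness highest), and `DMD3` (flexion pattern:
#' proximal-dominant, hip/knee extensor deficits highest, midfoot break in
#' every subject). All numbers are documented synthetic defaults.
#'
#' @return named list of [group_profile()] objects
#' @export
builtin_profiles <- function() {
  zero2 <- c(0, 0)
  sp_row <- function(p0, p1, p2, p3) c(p0, p1, p2, p3)
  mk_sp <- function(...) {
    m <- rbind(...)
    rownames(m) <- STIFFNESS_GROUPS
    m
  }
  td <- group_profile(
    "TD",
    strength = setNames(rep(list(zero2), length(STRENGTH_MEASURES)),
                        STRENGTH_MEASURES),
    rom = setNames(rep(list(zero2), length(ROM_MEASURES)), ROM_MEASURES),
    stiffness_probs = mk_sp(
      sp_row(1, 0, 0, 0), sp_row(1, 0, 0, 0), sp_row(1, 0, 0, 0),
      sp_row(1, 0, 0, 0), sp_row(1, 0, 0, 0), sp_row(1, 0, 0, 0)),
    height_m = c(1.33, 0.08), excess_mass_kg = c(0, 0),
    gait_speed_mps = c(1.20, 0.10), midfoot_break_prevalence = 0)

  dmd1 <- group_profile(
    "DMD1",
    strength = list(
      hip_ext = c(0.30, 0.10), hip_flex = c(0.20, 0.08),
      hip_abd = c(0.25, 0.08), knee_ext = c(0.25, 0.10),
      knee_flex = c(0.25, 0.10), plantar_flex = c(0.25, 0.10),
      dorsiflex = c(0.30, 0.10), abdominal = c(0.30, 0.10),
      back = c(0.20, 0.10)),
    rom = list(hip_ext_thomas = c(2, 2), popliteal_angle = c(10, 5),
               ankle_df_knee_ext = c(3, 3), ankle_df_knee_flex = c(2, 2),
               hip_add = c(2, 2)),
    stiffness_probs = mk_sp(
      sp_row(0.6, 0.3, 0.1, 0), sp_row(0.7, 0.25, 0.05, 0),
      sp_row(0.5, 0.35, 0.15, 0), sp_row(0.5, 0.35, 0.15, 0),
      sp_row(0.6, 0.3, 0.1, 0), sp_row(0.8, 0.2, 0, 0)),
    height_m = c(1.30, 0.07), excess_mass_kg = c(2, 2),
    gait_speed_mps = c(1.10, 0.15), midfoot_break_prevalence = 0)

  dmd2 <- group_profile(
    "DMD2",
    strength = list(
      hip_ext = c(0.35, 0.10), hip_flex = c(0.30, 0.10),
      hip_abd = c(0.35, 0.10), knee_ext = c(0.35, 0.12),
      knee_flex = c(0.40, 0.12), plantar_flex = c(0.55, 0.15),
      dorsiflex = c(0.45, 0.12), abdominal = c(0.45, 0.12),
      back = c(0.35, 0.12)),
    rom = list(hip_ext_thomas = c(5, 4), popliteal_angle = c(20, 10),
               ankle_df_knee_ext = c(12, 6), ankle_df_knee_flex = c(8, 5),
               hip_add = c(4, 3)),
    stiffness_probs = mk_sp(
      sp_row(0.4, 0.4, 0.2, 0), sp_row(0.5, 0.35, 0.15, 0),
      sp_row(0.3, 0.4, 0.25, 0.05), sp_row(0.1, 0.3, 0.4, 0.2),
      sp_row(0.15, 0.35, 0.35, 0.15), sp_row(0.6, 0.3, 0.1, 0)),
    height_m = c(1.32, 0.08), excess_mass_kg = c(5, 3),
    gait_speed_mps = c(0.95, 0.20), midfoot_break_prevalence = 0)

  dmd3 <- group_profile(
    "DMD3",
    strength = list(
      hip_ext = c(0.60, 0.15), hip_flex = c(0.45, 0.12),
      hip_abd = c(0.50, 0.12), knee_ext = c(0.55, 0.15),
      knee_flex = c(0.45, 0.12), plantar_flex = c(0.45, 0.12),
      dorsiflex = c(0.50, 0.12), abdominal = c(0.60, 0.12),
      back = c(0.50, 0.12)),
    rom = list(hip_ext_thomas = c(10, 5), popliteal_angle = c(30, 10),
               ankle_df_knee_ext = c(10, 5), ankle_df_knee_flex = c(8, 4),
               hip_add = c(5, 3)),
    stiffness_probs = mk_sp(
      sp_row(0.15, 0.35, 0.35, 0.15), sp_row(0.3, 0.4, 0.25, 0.05),
      sp_row(0.1, 0.3, 0.4, 0.2), sp_row(0.2, 0.35, 0.3, 0.15),
      sp_row(0.25, 0.35, 0.3, 0.1), sp_row(0.5, 0.35, 0.15, 0)),
    height_m = c(1.35, 0.08), excess_mass_kg = c(8, 4),
    gait_speed_mps = c(0.85, 0.20), midfoot_break_prevalence = 1)

  list(TD = td, DMD1 = dmd1, DMD2 = dmd2, DMD3 = dmd3)
}

#' Generate a synthetic clinical cohort
#'
#' Draws `n` subject-sessions from a [group_profile()]. Continuous measures
#' use truncated-normal sampling at the profile's mean/SD, truncated at the
#' measure's physical bounds (deficits to `[0, 1]`, ROM deficits and speeds to
#' non-negative/positive values); ordinal stiffness scores are drawn from the
#' profile's category probabilities; body mass is the TD expectation for the
#' drawn height plus a drawn excess mass.
#'
#' @param profile a [group_profile()]
#' @param n number of records (>= 1)
#' @param seed integer seed; identical seed gives identical output
#' @return data.frame of class `dmd_cohort`, one row per subject-session with
#'   columns `subject_id`, `group`, `str_*` (deficit fractions), `rom_*`
#'   (degrees), `stiff_*` (integer scores 0-3), `mass_kg`, `height_m`,
#'   `gait_speed_mps`, `midfoot_break`
#' @export
generate_cohort <- function(profile, n, seed = 1L) {
  validate_profile(profile)
  if (!is.numeric(n) || n < 1) stop_field("n", "must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    out <- data.frame(
      subject_id = sprintf("%s_%03d", profile$group, seq_len(n)),
      group = profile$group, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(profile$strength))) {
      r <- profile$strength[i, ]
      out[[paste0("str_", r$measure)]] <- rtruncnorm(n, r$mean, r$sd, 0, 1)
    }
    for (i in seq_len(nrow(profile$rom))) {
      r <- profile$rom[i, ]
      out[[paste0("rom_", r$measure)]] <- rtruncnorm(n, r$mean, r$sd, 0, Inf)
    }
    for (g in rownames(profile$stiffness_probs)) {
      p <- profile$stiffness_probs[g, ]
      out[[paste0("stiff_", g)]] <-
        sample(0:3, n, replace = TRUE, prob = p)
    }
    out$height_m <- rtruncnorm(n, profile$height_m[1], profile$height_m[2],
                               0.5, 2.2)
    excess <- rtruncnorm(n, profile$excess_mass_kg[1],
                         profile$excess_mass_kg[2], 0, Inf)
    out$mass_kg <- expected_td_mass(out$height_m) + excess
    out$gait_speed_mps <- rtruncnorm(n, profile$gait_speed_mps[1],
                                     profile$gait_speed_mps[2], 0.1, Inf)
    out$midfoot_break <-
      runif(n) < profile$midfoot_break_prevalence
    class(out) <- c("dmd_cohort", "data.frame")
    out
  })
}

#' Validate a cohort table
#'
#' Checks every record against the clinical-record invariants: deficits in
#' `[0, 1]`, ROM deficits >= 0, stiffness scores integral in 0-3, mass,
#' height and speed strictly positive.
#'
#' @param cohort a `dmd_cohort` data.frame
#' @return the cohort, invisibly; errors name the offending row and field
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", "group", paste0("str_", STRENGTH_MEASURES),
            paste0("rom_", ROM_MEASURES), paste0("stiff_", STIFFNESS_GROUPS),
            "mass_kg", "height_m", "gait_speed_mps", "midfoot_break")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_field(miss[1], "missing column")
  fail <- function(col, rows, why) {
    stop(sprintf("row %d, field `%s`: %s", rows[1], col, why), call. = FALSE)
  }
  if (!all(cohort$group %in% GROUP_LEVELS)) {
    fail("group", which(!cohort$group %in% GROUP_LEVELS), "unknown group")
  }
  for (col in paste0("str_", STRENGTH_MEASURES)) {
    bad <- which(cohort[[col]] < 0 | cohort[[col]] > 1 | is.na(cohort[[col]]))
    if (length(bad)) fail(col, bad, "deficit must lie in [0, 1]")
  }
  for (col in paste0("rom_", ROM_MEASURES)) {
    bad <- which(cohort[[col]] < 0 | is.na(cohort[[col]]))
    if (length(bad)) fail(col, bad, "ROM deficit must be >= 0")
  }
  for (col in paste0("stiff_", STIFFNESS_GROUPS)) {
    v <- cohort[[col]]
    bad <- which(is.na(v) | v != round(v) | v < 0 | v > 3)
    if (length(bad)) fail(col, bad, "score must be integral on the 0-3 point ordinal scale")
  }
  for (col in c("mass_kg", "height_m", "gait_speed_mps")) {
    bad <- which(cohort[[col]] <= 0 | is.na(cohort[[col]]))
    if (length(bad)) fail(col, bad, "must be strictly positive")
  }
  invisible(cohort)
}

#' Summarize a single-group cohort into severity levels
#'
#' Computes per-measure mean and sample SD (n-1 denominator) and the three
#' severity levels used for model personalization: one SD below the mean
#' (less affected), the mean, and one SD above the mean (more affected),
#' with deficits clipped to `[0, 1]` and ROM deficits to `>= 0`. Ordinal
#' stiffness scores are summarized as one modal score per severity level:
#' the empirical mode at the mean level (ties break to the higher, more
#' impaired score), shifted down/up by the rounded score SD and clamped to
#' 0-3 at the -1SD/+1SD levels so levels stay monotone.
#'
#' @param cohort a validated single-group `dmd_cohort` with >= 2 rows
#' @return object of class `group_summary`
#' @export
summarize_group <- function(cohort) {
  validate_cohort(cohort)
  if (nrow(cohort) < 2) stop("need at least 2 records", call. = FALSE)
  if (length(unique(cohort$group)) != 1) {
    stop("records mix groups; summarize one group at a time", call. = FALSE)
  }
  lvl <- function(m, s, lo, hi) {
    c(minus1sd = clamp(m - s, lo, hi), mean = clamp(m, lo, hi),
      plus1sd = clamp(m + s, lo, hi))
  }
  cont <- function(measures, prefix, lo, hi) {
    do.call(rbind, lapply(measures, function(ms) {
      v <- cohort[[paste0(prefix, ms)]]
      m <- mean(v); s <- sd(v)
      l <- lvl(m, s, lo, hi)
      data.frame(measure = ms, mean = m, sd = s, minus1sd = l[[1]],
                 mid = l[[2]], plus1sd = l[[3]])
    }))
  }
  strength <- cont(STRENGTH_MEASURES, "str_", 0, 1)
  rom <- cont(ROM_MEASURES, "rom_", 0, Inf)

  stiffness <- do.call(rbind, lapply(STIFFNESS_GROUPS, function(g) {
    v <- cohort[[paste0("stiff_", g)]]
    tab <- tabulate(v + 1L, nbins = 4L)
    # empirical mode; tie breaks to the higher (more impaired) score
    mode_score <- max(which(tab == max(tab))) - 1L
    s <- sd(v)
    lo <- min(mode_score, clamp(round(mean(v) - s), 0, 3))
    hi <- max(mode_score, clamp(round(mean(v) + s), 0, 3))
    data.frame(muscle_group = g, minus1sd = as.integer(lo),
               mid = mode_score, plus1sd = as.integer(hi))
  }))

  structure(list(
    group = cohort$group[1],
    n = nrow(cohort),
    strength = strength,
    rom = rom,
    stiffness = stiffness,
    height_m = mean(cohort$height_m),
    mass_kg = mean(cohort$mass_kg),
    expected_td_mass_kg = expected_td_mass(mean(cohort$height_m)),
    gait_speed_mps = mean(cohort$gait_speed_mps),
    midfoot_break = mean(cohort$midfoot_break) >= 0.5
  ), class = "group_summary")
}

severity_levels <- c("minus1sd", "mean", "plus1sd")

# Look up one severity column ("minus1sd" | "mean" | "plus1sd") of a
# summary table.
summary_level <- function(df, severity) {
  severity <- match.arg(severity, severity_levels)
  col <- c(minus1sd = "minus1sd", mean = "mid", plus1sd = "plus1sd")[severity]
  setNames(df[[col]], df[[1]])
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s (n = %d)\n", x$group, x$n))
  cat(sprintf("  height %.2f m, mass %.1f kg (TD expectation %.1f kg)\n",
              x$height_m, x$mass_kg, x$expected_td_mass_kg))
  cat(sprintf("  gait speed %.2f m/s, midfoot break: %s\n",
              x$gait_speed_mps, x$midfoot_break))
  cat("  strength deficits (mean):\n")
  print(x$strength[, c("measure", "mean", "sd")], row.names = FALSE)
  invisible(x)
}
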