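# Gait post-processing: event detection from ground-reaction forces, 101-point
# time normalization over the gait cycle, spatiotemporal parameters,
# DMD-minus-TD deviation curves, and the severity-sweep report.

#' Detect gait events from vertical ground-reaction forces
#'
#' Heel strike is the first upward crossing of the vertical GRF through the
#' threshold; toe-off the subsequent downward crossing; reported per leg.
#'
#' @param traj a `full_cycle` trajectory (from [mirror_to_full_cycle()])
#' @param threshold vertical force threshold, N (default 20)
#' @return list per leg with `heel_strike` and `toe_off` times, s
#' @export
detect_events <- function(traj, threshold = 20) {
  if (threshold <= 0) stop_field("threshold", "must be > 0")
  one_leg <- function(fy) {
    n <- length(fy)
    above <- fy > threshold
    if (all(above) || all(!above)) {
      stop("no gait events: vertical GRF never crosses the threshold",
           call. = FALSE)
    }
    # the samples are one gait cycle (periodic endpoints); find the longest
    # contiguous above-threshold run, cyclically, to skip brief ground
    # grazes during swing
    ext <- c(above, above[-1])
    runs <- rle(ext)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    cand <- which(runs$values & starts <= n)
    if (!length(cand)) {
      stop("no gait events: vertical GRF never crosses the threshold",
           call. = FALSE)
    }
    best <- cand[which.max(runs$lengths[cand])]
    i0 <- starts[best]          # first sample above threshold
    i1 <- ends[best]            # last sample above threshold (may wrap)
    tcross <- function(i) {     # crossing between samples i and i+1 (cyclic)
      iw <- (i - 1) %% (n - 1) + 1
      t0 <- traj$time[iw]; t1 <- traj$time[iw + 1]
      f0 <- fy[iw]; f1 <- fy[iw + 1]
      tc <- t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
      tc + ((i - 1) %/% (n - 1)) * traj$cycle_time
    }
    hs <- if (i0 == 1 && above[1]) traj$time[1] else tcross(i0 - 1)
    to <- if (i1 >= n) tcross(i1) else tcross(i1)
    list(heel_strike = hs, toe_off = to)
  }
  list(right = one_leg(traj$grf_r[, 2]), left = one_leg(traj$grf_l[, 2]))
}

#' Time-normalize a full-cycle trajectory to 101 points
#'
#' Resamples every angle, moment and GRF channel linearly onto 101 points
#' spanning 0-100% of the gait cycle, starting at the detected (or supplied)
#' right heel strike; angles are reported in degrees with the package sign
#' conventions.
#'
#' @param traj a `full_cycle` trajectory
#' @param events optional result of [detect_events()]; detected if missing
#' @param threshold GRF threshold passed to [detect_events()]
#' @return list of class `gait_curves`: `angles_deg`, `moments`, `grf`
#'   (101-row matrices), `cycle_start` s, `cycle_time` s
#' @export
time_normalize <- function(traj, events = NULL, threshold = 20) {
  if (is.null(events)) events <- detect_events(traj, threshold)
  t0 <- events$right$heel_strike
  if (t0 < traj$time[1] || t0 > traj$time[length(traj$time)]) {
    stop("events lie outside the trajectory span", call. = FALSE)
  }
  Tcyc <- traj$cycle_time
  tq <- t0 + seq(0, 1, length.out = 101) * Tcyc
  # periodic extension: wrap beyond the trajectory end (pelvis x advances)
  sample_mat <- function(M, periodic_shift = NULL) {
    out <- matrix(NA_real_, 101, ncol(M), dimnames = list(NULL, colnames(M)))
    for (j in seq_len(ncol(M))) {
      y <- M[, j]
      tw <- ifelse(tq > traj$time[length(traj$time)], tq - Tcyc, tq)
      v <- approx(traj$time, y, xout = tw, rule = 2)$y
      if (!is.null(periodic_shift) && j %in% periodic_shift) {
        v[tq > traj$time[length(traj$time)]] <-
          v[tq > traj$time[length(traj$time)]] + traj$distance
      }
      out[, j] <- v
    }
    out
  }
  ang_cols <- setdiff(COORD_NAMES, c("pelvis_tx", "pelvis_ty"))
  angles <- sample_mat(traj$q)[, ang_cols] * 180 / pi
  moments <- sample_mat(traj$tau_muscle + traj$tau_passive)[, ang_cols]
  grf <- cbind(sample_mat(traj$grf_r), sample_mat(traj$grf_l))
  colnames(grf) <- c("grf_r_x", "grf_r_y", "grf_l_x", "grf_l_y")
  structure(list(angles_deg = angles, moments = moments, grf = grf,
                 cycle_start = t0, cycle_time = Tcyc,
                 pct = seq(0, 100, length.out = 101),
                 mass_kg = traj$mass_kg),
            class = "gait_curves")
}

#' Spatiotemporal parameters of a full-cycle trajectory
#'
#' @param traj a `full_cycle` trajectory
#' @param events optional result of [detect_events()]
#' @return data.frame: stride length m, cycle time s, cadence steps/min,
#'   stance percentage per leg, average speed m/s
#' @export
spatiotemporal <- function(traj, events = NULL) {
  if (is.null(events)) events <- detect_events(traj)
  Tcyc <- traj$cycle_time
  stance_pct <- function(ev) {
    100 * ((ev$toe_off - ev$heel_strike) %% Tcyc) / Tcyc
  }
  data.frame(
    stride_length_m = traj$distance,
    cycle_time_s = Tcyc,
    cadence_steps_min = 120 / Tcyc,
    stance_pct_r = stance_pct(events$right),
    stance_pct_l = stance_pct(events$left),
    speed_mps = traj$distance / Tcyc)
}

#' Pointwise difference between two sets of gait curves
#'
#' Variant minus reference on identical 101-point grids; antisymmetric and
#' zero for identical inputs.
#'
#' @param variant,reference `gait_curves` objects
#' @return list of class `deviation_curves` with `angles_deg`, `moments`,
#'   `grf` difference matrices
#' @export
deviation_curves <- function(variant, reference) {
  stopifnot(inherits(variant, "gait_curves"),
            inherits(reference, "gait_curves"))
  for (fld in c("angles_deg", "moments", "grf")) {
    if (!identical(dim(variant[[fld]]), dim(reference[[fld]]))) {
      stop("mismatched curve grids", call. = FALSE)
    }
  }
  structure(list(
    angles_deg = variant$angles_deg - reference$angles_deg,
    moments = variant$moments - reference$moments,
    grf = variant$grf - reference$grf,
    pct = variant$pct), class = "deviation_curves")
}

# Peak gait features narrated in the severity analyses. Ankle moment sign:
# plantar-flexion moment is negative in package convention, so the peak
# plantar-flexion moment is the maximum of -moment over stance.
gait_features <- function(curves, events_stance_pct = 60) {
  stance <- curves$pct <= events_stance_pct
  swing <- curves$pct > events_stance_pct
  c(peak_pf_moment = max(-curves$moments[stance, "ankle_r"]),
    ankle_ic_deg = curves$angles_deg[1, "ankle_r"],
    peak_knee_flex_swing_deg = max(curves$angles_deg[swing, "knee_r"]),
    peak_mt_df_stance_deg = max(curves$angles_deg[stance, "mt_r"]),
    mean_pelvic_tilt_deg = mean(curves$angles_deg[, "pelvis_tilt"]),
    min_knee_flex_loading_deg = min(curves$angles_deg[curves$pct <= 25,
                                                      "knee_r"]))
}

#' Assemble the severity-sweep deviation report
#'
#' Takes the per-variant results of an experiment plan (converged
#' `trajectory_solution`s or `feasibility_report`s) plus the TD reference,
#' normalizes all converged gaits, and reports DMD-minus-TD difference
#' curves, spatiotemporal parameters, the peak-feature table and feasibility
#' flags.
#'
#' @param results named list of results, one per plan label
#' @param td_solution converged TD `trajectory_solution`
#' @param problems named list of `ocp_problem`s matching `results`
#' @param td_problem the TD `ocp_problem`
#' @return list of class `deviation_report`
#' @export
severity_sweep <- function(results, td_solution, problems, td_problem) {
  if (!inherits(td_solution, "trajectory_solution")) {
    stop("missing TD baseline: the reference simulation did not converge",
         call. = FALSE)
  }
  td_curves <- time_normalize(mirror_to_full_cycle(td_solution, td_problem))
  td_full <- mirror_to_full_cycle(td_solution, td_problem)
  report <- list(
    td = list(curves = td_curves, spatiotemporal = spatiotemporal(td_full),
              features = gait_features(td_curves)),
    variants = list(), feasibility = list())
  for (lab in names(results)) {
    res <- results[[lab]]
    if (inherits(res, "trajectory_solution")) {
      full <- mirror_to_full_cycle(res, problems[[lab]])
      curves <- tryCatch(time_normalize(full), error = function(e) NULL)
      if (is.null(curves)) {
        report$feasibility[[lab]] <- list(status = "no_events",
                                          note = "no GRF threshold crossing")
        next
      }
      report$variants[[lab]] <- list(
        curves = curves,
        deviation = deviation_curves(curves, td_curves),
        spatiotemporal = spatiotemporal(full),
        features = gait_features(curves))
      report$feasibility[[lab]] <- list(status = "converged")
    } else {
      report$feasibility[[lab]] <- list(status = res$status,
                                        violation = res$violation,
                                        note = res$note)
    }
  }
  feats <- lapply(report$variants, `[[`, "features")
  report$feature_table <- if (length(feats)) {
    cbind(data.frame(variant = names(feats)),
          do.call(rbind, feats) - matrix(report$td$features,
                                         nrow = length(feats),
                                         ncol = length(report$td$features),
                                         byrow = TRUE,
                                         dimnames = list(NULL, names(report$td$features))))
  } else data.frame()
  class(report) <- "deviation_report"
  report
}

#' @export
print.deviation_report <- function(x, ...) {
  n_ok <- sum(vapply(x$feasibility, function(f) f$status == "converged",
                     logical(1)))
  cat(sprintf("<deviation_report> %d variants (%d converged) vs TD\n",
              length(x$feasibility), n_ok))
  for (lab in names(x$feasibility)) {
    f <- x$feasibility[[lab]]
    cat(sprintf("  %-26s %s\n", lab, f$status))
  }
  invisible(x)
}

#' Run the full experiment for one group
#'
#' Personalizes the generic model per the group's experiment plan, solves
#' every variant plus the TD reference, and assembles the deviation report.
#'
#' @param summary a `group_summary` of the group to simulate
#' @param td_summary a `group_summary` of the TD group (reference)
#' @param config an [ocp_config()]; the target speed defaults to each
#'   group's mean measured gait speed
#' @param generic the generic model (default [default_planar_model()])
#' @param verbose print solver progress
#' @return list with `report`, `results`, `td_solution`, `plan`
#' @export
run_experiment <- function(summary, td_summary, config = ocp_config(),
                           generic = default_planar_model(),
                           verbose = FALSE) {
  td_model <- personalize_model(generic, td_summary)
  td_cfg <- config
  td_cfg$target_speed <- td_summary$gait_speed_mps
  td_problem <- build_problem(td_model, td_cfg)
  td_sol <- solve_gait(td_problem, label = "td_reference", verbose = verbose)
  plan <- build_experiment_plan(summary)
  results <- list(); problems <- list()
  grp_cfg <- config
  grp_cfg$target_speed <- summary$gait_speed_mps
  warm <- if (inherits(td_sol, "trajectory_solution")) td_sol$z else NULL
  for (lab in names(plan)) {
    model <- personalize_model(generic, summary, plan[[lab]])
    problems[[lab]] <- build_problem(model, grp_cfg)
    results[[lab]] <- solve_gait(problems[[lab]], guess = warm,
                                 label = lab, verbose = verbose)
  }
  report <- severity_sweep(results, td_sol, problems, td_problem)
  list(report = report, results = results, td_solution = td_sol,
       plan = plan, problems = problems, td_problem = td_problem)
}
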