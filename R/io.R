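# File I/O: clinical-measurement CSV tables, group-summary YAML, OpenSim
# storage (STO/MOT dialect) trajectories, JSON run manifests and reports.
# On-disk angles are degrees; everything internal is radians.

#' Write a cohort table to CSV
#' @param cohort a `dmd_cohort`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a clinical-measurement CSV table
#'
#' One row per subject-session; columns as written by [write_cohort_csv()].
#' Validation errors name the offending row and field.
#'
#' @param path input path
#' @return a validated `dmd_cohort`
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) stop_field("path", "file does not exist")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("unreadable CSV: ",
                                          conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0) stop("empty clinical table", call. = FALSE)
  if ("midfoot_break" %in% names(df)) {
    df$midfoot_break <- as.logical(df$midfoot_break)
  }
  class(df) <- c("dmd_cohort", "data.frame")
  validate_cohort(df)
  df
}

#' Write a group summary as YAML
#' @param summary a `group_summary`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_summary_yaml <- function(summary, path) {
  stopifnot(inherits(summary, "group_summary"))
  obj <- list(
    type = "group_summary", group = summary$group, n = summary$n,
    strength = lapply(seq_len(nrow(summary$strength)), function(i)
      as.list(summary$strength[i, ])),
    rom = lapply(seq_len(nrow(summary$rom)), function(i)
      as.list(summary$rom[i, ])),
    stiffness = lapply(seq_len(nrow(summary$stiffness)), function(i)
      as.list(summary$stiffness[i, ])),
    height_m = summary$height_m, mass_kg = summary$mass_kg,
    expected_td_mass_kg = summary$expected_td_mass_kg,
    gait_speed_mps = summary$gait_speed_mps,
    midfoot_break = summary$midfoot_break)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a group summary written by [write_summary_yaml()]
#' @param path input path
#' @return a `group_summary`
#' @export
read_summary_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$type, "group_summary")) {
    stop_field("path", "not a group_summary file")
  }
  rowbind <- function(lst) do.call(rbind, lapply(lst, as.data.frame))
  structure(list(
    group = obj$group, n = obj$n,
    strength = rowbind(obj$strength), rom = rowbind(obj$rom),
    stiffness = rowbind(obj$stiffness),
    height_m = obj$height_m, mass_kg = obj$mass_kg,
    expected_td_mass_kg = obj$expected_td_mass_kg,
    gait_speed_mps = obj$gait_speed_mps,
    midfoot_break = obj$midfoot_break), class = "group_summary")
}

#' Write a time-series table in OpenSim storage (STO/MOT) dialect
#'
#' Header lines (`name`, `nRows=`, `nColumns=`, `inDegrees=`, `endheader`)
#' followed by a tab-delimited numeric block with monotone time in the first
#' column.
#'
#' @param data matrix or data.frame of channels (no time column)
#' @param time numeric vector of monotone increasing times, s
#' @param path output path
#' @param name table name written in the header
#' @param in_degrees value of the `inDegrees` header flag
#' @return `path`, invisibly
#' @export
write_sto <- function(data, time, path, name = "dmdgait", in_degrees = TRUE) {
  data <- as.matrix(data)
  if (is.null(colnames(data)) || anyNA(colnames(data))) {
    stop_field("data", "needs column names")
  }
  if (anyDuplicated(colnames(data))) {
    stop_field("data", "duplicate column names")
  }
  if (length(time) != nrow(data)) stop_field("time", "length mismatch")
  if (any(diff(time) <= 0)) stop_field("time", "must be strictly increasing")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(data)),
               sprintf("nColumns=%d", ncol(data) + 1L),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(c("time", colnames(data)), collapse = "\t")), con)
  block <- cbind(time, data)
  writeLines(apply(block, 1, function(r)
    paste(sprintf("%.12g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read an OpenSim storage (STO/MOT) file written by [write_sto()]
#' @param path input path
#' @return list with `time`, `data` (matrix), `name`, `in_degrees`
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "endheader")
  if (!length(endh)) stop_field("path", "missing `endheader`")
  hdr <- lines[seq_len(endh[1] - 1)]
  name <- hdr[1]
  in_degrees <- any(grepl("^inDegrees=yes", hdr))
  cols <- strsplit(lines[endh[1] + 1], "\t")[[1]]
  body <- lines[(endh[1] + 2):length(lines)]
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  colnames(vals) <- cols
  list(time = vals[, 1], data = vals[, -1, drop = FALSE], name = name,
       in_degrees = in_degrees)
}

#' Write a full-cycle trajectory as STO files
#'
#' Writes `<stem>_kinematics.sto` (angles in degrees, pelvis translations in
#' metres) and `<stem>_forces.sto` (ground-reaction forces, N).
#'
#' @param traj a `full_cycle` trajectory
#' @param stem output path stem
#' @return character vector of the paths written
#' @export
write_trajectory_sto <- function(traj, stem) {
  ang <- traj$q
  deg_cols <- setdiff(COORD_NAMES, c("pelvis_tx", "pelvis_ty"))
  ang[, deg_cols] <- ang[, deg_cols] * 180 / pi
  p1 <- write_sto(ang, traj$time, paste0(stem, "_kinematics.sto"),
                  name = paste0(traj$label, " kinematics"))
  grf <- cbind(traj$grf_r, traj$grf_l)
  colnames(grf) <- c("grf_r_x", "grf_r_y", "grf_l_x", "grf_l_y")
  p2 <- write_sto(grf, traj$time, paste0(stem, "_forces.sto"),
                  name = paste0(traj$label, " forces"), in_degrees = FALSE)
  c(p1, p2)
}

#' Write a run manifest as JSON
#'
#' Records configuration digests, model digests, seeds, package version,
#' solver statuses and the output files of a pipeline run.
#'
#' @param path output path
#' @param seeds named list/vector of seeds used by stochastic stages
#' @param models named list of `planar_model`s (digests are recorded)
#' @param statuses named character vector of per-variant solver statuses
#' @param outputs character vector of output file paths (must exist)
#' @param config any serializable configuration object
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(path, seeds = list(), models = list(),
                           statuses = character(0), outputs = character(0),
                           config = list()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing)) {
    stop_field("outputs", paste("file does not exist:", missing[1]))
  }
  manifest <- list(
    package = "dmdgait",
    version = as.character(utils::packageVersion("dmdgait")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    model_digests = lapply(models, model_digest),
    statuses = as.list(statuses),
    outputs = as.list(outputs),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Write a deviation report to JSON (round-trippable)
#' @param report a `deviation_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "deviation_report"))
  ser_curves <- function(cv) list(
    pct = cv$pct, angles_deg = as.data.frame(cv$angles_deg),
    moments = as.data.frame(cv$moments), grf = as.data.frame(cv$grf),
    cycle_time = cv$cycle_time)
  obj <- list(
    type = "deviation_report",
    td = list(curves = ser_curves(report$td$curves),
              spatiotemporal = report$td$spatiotemporal,
              features = as.list(report$td$features)),
    variants = lapply(report$variants, function(v) list(
      deviation = list(angles_deg = as.data.frame(v$deviation$angles_deg),
                       moments = as.data.frame(v$deviation$moments)),
      spatiotemporal = v$spatiotemporal,
      features = as.list(v$features))),
    feasibility = report$feasibility,
    feature_table = report$feature_table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a deviation report written by [write_report_json()]
#' @param path input path
#' @return list mirroring the report structure (matrices as data.frames)
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "deviation_report")) {
    stop_field("path", "not a deviation_report file")
  }
  obj
}
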