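#!/usr/bin/env Rscript
# Stage 4 — six/seven-model severity sweep for one DMD group.
#
# Solves the full experiment plan of one group (default: DMD2, the
# tiptoeing pattern; pass another group label as the first argument), warm
# starting every variant from the TD reference of stage 3, and writes the
# per-variant solver status, gait curves and the deviation report.
# Infeasible variants are a reported scientific outcome.

library(dmdgait)

grp <- commandArgs(trailingOnly = TRUE)
grp <- if (length(grp)) tolower(grp[1]) else "dmd2"
outdir <- file.path("results/sweep", grp)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

summ <- read_summary_yaml(file.path("results/cohort",
                                    paste0(grp, "_summary.yaml")))
td_fit <- readRDS("results/td/td_fit.rds")
generic <- default_planar_model()
plan <- build_experiment_plan(summ)
cfg <- ocp_config(target_speed = summ$gait_speed_mps, mesh_intervals = 15,
                  track_w0 = 3)

results <- list(); problems <- list(); statuses <- character(0)
for (lab in names(plan)) {
  cat("solving", lab, "...\n")
  model <- personalize_model(generic, summ, plan[[lab]])
  problems[[lab]] <- build_problem(model, cfg)
  results[[lab]] <- solve_gait(problems[[lab]], guess = td_fit$solution$z,
                               label = lab)
  statuses[lab] <- if (inherits(results[[lab]], "trajectory_solution"))
    "converged" else results[[lab]]$status
  print(results[[lab]])
}

report <- severity_sweep(results, td_fit$solution, problems,
                         td_fit$problem)
print(report)
write_report_json(report, file.path(outdir, "deviation_report.json"))
if (nrow(report$feature_table)) {
  write.csv(report$feature_table, file.path(outdir, "feature_table.csv"),
            row.names = FALSE)
}
for (lab in names(report$variants)) {
  dev <- report$variants[[lab]]$deviation
  write.csv(cbind(pct = dev$pct, dev$angles_deg),
            file.path(outdir, paste0(lab, "_angle_deviation.csv")),
            row.names = FALSE)
}
write_manifest(file.path(outdir, "manifest.json"),
               statuses = statuses,
               outputs = file.path(outdir, "deviation_report.json"),
               config = list(group = grp,
                             target_speed = cfg$target_speed))
cat("severity sweep for", toupper(grp), "written to", outdir, "\n")
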