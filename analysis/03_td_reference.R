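#!/usr/bin/env Rscript
# Stage 3 — typically developing reference simulation.
#
# Solves the predictive gait problem for the TD-scaled model at the group's
# mean self-selected speed, deepens the optimum by re-solving from its own
# solution, and writes the full-cycle trajectory (STO), the normalized gait
# curves and the spatiotemporal table. The solution is also the warm start
# for every DMD variant in stage 4.

library(dmdgait)

dir.create("results/td", recursive = TRUE, showWarnings = FALSE)
summ <- read_summary_yaml("results/cohort/td_summary.yaml")
model <- personalize_model(default_planar_model(), summ)
cfg <- ocp_config(target_speed = summ$gait_speed_mps, mesh_intervals = 15)
problem <- build_problem(model, cfg)

cat("solving TD reference gait ...\n")
sol <- solve_gait(problem, label = "td_reference")
stopifnot(inherits(sol, "trajectory_solution"))
# re-solve from the converged trajectory to deepen the local optimum
sol <- solve_gait(problem, guess = sol$z, label = "td_reference")
print(sol)

full <- mirror_to_full_cycle(sol, problem)
paths <- write_trajectory_sto(full, "results/td/td_reference")
curves <- time_normalize(full)
st <- spatiotemporal(full)
print(st)
write.csv(cbind(pct = curves$pct, curves$angles_deg),
          "results/td/td_angles.csv", row.names = FALSE)
write.csv(st, "results/td/td_spatiotemporal.csv", row.names = FALSE)
saveRDS(list(solution = sol, problem = problem), "results/td/td_fit.rds")

write_manifest("results/td/manifest.json",
               models = list(td = model),
               statuses = c(td_reference = sol$status),
               outputs = c(paths, "results/td/td_angles.csv",
                           "results/td/td_spatiotemporal.csv"),
               config = list(target_speed = cfg$target_speed,
                             mesh_intervals = cfg$mesh_intervals))
cat("TD reference written to results/td/\n")
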