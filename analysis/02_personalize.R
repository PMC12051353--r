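#!/usr/bin/env Rscript
# Stage 2 — personalized model variants.
#
# Reads the group summaries of stage 1, builds each group's experiment plan
# (weakness at three severity levels, weakness + contractures at the same
# levels, plus the midfoot-break variant for the flexion group), and writes
# every personalized planar model as YAML together with a plan manifest.

library(dmdgait)

dir.create("results/models", recursive = TRUE, showWarnings = FALSE)
generic <- default_planar_model()
outputs <- character(0)
models <- list()
statuses <- character(0)

for (grp in c("td", "dmd1", "dmd2", "dmd3")) {
  summ <- read_summary_yaml(file.path("results/cohort",
                                      paste0(grp, "_summary.yaml")))
  plan <- build_experiment_plan(summ)
  cat(sprintf("%s: %d variant(s): %s\n", toupper(grp), length(plan),
              paste(names(plan), collapse = ", ")))
  for (lab in names(plan)) {
    model <- personalize_model(generic, summ, plan[[lab]])
    path <- file.path("results/models",
                      sprintf("%s_%s.yaml", grp, lab))
    write_model_yaml(model, path)
    outputs <- c(outputs, path)
    models[[paste(grp, lab, sep = "_")]] <- model
  }
}

write_manifest("results/models/manifest.json",
               models = models, outputs = outputs)
cat("personalized models written to results/models/\n")
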