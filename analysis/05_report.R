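#!/usr/bin/env Rscript
# Stage 5 — cross-group summary of the severity sweeps.
#
# Collects the feature tables and feasibility flags of every group sweep in
# results/sweep/* into one table: the DMD-minus-TD change of each narrated
# peak gait feature per variant, plus which variants failed to produce a
# gait (the loss-of-ambulation analogue).

library(dmdgait)

dirs <- list.dirs("results/sweep", recursive = FALSE)
stopifnot(length(dirs) > 0)
rows <- list(); flags <- list()
for (d in dirs) {
  grp <- basename(d)
  rep <- read_report_json(file.path(d, "deviation_report.json"))
  for (lab in names(rep$feasibility)) {
    st <- rep$feasibility[[lab]]$status
    flags[[paste(grp, lab)]] <- data.frame(group = toupper(grp),
                                           variant = lab, status = st)
  }
  ft <- file.path(d, "feature_table.csv")
  if (file.exists(ft)) {
    tab <- read.csv(ft)
    tab <- cbind(group = toupper(grp), tab)
    rows[[grp]] <- tab
  }
}
features <- do.call(rbind, rows)
feasibility <- do.call(rbind, flags)
write.csv(features, "results/sweep/feature_changes.csv", row.names = FALSE)
write.csv(feasibility, "results/sweep/feasibility.csv", row.names = FALSE)
cat("== DMD-minus-TD peak-feature changes ==\n")
print(features, row.names = FALSE)
cat("\n== feasibility per variant ==\n")
print(feasibility, row.names = FALSE)
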