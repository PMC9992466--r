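#!/usr/bin/env Rscript
# Summarize completed runs: per-year trajectories, ID/OOD decay tables,
# scaling curves and reclassification fractions, all read back from the
# emitted CSVs (nothing is recomputed).

source(file.path("analysis", "_common.R"))

for (run in c("baseline", "exp1", "exp2")) {
  dir <- file.path(RESULTS_DIR, run)
  if (!dir.exists(dir)) {
    message("skipping ", run, " (no results directory)")
    next
  }
  rep <- make_report(dir)
  message(run, ": wrote ", paste(names(rep), collapse = ", "),
          " summaries under ", dir)
}
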