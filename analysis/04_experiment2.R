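#!/usr/bin/env Rscript
# Experiment 2: scaling of the pretrained representations with
# pretraining set size, on a nested ladder (every larger pretraining set
# contains the smaller ones), for both encoder architectures; emits
# per-size ID/OOD metrics, fitted scaling slopes, and the
# reclassification analysis of the best representation model against
# count-LR.
#
# Expected finding: discrimination of the downstream heads improves (or
# at least does not degrade) along the ladder, and the reclassification
# table shows more correct than incorrect reclassifications where
# count-LR has degraded.

source(file.path("analysis", "_common.R"))

cfg <- study_config(tasks = c("long_los", "icu"))
cfg$architectures <- c("gru", "transformer")
cfg$size_ladder <- c(200L, 400L, 800L)
cfg$exp2_head_years <- c(2009L, 2014L)
cfg$exp2_ood_years <- c(2015L, 2016L)
res <- run_experiment2(cfg)
write_experiment(res, file.path(RESULTS_DIR, "exp2"))

print(res$slopes)
print(res$reclassification[seq_len(min(10, nrow(res$reclassification)))])
message("wrote ", file.path(RESULTS_DIR, "exp2"))
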