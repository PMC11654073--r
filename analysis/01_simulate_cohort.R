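#!/usr/bin/env Rscript

# Step 1 — simulate the study cohort.
#
# Generates a synthetic cohort in which each subject's multivoxel word
# patterns share a known fraction (rho) of signal between the native
# language (CW) and the novel language (ALW), and each subject's power-law
# learning rate b is coupled to rho with a preset link of 0.6. Everything
# downstream must recover that link from the data alone; the ground truth
# written here is used only for post-hoc comparison.
#
# Outputs under results/cohort/data/: per-subject BOLD runs (4-D NIfTI) and
# BIDS-style events tables, ROI masks, the behavioral table, and the truth
# record.

library(pslearn)

config <- read_config("analysis/config.yaml")
out_dir <- config$out_dir

files <- stage_simulate(config, out_dir)
truth <- jsonlite::read_json(file.path(out_dir, "data", "truth.json"),
                             simplifyVector = TRUE)

cat(sprintf("Simulated %d subjects (seed %d) into %s\n",
            config$simulate$n_subjects, config$seed, out_dir))
cat(sprintf("  files written: %d (BOLD runs, events, masks, behavior, truth)\n",
            length(files)))
cat(sprintf("  true shared fraction: %.2f-%.2f; true learning rate: %.2f-%.2f\n",
            min(truth$truth$true_shared_frac), max(truth$truth$true_shared_frac),
            min(truth$truth$true_b), max(truth$truth$true_b)))
cat(sprintf("  preset correlation between rho and b: %.2f (realized %.2f)\n",
            truth$link_strength,
            cor(truth$truth$true_shared_frac, truth$truth$true_b)))
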