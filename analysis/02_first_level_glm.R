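#!/usr/bin/env Rscript

# Step 2 — first-level single-item GLMs.
#
# For every subject and run: build a design matrix with one HRF-convolved
# regressor per item (plus temporal derivatives as nuisance), high-pass
# filter data and design at 100 s, estimate per-item betas by OLS, and
# average the betas across the repeated runs of each condition. The averaged
# items x voxels patterns are written as 4-D beta volumes per subject and
# condition under results/cohort/glm/.

library(pslearn)

config <- read_config("analysis/config.yaml")
out_dir <- config$out_dir

files <- stage_glm(config, out_dir)

cat(sprintf("Estimated single-item patterns for %d beta volumes\n",
            length(files)))
example <- read_nifti_4d(files[1])
cat(sprintf("  example volume %s: %s (x, y, z, items)\n",
            basename(files[1]), paste(dim(example), collapse = " x ")))
cat(sprintf("  beta range: [%.2f, %.2f] signal units\n",
            min(example), max(example)))
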