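#!/usr/bin/env Rscript

# Step 4 — behavioral learning curves.
#
# Confirms the training effect with a one-way repeated-measures ANOVA on the
# session x subject RT panel, then fits each subject's power law
# y = a * x^(-b) by nonlinear least squares and applies the R^2 >= 0.7
# inclusion rule. Writes results/cohort/learning_fits.csv and
# exclusion_report.json.

library(pslearn)

config <- read_config("analysis/config.yaml")
out_dir <- config$out_dir

behavior <- read_table_csv(file.path(out_dir, "data", "behavior.csv"))
panel <- do.call(rbind, lapply(split(behavior$rt_ms, behavior$participant_id),
                               identity))
cat("Training effect on reaction times:\n  ")
print(rm_anova(panel))

stage_learning(config, out_dir)
fits <- read_table_csv(file.path(out_dir, "learning_fits.csv"))
report <- jsonlite::read_json(file.path(out_dir, "exclusion_report.json"),
                              simplifyVector = TRUE)

cat(sprintf("Fitted %d learning curves: a in [%.0f, %.0f] ms, b in [%.2f, %.2f]\n",
            nrow(fits), min(fits$a), max(fits$a), min(fits$b), max(fits$b)))
cat(sprintf("  inclusion rule R^2 >= %.1f: %d kept, %d excluded (mean R^2 of kept = %.2f)\n",
            report$threshold, report$n_included, report$n_excluded,
            report$mean_r_squared_included))
if (report$n_excluded > 0) {
  cat("  excluded:", paste(unlist(report$excluded_ids), collapse = ", "), "\n")
}
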