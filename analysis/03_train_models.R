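#!/usr/bin/env Rscript
# Stage 3 — shoot-biomass estimation models.
#
# For each algorithm x view set: 80/20 split, train-fitted
# standardization, exhaustive grid search under seeded 5-fold CV, held-out
# evaluation, post hoc subgroup accuracy, and SHAP attributions.

source("analysis/00_config.R")
cfg <- analysis_config()
cfg$stages <- "train"
run_pipeline(cfg)

ev <- jsonlite::read_json(file.path(cfg$output_dir, "evaluation.json"))
cat("held-out accuracy by algorithm and view set:\n")
for (nm in names(ev)) {
  o <- ev[[nm]]$overall
  cat(sprintf("  %-20s R2 = %.3f  RMSE = %5.1f g/plant (n = %d)\n",
              nm, o$r2, o$rmse, o$n))
}
best <- names(ev)[which.max(vapply(ev, function(e) e$overall$r2, 1))]
cat(sprintf("best model: %s\n", best))

sh <- read.csv(file.path(cfg$output_dir, "shap.csv"))
feats <- c("A_proj", "GRVI", "GLI", "VARI", "GSI", "H_max", "H_ave")
imp <- colMeans(abs(sh[sh$algorithm == "SVR" & sh$view == "COMBINED", feats]))
cat("mean |SHAP| (SVR, combined view):\n")
print(round(sort(imp, decreasing = TRUE), 2))
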