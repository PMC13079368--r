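#!/usr/bin/env Rscript
# Stage 5 — run summary and recovery check.
#
# Collates the run manifest and compares the fitted genotype parameters
# against the simulation truths (available here because the series is
# synthetic) — the package-level analogue of a positive control.

source("analysis/00_config.R")
cfg <- analysis_config()
cfg$stages <- "summarize"
run_pipeline(cfg)

sm <- read.csv(file.path(cfg$output_dir, "growth_summary.csv"))
truth <- default_growth_params(cfg$simulate$series$n_genotypes)
a <- merge(sm[sm$quantity == "A", c("genotype_id", "mean", "lower", "upper")],
           truth[, c("genotype_id", "A")])
a$rel_error <- abs(a$mean - a$A) / a$A
a$covered99 <- a$A >= a$lower & a$A <= a$upper
cat(sprintf("A recovery: %d/%d genotypes within 15%% of truth; max rel. error %.1f%%\n",
            sum(a$rel_error < 0.15), nrow(a), 100 * max(a$rel_error)))
cat(sprintf("99%% intervals covering the truth: %d/%d\n",
            sum(a$covered99), nrow(a)))
cat(sprintf("manifest: %s\n", file.path(cfg$output_dir, "manifest.json")))
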