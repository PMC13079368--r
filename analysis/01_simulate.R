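#!/usr/bin/env Rscript
# Stage 1 — simulate the trials.
#
# Lays out the split-plot field trial (fertilizer on main plots, genotype
# on subplots), assigns each destructively sampled plant a latent canopy
# and an allometric shoot dry weight, and generates the 12-genotype
# biomass monitoring series from the Richards-with-senescence model.

source("analysis/00_config.R")
cfg <- analysis_config()
cfg$stages <- "simulate"
run_pipeline(cfg)

sampling <- read.csv(file.path(cfg$output_dir, "sampling.csv"))
series <- read.csv(file.path(cfg$output_dir, "series.csv"))
biomass <- read.csv(file.path(cfg$output_dir, "biomass.csv"))

cat(sprintf("field: %d plots, %d destructively sampled plants\n",
            length(unique(sampling$plot_id)), nrow(sampling)))
cat(sprintf("shoot dry weight: %.0f-%.0f g/plant (median %.0f)\n",
            min(biomass$biomass), max(biomass$biomass),
            median(biomass$biomass)))
cat(sprintf("series: %d records = %d genotypes x %d plants x %d reps x %d flights\n",
            nrow(series), length(unique(series$genotype_id)),
            max(series$plant_id), max(series$replicate_id),
            length(unique(series$t))))
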