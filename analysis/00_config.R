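# Shared configuration for the analysis drivers 01-05.
# All stages write under results/analysis and are resumable: a re-run
# skips stages whose outputs already exist.

library(yamphen)

analysis_config <- function() {
  validate_config(list(
    seed = 20240429,
    output_dir = "results/analysis",
    simulate = list(
      # one season of the field trial, two plants harvested per plot per
      # stage (a desk-scale subsample of the reference 4)
      field = list(n_genotypes = 12, n_treatments = 2, n_replicates = 3,
                   n_sampling_times = 2, plants_sampled_per_plot = 2,
                   n_years = 1),
      pixel_size_m = 0.02,
      # the monitoring trial at its reference size
      series = list(n_genotypes = 12, n_plants = 8, n_replicates = 3,
                    time_points = seq(14, 224, by = 21)),
      sigma_obs = 22),
    train = list(algorithms = c("SVR", "STEPWISE"),
                 views = c("OBLIQUE60", "NADIR90", "COMBINED")),
    fit_growth = list(n_chains = 4, n_iterations = 3000, n_warmup = 500)))
}
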