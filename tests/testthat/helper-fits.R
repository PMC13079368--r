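# one small hierarchical fit shared across test files (lazily built)
.fit_cache <- new.env(parent = emptyenv())

tiny_series <- function() {
  simulate_growth_series(theta = default_growth_params(3),
                         design = series_design(n_genotypes = 3,
                                                n_plants = 2,
                                                n_replicates = 2),
                         sigma_obs = 12, seed = 41)
}

tiny_fit <- function() {
  if (is.null(.fit_cache$tiny)) {
    .fit_cache$tiny <- fit_hierarchical(
      tiny_series(), mcmc = mcmc_config(4, 800, 300, seed = 17))
  }
  .fit_cache$tiny
}

# the one full-design recovery fit shared by the acceptance tests:
# reference series design, sigma_obs = 10% of mean A, convergence profile
acceptance_recovery <- function() {
  if (is.null(.fit_cache$accept)) {
    theta <- default_growth_params()
    .fit_cache$accept <- recovery_experiment(
      theta = theta, design = series_design(),
      sigma_obs = 0.1 * mean(theta$A),
      mcmc = mcmc_config_long(seed = 101), seed = 101)
  }
  .fit_cache$accept
}
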