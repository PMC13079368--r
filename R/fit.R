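#' MCMC sampler configuration
#'
#' Defaults follow the reference analysis: four chains of 3,000 iterations
#' each, of which the first 500 are warm-up (sampler adaptation), retaining
#' `n_chains * (n_iterations - n_warmup) = 10,000` draws.
#'
#' @param n_chains,n_iterations,n_warmup integers, `n_warmup < n_iterations`.
#' @param seed integer seed; per-chain RNG streams are derived from it.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 3000, n_warmup = 500,
                        seed = 1) {
  if (n_warmup >= n_iterations) stop("n_warmup must be < n_iterations")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Reduced-iteration profile for routine testing
#' @param seed integer seed.
#' @return an `mcmc_config` with 4 chains x 1,000 iterations (500 warm-up).
#' @export
mcmc_config_reduced <- function(seed = 1) {
  mcmc_config(n_chains = 4, n_iterations = 1000, n_warmup = 500, seed = seed)
}

#' Convergence-grade profile for the gradient-free sampler
#'
#' The adaptive Gibbs/slice sampler behind [fit_hierarchical()] moves one
#' parameter at a time, so draws along the correlated `(nu, k, t_i)`
#' direction carry high autocorrelation and need longer chains than a
#' Hamiltonian sampler would to reach the same split-Rhat. This profile
#' (4 chains x 12,000 iterations, 1,500 warm-up) brings the full
#' 12-genotype fit to max split-Rhat well under 1.1 in a few minutes on
#' one CPU.
#'
#' @param seed integer seed.
#' @return an `mcmc_config`.
#' @export
mcmc_config_long <- function(seed = 1) {
  mcmc_config(n_chains = 4, n_iterations = 12000, n_warmup = 1500,
              seed = seed)
}

#' Weakly informative priors for the hierarchical growth model
#'
#' Population means `mu0` get Normal priors with data-driven centers: log of
#' the maximum observed biomass for `log A`; the time of the largest first
#' difference of the pooled mean trajectory for `t_i`; the last observation
#' time minus 10 for `t_d`; fixed broad centers for the remaining
#' log-parameters. Population SDs `sigma0` and the observation SD get
#' half-Normal priors, the latter scaled to the SD of the observed `y`.
#'
#' @param series the series the model will be fitted to.
#' @return a list of prior hyperparameters consumed by [fit_hierarchical()].
#' @export
growth_priors <- function(series) {
  stopifnot(all(c("t", "y") %in% names(series)))
  prof <- stats::aggregate(y ~ t, data = series, FUN = mean)
  prof <- prof[order(prof$t), ]
  t_infl <- if (nrow(prof) >= 2) {
    mid <- (prof$t[-1] + prof$t[-nrow(prof)]) / 2
    mid[which.max(diff(prof$y))]
  } else mean(series$t)
  # decay onset center: where the pooled mean trajectory peaks
  t_peak <- prof$t[which.max(prof$y)]
  list(
    mu0_center = c(logA = log(max(series$y, na.rm = TRUE)), lognu = 0,
                   logk = log(6 / max(diff(range(series$t)), 1)),
                   t_i = t_infl, logd = -4, t_d = t_peak),
    mu0_sd = c(1.5, 1.5, 1.5, 40, 1.5, 40),
    sigma0_scale = c(1, 1, 1, 20, 1, 20),
    sigma_obs_scale = stats::sd(series$y)
  )
}

jags_growth_model <- function(decay_mode, sigma0_mode) {
  dec <- if (decay_mode == "gated")
    "d[g[i]]*(t[i]-td[g[i]])*step(t[i]-td[g[i]])" else
    "d[g[i]]*(t[i]-td[g[i]])"
  hier <- if (sigma0_mode == "diagonal") "
  for (j in 1:G) {
    for (m in 1:6) { eta[j,m] ~ dnorm(mu0[m], tau0[m]) }
  }
  for (m in 1:6) { sig0[m] ~ dnorm(0, pow(s0[m], -2)) T(0.001,) ; tau0[m] <- pow(sig0[m], -2) }
" else "
  for (j in 1:G) { eta[j,1:6] ~ dmnorm(mu0[1:6], Omega[1:6,1:6]) }
  Omega[1:6,1:6] ~ dwish(Rmat[1:6,1:6], 8)
  Sigma0[1:6,1:6] <- inverse(Omega[1:6,1:6])
  for (m in 1:6) { sig0[m] <- sqrt(Sigma0[m,m]) }
"
  paste0("
model {
  for (i in 1:N) {
    lg[i] <- -(1/nu[g[i]]) * log(1 + nu[g[i]]*exp(-k[g[i]]*(t[i]-ti[g[i]])))
    mu[i] <- A[g[i]] * exp(lg[i] - ", dec, ")
    y[i] ~ dnorm(mu[i], tau_obs)
  }
  for (j in 1:G) {
    A[j]  <- exp(eta[j,1])
    nu[j] <- exp(eta[j,2])
    k[j]  <- exp(eta[j,3])
    ti[j] <- eta[j,4]
    d[j]  <- exp(eta[j,5])
    td[j] <- eta[j,6]
  }
", hier, "
  for (m in 1:6) { mu0[m] ~ dnorm(m0[m], pow(m0sd[m], -2)) }
  sigma_obs ~ dnorm(0, pow(sy, -2)) T(0.0001,)
  tau_obs <- pow(sigma_obs, -2)
}")
}

#' Fit the hierarchical Bayesian growth model
#'
#' Jointly estimates genotype-level Richards-with-senescence parameters
#' `theta_g`, their population mean vector and covariance, and the
#' observation SD, from an estimated-biomass series. Genotype parameters
#' follow a Normal population law on the transformed scale
#' `(log A, log nu, log k, t_i, log d, t_d)`. Sampling uses JAGS (adaptive
#' Gibbs/slice MCMC) with a centered hierarchy, which mixes well here
#' because each genotype contributes many observations. The warm-up
#' iterations are used for sampler adaptation; the remaining
#' `n_iterations - n_warmup` per chain are retained.
#'
#' Records are internally sorted by genotype, plant, replicate and time, so
#' results are invariant to input row order.
#'
#' @param series data frame with `genotype_id`, `t`, `y` (and optionally
#'   `plant_id`, `replicate_id`). Every genotype needs >= 4 distinct time
#'   points.
#' @param priors prior hyperparameters; defaults to [growth_priors()] of
#'   `series`.
#' @param mcmc an [mcmc_config()].
#' @param decay_mode `"gated"` (default: identifiable senescence onset) or
#'   `"as_printed"` (decay factor active for all `t`; see [growth_curve()]).
#' @param sigma0_mode `"diagonal"` (default, independent population scales)
#'   or `"full"` (full covariance with an inverse-Wishart-type prior).
#' @param quiet suppress JAGS progress output.
#' @return an object of class `posterior_draws`: list with `draws` (array
#'   chain x draw x parameter; genotype parameters on the natural scale),
#'   `registry` (parameter bookkeeping), `config`, `decay_mode`,
#'   `genotypes`.
#' @export
fit_hierarchical <- function(series, priors = NULL, mcmc = mcmc_config(),
                             decay_mode = c("gated", "as_printed"),
                             sigma0_mode = c("diagonal", "full"),
                             quiet = TRUE) {
  decay_mode <- match.arg(decay_mode)
  sigma0_mode <- match.arg(sigma0_mode)
  stopifnot(inherits(mcmc, "mcmc_config"))
  need <- c("genotype_id", "t", "y")
  if (!all(need %in% names(series))) stop("series must have genotype_id, t, y")
  tp_per_g <- tapply(series$t, series$genotype_id,
                     function(v) length(unique(v)))
  if (any(tp_per_g < 4))
    stop("every genotype needs >= 4 distinct time points; worst has ",
         min(tp_per_g))

  ord <- order(series$genotype_id,
               series$plant_id %||% seq_len(nrow(series)),
               series$replicate_id %||% seq_len(nrow(series)), series$t)
  series <- series[ord, ]
  genotypes <- sort(unique(series$genotype_id))
  g <- match(series$genotype_id, genotypes)
  G <- length(genotypes)
  if (is.null(priors)) priors <- growth_priors(series)

  jd <- list(N = nrow(series), G = G, g = g, t = series$t, y = series$y,
             m0 = unname(priors$mu0_center), m0sd = unname(priors$mu0_sd),
             sy = priors$sigma_obs_scale)
  if (sigma0_mode == "diagonal") jd$s0 <- unname(priors$sigma0_scale)
  else jd$Rmat <- diag(unname(priors$sigma0_scale)^2)

  model_str <- jags_growth_model(decay_mode, sigma0_mode)

  init_fun <- function(chain, jitter) {
    set.seed(derive_seed(mcmc$seed, paste0("init", chain, "j", jitter)))
    eta0 <- matrix(rep(unname(priors$mu0_center), each = G), G, 6)
    eta0 <- eta0 + matrix(stats::rnorm(G * 6), G, 6) *
      rep(c(0.1, 0.1, 0.1, 2, 0.1, 2) * (1 + jitter), each = G)
    ini <- list(eta = eta0, mu0 = unname(priors$mu0_center),
                sigma_obs = max(priors$sigma_obs_scale / 2, 1e-3),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(mcmc$seed, paste0("chain", chain,
                                                          "j", jitter)))
    if (sigma0_mode == "diagonal")
      ini$sig0 <- pmax(unname(priors$sigma0_scale) / 4, 0.01)
    ini
  }

  monitors <- c("A", "nu", "k", "ti", "d", "td", "mu0", "sig0", "sigma_obs")
  n_keep <- mcmc$n_iterations - mcmc$n_warmup
  # warm-up covers sampler adaptation plus burn-in, both discarded
  n_adapt <- max(ceiling(mcmc$n_warmup / 2), 2L)
  n_burn <- mcmc$n_warmup - n_adapt
  fit <- NULL
  for (attempt in 0:4) {
    fit <- tryCatch({
      jm <- rjags::jags.model(
        textConnection(model_str), data = jd, n.chains = mcmc$n_chains,
        n.adapt = n_adapt, quiet = quiet,
        inits = lapply(seq_len(mcmc$n_chains), init_fun, jitter = attempt))
      if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
      rjags::coda.samples(jm, monitors, n.iter = n_keep,
                          progress.bar = "none")
    }, error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error"))
    stop("initialization failed after 4 jittered retries: ",
         conditionMessage(fit))

  pars <- colnames(fit[[1]])
  arr <- array(NA_real_, c(mcmc$n_chains, n_keep, length(pars)),
               dimnames = list(chain = NULL, draw = NULL, parameter = pars))
  for (ch in seq_len(mcmc$n_chains)) arr[ch, , ] <- as.matrix(fit[[ch]])

  registry <- parse_registry(pars, genotypes)
  structure(list(draws = arr, registry = registry, config = mcmc,
                 decay_mode = decay_mode, sigma0_mode = sigma0_mode,
                 genotypes = genotypes, priors = priors),
            class = "posterior_draws")
}

parse_registry <- function(pars, genotypes) {
  qty <- sub("\\[.*", "", pars)
  idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\].*", "\\1", pars)))
  hyper_names <- c("logA", "lognu", "logk", "t_i", "logd", "t_d")
  data.frame(
    parameter = pars, quantity = qty,
    genotype_id = ifelse(qty %in% c("A", "nu", "k", "ti", "d", "td"),
                         genotypes[idx], NA_character_),
    component = ifelse(qty %in% c("mu0", "sig0"), hyper_names[idx],
                       NA_character_),
    stringsAsFactors = FALSE)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_draws: %d chains x %d draws x %d parameters (%d retained)\n",
              d[1], d[2], d[3], d[1] * d[2]))
  cat(sprintf("  %d genotypes, decay_mode = %s, sigma0_mode = %s\n",
              length(x$genotypes), x$decay_mode, x$sigma0_mode))
  invisible(x)
}

#' Total number of retained posterior draws
#' @param draws a `posterior_draws`.
#' @return integer `n_chains * (n_iterations - n_warmup)`.
#' @export
n_retained <- function(draws) {
  d <- dim(draws$draws)
  d[1] * d[2]
}
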