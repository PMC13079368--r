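#' Time-series monitoring design
#'
#' The defaults reproduce the reference monitoring trial: 12 genotypes x
#' 8 plants x 3 replicates observed at 11 flights, giving 3,168 records.
#' The default flight schedule starts two weeks after transplanting and
#' repeats every three weeks through late senescence (14 to 224 days after
#' transplanting), so that the post-peak decline is observed.
#'
#' @param n_genotypes,n_plants,n_replicates design counts.
#' @param time_points strictly increasing observation times (days after
#'   transplanting, DAP).
#' @return an object of class `series_design`.
#' @export
series_design <- function(n_genotypes = 12, n_plants = 8, n_replicates = 3,
                          time_points = seq(14, 224, by = 21)) {
  if (any(c(n_genotypes, n_plants, n_replicates) < 1))
    stop("all counts must be >= 1")
  if (any(diff(time_points) <= 0))
    stop("time_points must be strictly increasing")
  structure(list(n_genotypes = n_genotypes, n_plants = n_plants,
                 n_replicates = n_replicates, time_points = time_points),
            class = "series_design")
}

#' Reference genotype growth parameters
#'
#' A fixed table of 12 genotype parameter vectors used as the simulation
#' truth. It mirrors the qualitative structure reported for white Guinea
#' yam: seven genotypes with high asymptotic biomass `A`, a few with
#' elevated shape factor `nu` paired with lower growth-rate constant `k`
#' (slow early acceleration), inflection times `t_i` within 100-110 DAP and
#' decay onsets `t_d` within 190-200 DAP.
#'
#' @param n_genotypes number of genotypes (rows recycled/truncated from the
#'   12-row reference table).
#' @return data frame with columns `genotype_id`, `A`, `nu`, `k`, `t_i`,
#'   `d`, `t_d`.
#' @export
default_growth_params <- function(n_genotypes = 12) {
  ref <- data.frame(
    genotype_id = sprintf("G%02d", 1:12),
    A   = c(130, 145, 150, 160, 170, 240, 255, 265, 280, 300, 310, 320),
    nu  = c(0.9, 1.2, 0.8, 1.0, 1.4, 1.1, 2.6, 0.9, 2.8, 1.3, 3.0, 1.2),
    k   = c(0.085, 0.075, 0.090, 0.080, 0.070, 0.082, 0.052, 0.088, 0.050,
            0.078, 0.048, 0.080),
    t_i = c(101, 104, 100, 107, 103, 106, 109, 102, 108, 105, 110, 104),
    d   = c(0.015, 0.020, 0.025, 0.018, 0.022, 0.016, 0.024, 0.014, 0.026,
            0.019, 0.028, 0.017),
    t_d = c(191, 194, 197, 199, 192, 195, 198, 190, 200, 193, 196, 195),
    stringsAsFactors = FALSE)
  idx <- rep_len(seq_len(12), n_genotypes)
  out <- ref[idx, ]
  out$genotype_id <- sprintf("G%02d", seq_len(n_genotypes))
  rownames(out) <- NULL
  out
}

#' Population-level hyperparameters of the growth model
#'
#' The genotype parameter hierarchy lives on a transformed scale:
#' `(log A, log nu, log k, t_i, log d, t_d)`, which keeps the positive
#' parameters positive under a Normal population law.
#'
#' @param mu0 6-vector of population means on the transformed scale.
#' @param sigma0 6-vector of population SDs (transformed scale), > 0.
#' @param sigma_obs observation SD (g/plant), > 0.
#' @return an object of class `population_hyper`.
#' @export
population_hyper <- function(mu0 = c(log(210), log(1.2), log(0.075), 105,
                                     log(0.02), 195),
                             sigma0 = c(0.35, 0.45, 0.2, 3, 0.25, 3),
                             sigma_obs = 22) {
  if (length(mu0) != 6 || length(sigma0) != 6)
    stop("mu0 and sigma0 must have length 6")
  if (any(sigma0 <= 0) || sigma_obs <= 0)
    stop("sigma0 and sigma_obs must be > 0")
  nm <- c("logA", "lognu", "logk", "t_i", "logd", "t_d")
  names(mu0) <- names(sigma0) <- nm
  structure(list(mu0 = mu0, sigma0 = sigma0, sigma_obs = sigma_obs),
            class = "population_hyper")
}

#' Draw genotype parameters from the population law
#' @param hyper a [population_hyper()].
#' @param n_genotypes number of genotype vectors to draw.
#' @param seed integer seed.
#' @return data frame in the format of [default_growth_params()].
#' @export
draw_growth_params <- function(hyper, n_genotypes = 12, seed = 1) {
  stopifnot(inherits(hyper, "population_hyper"))
  set.seed(seed)
  eta <- sapply(1:6, function(j) stats::rnorm(n_genotypes, hyper$mu0[j],
                                              hyper$sigma0[j]))
  data.frame(genotype_id = sprintf("G%02d", seq_len(n_genotypes)),
             A = exp(eta[, 1]), nu = exp(eta[, 2]), k = exp(eta[, 3]),
             t_i = eta[, 4], d = exp(eta[, 5]), t_d = eta[, 6],
             stringsAsFactors = FALSE)
}

#' Simulate an estimated-biomass time series
#'
#' Generates `y = f(t; theta_g) + noise` for every genotype x plant x
#' replicate x time-point combination of the design. Noise is homoscedastic
#' Gaussian by default (matching the fitted likelihood); the
#' `"peak_proportional"` mode scales the SD with the plant's noiseless
#' trajectory so that scatter peaks around maximum shoot biomass, as seen
#' in field monitoring.
#'
#' @param theta genotype parameter table ([default_growth_params()] format),
#'   or `NULL` to draw from `hyper`.
#' @param design a [series_design()].
#' @param sigma_obs observation SD (g/plant), >= 0.
#' @param decay_mode `"gated"` (senescence starts at `t_d`) or
#'   `"as_printed"` (decay factor active at all times); see [growth_curve()].
#' @param seed integer seed.
#' @param noise `"homoscedastic"` or `"peak_proportional"`.
#' @param hyper optional [population_hyper()] used when `theta` is `NULL`.
#' @return data frame with `genotype_id`, `plant_id`, `replicate_id`, `t`,
#'   `y` (one row per design cell).
#' @export
simulate_growth_series <- function(theta = default_growth_params(),
                                   design = series_design(),
                                   sigma_obs = 22, decay_mode = "gated",
                                   seed = 1, noise = c("homoscedastic",
                                                       "peak_proportional"),
                                   hyper = NULL) {
  stopifnot(inherits(design, "series_design"))
  noise <- match.arg(noise)
  if (sigma_obs < 0) stop("sigma_obs must be >= 0")
  set.seed(seed)
  if (is.null(theta)) {
    if (is.null(hyper)) stop("supply theta or hyper")
    theta <- draw_growth_params(hyper, design$n_genotypes,
                                seed = derive_seed(seed, "theta"))
  }
  if (nrow(theta) < design$n_genotypes)
    stop("theta must cover every genotype in the design")
  theta <- theta[seq_len(design$n_genotypes), ]
  if (any(design$time_points < 0 | design$time_points > 250))
    warning("time points outside the plausible 0-250 DAP window")

  grid <- expand.grid(t = design$time_points,
                      replicate_id = seq_len(design$n_replicates),
                      plant_id = seq_len(design$n_plants),
                      g = seq_len(design$n_genotypes))
  grid <- grid[, c("g", "plant_id", "replicate_id", "t")]
  f <- numeric(nrow(grid))
  for (g in seq_len(design$n_genotypes)) {
    th <- theta[g, ]
    sel <- grid$g == g
    f[sel] <- growth_curve(grid$t[sel],
                           growth_params(th$A, th$nu, th$k, th$t_i, th$d,
                                         th$t_d), decay_mode = decay_mode)
  }
  sdvec <- if (noise == "homoscedastic") rep(sigma_obs, nrow(grid)) else {
    pk <- stats::ave(f, grid$g, FUN = max)
    sigma_obs * (0.3 + 0.7 * f / pmax(pk, 1e-12))
  }
  y <- f + stats::rnorm(nrow(grid), 0, sdvec)
  out <- data.frame(genotype_id = theta$genotype_id[grid$g],
                    plant_id = grid$plant_id, replicate_id = grid$replicate_id,
                    t = grid$t, y = y, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
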