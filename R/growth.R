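#' Genotype growth-curve parameters
#'
#' Parameter vector of the Richards-with-senescence curve: asymptotic
#' maximum biomass `A` (g/plant), shape factor `nu` (controls curvature /
#' asymmetry of the growth phase), intrinsic growth-rate constant `k`
#' (day^-1), inflection time `t_i` (DAP), decay-rate constant `d` (day^-1)
#' and decay onset `t_d` (DAP).
#'
#' @param A,nu,k,t_i,d,t_d scalars; `A`, `nu`, `k` must be > 0, `d` >= 0.
#' @return a named numeric vector of class `growth_params`.
#' @export
growth_params <- function(A, nu, k, t_i, d = 0, t_d = 0) {
  v <- c(A = unname(A), nu = unname(nu), k = unname(k), t_i = unname(t_i),
         d = unname(d), t_d = unname(t_d))
  if (any(!is.finite(v))) stop("growth parameters must be finite")
  if (A <= 0) stop("A must be > 0")
  if (nu <= 0 || k <= 0) stop("nu and k must be > 0")
  if (d < 0) stop("d must be >= 0")
  if (d > 0 && t_d <= t_i)
    yp_log("WARN", "decay onset t_d = %.1f precedes inflection t_i = %.1f",
           t_d, t_i)
  structure(v, class = "growth_params")
}

#' Richards growth curve with exponential senescence
#'
#' Shoot biomass at time `t` is a generalized-logistic (Richards) accrual
#' multiplied by an exponential decay term:
#' `f(t) = A (1 + nu e^{-k(t - t_i)})^{-1/nu} * e^{-d (t - t_d)}`.
#'
#' Two senescence conventions are supported. `"as_printed"` applies the
#' decay factor at all times, so it exceeds 1 before `t_d`; under this
#' convention `A`, `d`, `t_d` enter the curve only through `A e^{d t_d}`
#' and `d`, so `A` and `t_d` are not separately identifiable from data.
#' `"gated"` treats `t_d` as a true onset (factor equals 1 for `t < t_d`),
#' which is identifiable and is what the hierarchical fit uses by default.
#'
#' Evaluation is in log space and remains stable for large `|k (t - t_i)|`.
#'
#' @param t observation times (DAP), vectorized.
#' @param theta a [growth_params()] vector.
#' @param decay_mode `"as_printed"` or `"gated"`.
#' @return biomass values (g/plant), same length as `t`.
#' @export
growth_curve <- function(t, theta, decay_mode = c("as_printed", "gated")) {
  decay_mode <- match.arg(decay_mode)
  if (!inherits(theta, "growth_params"))
    theta <- do.call(growth_params, as.list(theta))
  A <- theta[["A"]]; nu <- theta[["nu"]]; k <- theta[["k"]]
  t_i <- theta[["t_i"]]; d <- theta[["d"]]; t_d <- theta[["t_d"]]
  loglogis <- -log1pexp(log(nu) - k * (t - t_i)) / nu
  dec <- if (decay_mode == "as_printed") d * (t - t_d) else
    d * pmax(t - t_d, 0)
  exp(log(A) + loglogis - dec)
}

#' Gaussian log-likelihood of a biomass series
#'
#' Sums the Normal log-density of each record's `y` at the curve value for
#' its genotype, with common observation SD.
#'
#' @param series data frame with `genotype_id`, `t`, `y`.
#' @param theta_by_genotype genotype parameter table
#'   ([default_growth_params()] format) covering every genotype in `series`.
#' @param sigma_obs observation SD, > 0.
#' @param decay_mode passed to [growth_curve()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(series, theta_by_genotype, sigma_obs,
                           decay_mode = c("as_printed", "gated")) {
  decay_mode <- match.arg(decay_mode)
  if (sigma_obs <= 0) stop("sigma_obs must be > 0")
  miss <- setdiff(unique(series$genotype_id), theta_by_genotype$genotype_id)
  if (length(miss))
    stop("no parameters for genotype(s): ", paste(miss, collapse = ", "))
  ll <- 0
  for (g in unique(series$genotype_id)) {
    th <- theta_by_genotype[theta_by_genotype$genotype_id == g, ][1, ]
    sel <- series$genotype_id == g
    mu <- growth_curve(series$t[sel],
                       growth_params(th$A, th$nu, th$k, th$t_i, th$d, th$t_d),
                       decay_mode = decay_mode)
    ll <- ll + sum(stats::dnorm(series$y[sel], mu, sigma_obs, log = TRUE))
  }
  ll
}
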