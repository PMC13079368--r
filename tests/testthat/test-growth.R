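test_that("growth curve honors its closed forms", {
  # at the inflection with nu = 1 and no decay: A/2
  th1 <- growth_params(150, 1, 0.08, 100)
  expect_equal(growth_curve(100, th1), 75, tolerance = 1e-12)
  # general inflection value A (1 + nu)^(-1/nu)
  for (nu in c(0.3, 1, 2.5, 7)) {
    th <- growth_params(200, nu, 0.06, 90)
    expect_equal(growth_curve(90, th), 200 * (1 + nu)^(-1 / nu),
                 tolerance = 1e-9)
  }
  # asymptote
  expect_equal(growth_curve(4000, th1), 150, tolerance = 150 * 1e-6)
  # nu = 1 reduces to the standard logistic on a whole grid
  tt <- seq(0, 220, by = 7)
  expect_equal(growth_curve(tt, th1), 150 / (1 + exp(-0.08 * (tt - 100))),
               tolerance = 1e-9)
})

test_that("log-space evaluation matches direct arithmetic and stays stable", {
  # pinned point, both decay conventions, against the naive formula
  A <- 150; nu <- 2; k <- 0.08; ti <- 100; d <- 0.02; td <- 190
  th <- growth_params(A, nu, k, ti, d, td)
  direct <- A * (1 + nu * exp(-k * (150 - ti)))^(-1 / nu)
  expect_equal(growth_curve(150, th, "as_printed"),
               direct * exp(-d * (150 - td)), tolerance = 1e-9)
  expect_equal(growth_curve(150, th, "gated"), direct, tolerance = 1e-9)
  # extreme negative times would overflow exp() naively
  expect_equal(growth_curve(-5000, th, "gated"), 0, tolerance = 1e-12)
  expect_true(is.finite(growth_curve(-5000, th, "as_printed")))
})

test_that("decay conventions differ only before the onset, and gated stays below A", {
  th <- growth_params(180, 1.5, 0.07, 95, 0.03, 185)
  tt <- seq(0, 230, by = 1)
  gated <- growth_curve(tt, th, "gated")
  printed <- growth_curve(tt, th, "as_printed")
  expect_true(all(gated <= 180 + 1e-9))
  expect_true(all(printed[tt < 185] > gated[tt < 185]))
  expect_equal(printed[tt >= 185], gated[tt >= 185], tolerance = 1e-12)
  # no decay: monotone non-decreasing
  th0 <- growth_params(180, 1.5, 0.07, 95)
  expect_true(all(diff(growth_curve(tt, th0)) >= 0))
  # domain errors
  expect_error(growth_params(150, -1, 0.08, 100), "nu")
  expect_error(growth_params(150, 1, 0, 100), "nu and k")
  expect_error(growth_params(-1, 1, 0.08, 100), "A")
})

test_that("log likelihood is a sum of Gaussian densities", {
  th <- default_growth_params(2)
  one <- data.frame(genotype_id = "G01", t = 120,
                    y = growth_curve(120, growth_params(
                      th$A[1], th$nu[1], th$k[1], th$t_i[1], th$d[1],
                      th$t_d[1]), "gated"))
  expect_equal(log_likelihood(one, th, sigma_obs = 7, "gated"),
               -log(7 * sqrt(2 * pi)), tolerance = 1e-12)
  # additivity under duplication
  small <- data.frame(genotype_id = c("G01", "G01", "G02"),
                      t = c(60, 120, 150), y = c(40, 160, 220))
  ll <- log_likelihood(small, th, sigma_obs = 20, "gated")
  expect_equal(log_likelihood(rbind(small, small), th, 20, "gated"), 2 * ll,
               tolerance = 1e-10)
  # hand computation, record by record
  mu <- c(growth_curve(c(60, 120), growth_params(th$A[1], th$nu[1], th$k[1],
                                                 th$t_i[1], th$d[1],
                                                 th$t_d[1]), "gated"),
          growth_curve(150, growth_params(th$A[2], th$nu[2], th$k[2],
                                          th$t_i[2], th$d[2], th$t_d[2]),
                       "gated"))
  by_hand <- sum(-0.5 * log(2 * pi) - log(20) -
                   (small$y - mu)^2 / (2 * 20^2))
  expect_equal(ll, by_hand, tolerance = 1e-10)
  # order invariance
  expect_equal(log_likelihood(small[c(3, 1, 2), ], th, 20, "gated"), ll)
  expect_error(log_likelihood(small, th, 0, "gated"), "sigma_obs")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(77)
  same <- matrix(rnorm(4 * 2500), 2500, 4)
  r_same <- split_rhat(same)
  # Rhat is bounded below by sqrt((n-1)/n), slightly under 1
  expect_gte(r_same, sqrt((1250 - 1) / 1250))
  expect_lt(r_same, 1.05)
  shifted <- same
  shifted[, 4] <- shifted[, 4] + 10
  expect_gt(split_rhat(shifted), 1.1)
  # within-chain drift is caught by the split
  drift <- matrix(rnorm(4 * 2000), 2000, 4) +
    seq(0, 8, length.out = 2000)
  expect_gt(split_rhat(drift), 1.1)
  # constant draws are flagged degenerate
  r0 <- split_rhat(matrix(1, 100, 4))
  expect_true(is.na(r0))
  expect_true(isTRUE(attr(r0, "degenerate")))
})

test_that("hierarchical fit keeps its draw-count bookkeeping", {
  fit <- tiny_fit()
  expect_equal(n_retained(fit), 4 * (800 - 300))
  expect_equal(dim(fit$draws)[1], 4)
  expect_equal(dim(fit$draws)[2], 500)
  # all natural-scale draws satisfy the parameter constraints
  for (q in c("A", "nu", "k", "d")) {
    cols <- grep(paste0("^", q, "\\["), dimnames(fit$draws)[[3]])
    expect_true(all(fit$draws[, , cols] >= 0))
  }
  cv <- convergence(fit)
  expect_equal(nrow(cv), dim(fit$draws)[3])
  expect_true(all(cv$rhat >= 1 - 1e-3, na.rm = TRUE))
})

test_that("fit is invariant to record order and refuses sparse designs", {
  ser <- tiny_series()
  fit <- tiny_fit()
  set.seed(5)
  fit_perm <- fit_hierarchical(ser[sample(nrow(ser)), ],
                               mcmc = mcmc_config(4, 800, 300, seed = 17))
  expect_identical(fit$draws, fit_perm$draws)
  sparse <- ser[ser$t == 14, ]
  expect_error(fit_hierarchical(sparse), "4 distinct time points")
})

test_that("posterior summaries report the right quantiles and bands", {
  fit <- tiny_fit()
  sm <- posterior_summaries(fit, dap_grid = seq(0, 230, by = 10))
  expect_equal(nrow(sm$params), dim(fit$draws)[3])
  # medians sit inside both intervals
  expect_true(all(sm$params$q25 <= sm$params$median + 1e-12 &
                    sm$params$median <= sm$params$q75 + 1e-12))
  expect_true(all(sm$params$lower <= sm$params$q25 + 1e-12 &
                    sm$params$q75 <= sm$params$upper + 1e-12))
  # quantiles agree with direct computation for one parameter
  v <- as.vector(fit$draws[, , "sigma_obs"])
  row <- sm$params[sm$params$parameter == "sigma_obs", ]
  expect_equal(row$median, median(v))
  expect_equal(row$lower, quantile(v, 0.005, names = FALSE))
  # the 95% band contains the pointwise posterior mean curve
  expect_true(all(sm$curves$lower <= sm$curves$mean + 1e-9 &
                    sm$curves$mean <= sm$curves$upper + 1e-9))
  expect_error(posterior_summaries(fit, interval_level = 1.2), "levels")
})

test_that("central intervals of known draws match known quantiles", {
  set.seed(8)
  arr <- array(rnorm(4 * 2500), c(4, 2500, 1),
               dimnames = list(NULL, NULL, "z"))
  fake <- structure(list(
    draws = arr,
    registry = data.frame(parameter = "z", quantity = "z",
                          genotype_id = NA, component = NA),
    genotypes = character(0), decay_mode = "gated"),
    class = "posterior_draws")
  sm <- posterior_summaries(fake)
  row <- sm$params[1, ]
  expect_equal(row$lower, qnorm(0.005), tolerance = 0.15)
  expect_equal(row$upper, qnorm(0.995), tolerance = 0.15)
  expect_equal(row$median, 0, tolerance = 0.05)
})
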