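# lightweight synthetic feature tables with a known smooth signal
make_feature_data <- function(n, seed, noise_sd = 5,
                              support = c("A_proj", "H_ave")) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * 7), n, 7))
  names(x) <- c("A_proj", "GRVI", "GLI", "VARI", "GSI", "H_max", "H_ave")
  lin <- rowSums(sapply(support, function(cn) 30 * x[[cn]]))
  x$biomass <- 100 + lin + rnorm(n, 0, noise_sd)
  x$genotype_id <- sprintf("G%02d", sample(4, n, replace = TRUE))
  x$year <- sample(c(2023, 2024), n, replace = TRUE)
  x
}

test_that("train/test splits have the contracted sizes and determinism", {
  d <- make_feature_data(10, 1)
  sp <- split_data(d, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_identical(split_data(d, 0.8, seed = 3), sp)
  # disjoint and exhaustive
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(d)))
  # the reference dataset size splits 922 / 230 under round-half-up
  d2 <- make_feature_data(1152, 2)
  sp2 <- split_data(d2, 0.8, seed = 1)
  expect_equal(nrow(sp2$train), floor(0.8 * 1152 + 0.5))
  expect_equal(nrow(sp2$test), 1152 - floor(0.8 * 1152 + 0.5))
  expect_error(split_data(d[1:5, ], 0.8, 1), "at least 10")
})

test_that("standardization is train-fitted, invertible, leak-free", {
  d <- make_feature_data(80, 4)
  sp <- split_data(d, 0.8, seed = 1)
  std <- standardize(sp$train, sp$test)
  mus <- colMeans(std$train[, std$feature_cols])
  sds <- apply(std$train[, std$feature_cols], 2, sd)
  expect_true(all(abs(mus) < 1e-12))
  expect_true(all(abs(sds - 1) < 1e-12))
  # round-trip on test columns
  back <- unstandardize(std$test, std$params)
  expect_equal(back$A_proj, sp$test$A_proj, tolerance = 1e-12)
  # permuting test rows never changes the parameters (anti-leakage)
  std_perm <- standardize(sp$train, sp$test[sample(nrow(sp$test)), ])
  expect_identical(std$params, std_perm$params)
  # constant feature dropped with a log message
  d$GLI <- 1
  expect_message(std2 <- standardize(d), "zero-variance")
  expect_false("GLI" %in% std2$feature_cols)
})

test_that("grid selection is optimal under its own CV record", {
  d <- make_feature_data(120, 5)
  std <- standardize(d)
  spec <- regression_spec("SVR", svr_C_grid = c(1, 10, 100),
                          svr_gamma_grid = c(0.01, 0.1, 1), seed = 7)
  fit <- tune_and_train(spec, std$train)
  rec <- fit$cv_record
  best_rmse <- rec$cv_rmse[which.min(rec$cv_rmse)]
  expect_true(all(rec$cv_rmse >= best_rmse, na.rm = TRUE))
  expect_equal(as.numeric(fit$best), as.numeric(
    rec[which.min(rec$cv_rmse), c("cost", "gamma")]))
  # determinism of the whole selection
  fit2 <- tune_and_train(spec, std$train)
  expect_identical(fit$best, fit2$best)
  # one-point grid returns that configuration
  spec1 <- regression_spec("SVR", svr_C_grid = 5, svr_gamma_grid = 0.1)
  fit1 <- tune_and_train(spec1, std$train)
  expect_equal(as.numeric(fit1$best), c(5, 0.1))
})

test_that("RF and XGB train, tune and predict deterministically", {
  d <- make_feature_data(100, 6)
  std <- standardize(d)
  for (alg in c("RF", "XGB")) {
    spec <- regression_spec(alg, rf_mtry_grid = c(2, 4),
                            xgb_learning_rate = 0.3, xgb_max_depth = c(3, 6),
                            xgb_gamma = 0, xgb_subsample = 1,
                            xgb_min_child_weight = 1, xgb_colsample = 1,
                            xgb_nrounds = 30, seed = 2)
    fit <- tune_and_train(spec, std$train)
    expect_s3_class(fit, "biomass_model")
    p1 <- predict(fit, std$train)
    fit2 <- tune_and_train(spec, std$train)
    expect_identical(fit$best, fit2$best)
    expect_equal(p1, predict(fit2, std$train), tolerance = 1e-12)
    ev <- evaluate(fit, std$train)
    expect_gt(ev$r2, 0.5)
  }
})

test_that("stepwise selection recovers a known 2-feature support", {
  # AIC-based bidirectional selection admits a noise feature with
  # probability ~0.16 each, so the check is support inclusion plus a cap
  # on spurious admissions, not exact set equality
  hits <- 0; spurious <- integer(10)
  for (s in 1:10) {
    d <- make_feature_data(150, 100 + s, noise_sd = 3)
    sw <- stepwise_aic(d)
    if (all(c("A_proj", "H_ave") %in% sw$selected)) hits <- hits + 1
    spurious[s] <- length(setdiff(sw$selected, c("A_proj", "H_ave")))
  }
  expect_gte(hits, 9)
  expect_lte(median(spurious), 2)
  # pure-noise response: intercept-only (or near-empty) model allowed
  set.seed(1)
  d0 <- make_feature_data(100, 11)
  d0$biomass <- rnorm(100)
  sw0 <- stepwise_aic(d0)
  expect_true(length(sw0$selected) <= 2)
  # duplicated feature columns are dropped, not fatal
  d2 <- make_feature_data(60, 12)
  d2$GLI <- d2$GRVI
  expect_message(sw2 <- stepwise_aic(d2), "duplicated")
  expect_false("GLI" %in% sw2$selected)
})

test_that("evaluation metrics match hand arithmetic", {
  obs <- c(10, 20, 30, 40, 50)
  pred <- c(12, 18, 33, 39, 52)
  td <- data.frame(biomass = obs)
  ev <- evaluate(NULL, td, predictions = pred)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  expect_equal(ev$r2, 1 - ss_res / ss_tot)
  expect_equal(ev$rmse, sqrt(mean((obs - pred)^2)))
  # perfect predictions
  evp <- evaluate(NULL, td, predictions = obs)
  expect_equal(evp$r2, 1)
  expect_equal(evp$rmse, 0)
  # constant-at-mean predictions give R^2 = 0
  evm <- evaluate(NULL, td, predictions = rep(mean(obs), 5))
  expect_equal(evm$r2, 0)
  # zero-variance test response flags R^2 undefined
  ev0 <- evaluate(NULL, data.frame(biomass = rep(5, 4)),
                  predictions = 1:4)
  expect_false(ev0$r2_defined)
})

test_that("subgroup reports are consistent and suppress tiny groups", {
  d <- make_feature_data(60, 8)
  pred <- d$biomass + rnorm(60, 0, 3)
  d$all <- "all"
  rep1 <- subgroup_report(pred, d, keys = "all")
  ev <- evaluate(NULL, d, predictions = pred)
  expect_equal(rep1$r2, ev$r2)
  expect_equal(rep1$rmse, ev$rmse)
  # two identical groups -> identical metrics
  d2 <- rbind(d, d); p2 <- c(pred, pred)
  d2$grp <- rep(c("a", "b"), each = 60)
  rep2 <- subgroup_report(p2, d2, keys = "grp")
  expect_equal(rep2$r2[1], rep2$r2[2])
  expect_equal(rep2$rmse[1], rep2$rmse[2])
  # a group smaller than min_n is suppressed with a flag
  d$grp <- c("tiny", "tiny", rep("big", 58))
  expect_message(rep3 <- subgroup_report(pred, d, keys = "grp"),
                 "suppressed")
  expect_true(rep3$suppressed[rep3$group == "tiny"])
  expect_true(is.na(rep3$r2[rep3$group == "tiny"]))
  # subgroup sizes sum to the test size
  expect_equal(sum(rep3$n), 60)
})

test_that("a noisier subgroup scores lower R2 in expectation", {
  worse <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    d <- make_feature_data(120, 300 + s, noise_sd = 0)
    d$grp <- rep(c("clean", "noisy"), each = 60)
    pred <- d$biomass + c(rnorm(60, 0, 4), rnorm(60, 0, 25))
    rep <- subgroup_report(pred, d, keys = "grp")
    if (rep$r2[rep$group == "noisy"] < rep$r2[rep$group == "clean"])
      worse <- worse + 1
  }
  expect_gte(worse, 16)
})
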