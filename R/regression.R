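FEATURE_COLS <- c("A_proj", "GRVI", "GLI", "VARI", "GSI", "H_max", "H_ave")

#' Specification of a biomass regression run
#'
#' Holds the algorithm choice and its hyperparameter grids. Defaults follow
#' the reference protocol: RBF-kernel SVR with cost in {1,5,10,50,100} and
#' gamma in {0.01,0.05,0.1,0.5,1}; random forests of 500 unpruned trees
#' with mtry 1-4; gradient boosting over learning rate {0.01,0.1,0.3},
#' depth {3,6,9}, gamma {0,0.1,0.2}, subsample {0.6,0.8,1}, minimum child
#' weight {1,3,5} and column subsample {0.6,0.8,1}; bidirectional stepwise
#' linear regression by AIC. Tuning is exhaustive grid search under seeded
#' 5-fold cross-validation, selecting the smallest mean CV RMSE.
#'
#' @param algorithm `"SVR"`, `"RF"`, `"XGB"` or `"STEPWISE"`.
#' @param svr_C_grid,svr_gamma_grid SVR grids.
#' @param rf_trees,rf_mtry_grid random-forest settings.
#' @param xgb_learning_rate,xgb_max_depth,xgb_gamma,xgb_subsample,xgb_min_child_weight,xgb_colsample,xgb_nrounds gradient-boosting settings.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param train_fraction fraction of rows used for training, in (0,1).
#' @param seed integer seed controlling split and fold assignment.
#' @return a list of class `regression_spec`.
#' @export
regression_spec <- function(algorithm = c("SVR", "RF", "XGB", "STEPWISE"),
                            svr_C_grid = c(1, 5, 10, 50, 100),
                            svr_gamma_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                            rf_trees = 500, rf_mtry_grid = 1:4,
                            xgb_learning_rate = c(0.01, 0.1, 0.3),
                            xgb_max_depth = c(3, 6, 9),
                            xgb_gamma = c(0, 0.1, 0.2),
                            xgb_subsample = c(0.6, 0.8, 1.0),
                            xgb_min_child_weight = c(1, 3, 5),
                            xgb_colsample = c(0.6, 0.8, 1.0),
                            xgb_nrounds = 100,
                            cv_folds = 5, train_fraction = 0.8, seed = 1) {
  algorithm <- match.arg(algorithm)
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0,1)")
  grids <- list(svr_C_grid, svr_gamma_grid, rf_mtry_grid, xgb_learning_rate,
                xgb_max_depth, xgb_gamma, xgb_subsample,
                xgb_min_child_weight, xgb_colsample)
  if (any(vapply(grids, length, integer(1)) == 0)) stop("grids must be nonempty")
  structure(list(algorithm = algorithm, svr_C_grid = svr_C_grid,
                 svr_gamma_grid = svr_gamma_grid, rf_trees = rf_trees,
                 rf_mtry_grid = rf_mtry_grid,
                 xgb_learning_rate = xgb_learning_rate,
                 xgb_max_depth = xgb_max_depth, xgb_gamma = xgb_gamma,
                 xgb_subsample = xgb_subsample,
                 xgb_min_child_weight = xgb_min_child_weight,
                 xgb_colsample = xgb_colsample, xgb_nrounds = xgb_nrounds,
                 cv_folds = cv_folds, train_fraction = train_fraction,
                 seed = seed), class = "regression_spec")
}

#' Split a table into training and testing subsets
#'
#' Train size is `train_fraction * n` rounded half-up; membership is a
#' seeded simple random sample, so the split is reproducible and disjoint.
#'
#' @param table data frame with >= 10 rows.
#' @param train_fraction fraction in (0,1).
#' @param seed integer seed.
#' @return list with `train` and `test` data frames.
#' @export
split_data <- function(table, train_fraction = 0.8, seed = 1) {
  n <- nrow(table)
  if (n < 10) stop("invalid split: need at least 10 rows")
  n_train <- round_half_up(train_fraction * n)
  if (n_train < 1 || n_train >= n) stop("invalid split: degenerate sizes")
  set.seed(seed)
  idx <- sample(n, n_train)
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Standardize features to zero mean and unit variance
#'
#' Parameters are fitted on the training subset only and applied to the
#' test subset, so no information leaks from test to train. Zero-variance
#' features are dropped with a logged warning.
#'
#' @param train,test data frames.
#' @param feature_cols columns to scale.
#' @return list with scaled `train`, `test`, the retained `feature_cols`,
#'   and `params` (data frame of per-feature mean and sd).
#' @export
standardize <- function(train, test = NULL, feature_cols = FEATURE_COLS) {
  mu <- vapply(feature_cols, function(cn) mean(train[[cn]]), numeric(1))
  sdv <- vapply(feature_cols, function(cn) stats::sd(train[[cn]]), numeric(1))
  drop <- feature_cols[!is.finite(sdv) | sdv < 1e-12]
  if (length(drop)) {
    yp_log("WARN", "dropping zero-variance feature(s): %s",
           paste(drop, collapse = ", "))
    feature_cols <- setdiff(feature_cols, drop)
    mu <- mu[feature_cols]; sdv <- sdv[feature_cols]
  }
  scale_df <- function(df) {
    for (cn in feature_cols) df[[cn]] <- (df[[cn]] - mu[cn]) / sdv[cn]
    df
  }
  list(train = scale_df(train),
       test = if (!is.null(test)) scale_df(test),
       feature_cols = feature_cols,
       params = data.frame(feature = feature_cols, mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Invert a standardization
#' @param df standardized data frame.
#' @param params the `params` element returned by [standardize()].
#' @return data frame on the original scale.
#' @export
unstandardize <- function(df, params) {
  for (i in seq_len(nrow(params))) {
    cn <- params$feature[i]
    df[[cn]] <- df[[cn]] * params$sd[i] + params$mean[i]
  }
  df
}

fit_one <- function(algorithm, x, y, pars, spec) {
  switch(algorithm,
    SVR = e1071::svm(x = x, y = y, type = "eps-regression",
                     kernel = "radial", cost = pars$cost, gamma = pars$gamma,
                     scale = FALSE),
    RF = randomForest::randomForest(x = x, y = y, ntree = spec$rf_trees,
                                    mtry = pars$mtry),
    XGB = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = pars$eta,
                    max_depth = pars$max_depth, gamma = pars$gamma,
                    subsample = pars$subsample,
                    min_child_weight = pars$min_child_weight,
                    colsample_bytree = pars$colsample_bytree, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = spec$xgb_nrounds, verbose = 0),
    stop("unknown algorithm"))
}

predict_one <- function(algorithm, model, x) {
  switch(algorithm,
    SVR = as.numeric(stats::predict(model, x)),
    RF = as.numeric(stats::predict(model, x)),
    XGB = as.numeric(stats::predict(
      model, xgboost::xgb.DMatrix(x, nthread = 1))),
    STEPWISE = as.numeric(stats::predict(model, as.data.frame(x))))
}

hyper_grid <- function(spec) {
  switch(spec$algorithm,
    SVR = expand.grid(cost = spec$svr_C_grid, gamma = spec$svr_gamma_grid),
    RF = expand.grid(mtry = spec$rf_mtry_grid),
    XGB = expand.grid(eta = spec$xgb_learning_rate,
                      max_depth = spec$xgb_max_depth,
                      gamma = spec$xgb_gamma, subsample = spec$xgb_subsample,
                      min_child_weight = spec$xgb_min_child_weight,
                      colsample_bytree = spec$xgb_colsample),
    STEPWISE = data.frame(dummy = 0))
}

#' Tune hyperparameters and fit the final model
#'
#' Exhaustive grid search over the specification's grids under seeded
#' k-fold cross-validation on the training subset; the combination with
#' the smallest mean CV RMSE wins (ties go to the earlier grid row), and
#' the final model is refit on the full training subset. Grid points that
#' fail to fit are recorded as failed and excluded from selection.
#' `STEPWISE` has no grid and delegates to [stepwise_aic()].
#'
#' @param spec a [regression_spec()].
#' @param train standardized training data frame containing `response`.
#' @param response response column name (original, unstandardized scale).
#' @param feature_cols feature column names.
#' @return an object of class `biomass_model`: list with the fitted
#'   `model`, `algorithm`, `best` hyperparameters, `cv_record` (mean CV
#'   RMSE per combination) and bookkeeping.
#' @export
tune_and_train <- function(spec, train, response = "biomass",
                           feature_cols = FEATURE_COLS) {
  stopifnot(inherits(spec, "regression_spec"))
  feature_cols <- intersect(feature_cols, names(train))
  y <- train[[response]]
  if (spec$algorithm == "STEPWISE") {
    sw <- stepwise_aic(train, response = response,
                       feature_cols = feature_cols)
    return(structure(list(model = sw$model, algorithm = "STEPWISE",
                          best = NULL, cv_record = NULL,
                          selected_features = sw$selected,
                          feature_cols = feature_cols, response = response),
                     class = "biomass_model"))
  }
  x <- as.matrix(train[, feature_cols, drop = FALSE])
  if (nrow(x) < spec$cv_folds)
    stop("invalid split: fewer training rows than cv_folds")
  grid <- hyper_grid(spec)
  set.seed(derive_seed(spec$seed, "cvfolds"))
  fold <- sample(rep_len(seq_len(spec$cv_folds), nrow(x)))
  cv_rmse <- rep(NA_real_, nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    errs <- numeric(spec$cv_folds)
    failed <- FALSE
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      m <- tryCatch({
        set.seed(derive_seed(spec$seed, sprintf("fit%d_%d", gi, f)))
        fit_one(spec$algorithm, x[tr, , drop = FALSE], y[tr],
                grid[gi, , drop = FALSE], spec)
      }, error = function(e) e)
      if (inherits(m, "error")) { failed <- TRUE; break }
      pred <- predict_one(spec$algorithm, m, x[!tr, , drop = FALSE])
      errs[f] <- sqrt(mean((y[!tr] - pred)^2))
    }
    if (failed) {
      yp_log("WARN", "grid point %d failed to fit; excluded", gi)
    } else cv_rmse[gi] <- mean(errs)
  }
  if (all(is.na(cv_rmse))) stop("every grid point failed to fit")
  best_i <- which.min(cv_rmse)
  set.seed(derive_seed(spec$seed, "finalfit"))
  final <- fit_one(spec$algorithm, x, y, grid[best_i, , drop = FALSE], spec)
  cv_record <- cbind(grid, cv_rmse = cv_rmse)
  structure(list(model = final, algorithm = spec$algorithm,
                 best = grid[best_i, , drop = FALSE], cv_record = cv_record,
                 selected_features = feature_cols,
                 feature_cols = feature_cols, response = response),
            class = "biomass_model")
}

#' @export
predict.biomass_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  predict_one(object$algorithm, object$model, x)
}

#' Bidirectional stepwise linear regression by AIC
#'
#' Starts from the intercept-only model and repeatedly applies the single
#' add/drop move with the largest AIC decrease until no move improves it
#' (the `n log(RSS/n) + 2 (p+1)` convention, as used by [stats::step()]).
#' Exactly duplicated feature columns are dropped with a warning before
#' selection.
#'
#' @param train data frame with the response and candidate features.
#' @param response response column name.
#' @param feature_cols candidate feature columns.
#' @return list with the final `model` (an `lm`) and `selected` feature
#'   names (possibly empty).
#' @export
stepwise_aic <- function(train, response = "biomass",
                         feature_cols = FEATURE_COLS) {
  feature_cols <- intersect(feature_cols, names(train))
  xm <- as.matrix(train[, feature_cols, drop = FALSE])
  dup <- duplicated(t(xm))
  if (any(dup)) {
    yp_log("WARN", "dropping exactly duplicated feature(s): %s",
           paste(feature_cols[dup], collapse = ", "))
    feature_cols <- feature_cols[!dup]
  }
  dat <- train[, c(response, feature_cols), drop = FALSE]
  null_f <- stats::as.formula(paste(response, "~ 1"))
  full_f <- stats::as.formula(paste(response, "~",
                                    paste(feature_cols, collapse = " + ")))
  fit0 <- stats::lm(null_f, data = dat)
  sel <- stats::step(fit0, scope = list(lower = null_f, upper = full_f),
                     direction = "both", trace = 0)
  selected <- setdiff(all.vars(stats::formula(sel)), response)
  list(model = sel, selected = selected)
}

#' Evaluate predictions on a held-out test subset
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the test mean; RMSE is
#' on the original response scale (g/plant). Also reports the slope and
#' intercept of observed regressed on predicted.
#'
#' @param model a `biomass_model`, or `NULL` when `predictions` is given.
#' @param test test data frame (standardized features + response).
#' @param response response column name.
#' @param predictions optional precomputed prediction vector.
#' @return list with `r2`, `rmse`, `n`, `slope`, `intercept` and
#'   `r2_defined` (FALSE when the test response has zero variance).
#' @export
evaluate <- function(model, test, response = "biomass", predictions = NULL) {
  if (nrow(test) < 1) stop("test set is empty")
  obs <- test[[response]]
  pred <- predictions %||% predict(model, test)
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2_defined <- ss_tot > 1e-12
  slope <- intercept <- NA_real_
  if (stats::sd(pred) > 1e-12) {
    cf <- stats::coef(stats::lm(obs ~ pred))
    intercept <- unname(cf[1]); slope <- unname(cf[2])
  }
  list(r2 = if (r2_defined) 1 - ss_res / ss_tot else NA_real_,
       rmse = sqrt(mean((obs - pred)^2)), n = length(obs),
       slope = slope, intercept = intercept, r2_defined = r2_defined)
}

#' Post hoc subgroup accuracy report
#'
#' Groups the single set of held-out test predictions by metadata keys
#' (no refitting) and reports per-group accuracy. Groups smaller than
#' `min_n` get their metrics suppressed with a flag.
#'
#' @param predictions prediction vector for the full test subset.
#' @param metadata test-set data frame holding the grouping keys and the
#'   observed response.
#' @param keys character vector of grouping column names.
#' @param response response column name.
#' @param min_n smallest group size whose metrics are reported.
#' @return data frame: `key`, `group`, `n`, `r2`, `rmse`, `slope`,
#'   `intercept`, `suppressed`.
#' @export
subgroup_report <- function(predictions, metadata, keys,
                            response = "biomass", min_n = 3) {
  stopifnot(length(predictions) == nrow(metadata))
  rows <- list(); i <- 1L; n_sup <- 0L
  for (key in keys) {
    for (lev in unique(metadata[[key]])) {
      sel <- metadata[[key]] == lev
      if (sum(sel) < min_n) {
        rows[[i]] <- data.frame(key = key, group = as.character(lev),
                                n = sum(sel), r2 = NA_real_, rmse = NA_real_,
                                slope = NA_real_, intercept = NA_real_,
                                suppressed = TRUE, stringsAsFactors = FALSE)
        n_sup <- n_sup + 1L
      } else {
        ev <- evaluate(NULL, metadata[sel, , drop = FALSE],
                       response = response, predictions = predictions[sel])
        rows[[i]] <- data.frame(key = key, group = as.character(lev),
                                n = ev$n, r2 = ev$r2, rmse = ev$rmse,
                                slope = ev$slope, intercept = ev$intercept,
                                suppressed = FALSE, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (n_sup > 0)
    yp_log("WARN", "%d subgroup(s) below n = %d suppressed", n_sup, min_n)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
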