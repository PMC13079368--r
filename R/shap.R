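#' Shapley-value attributions for a fitted biomass model
#'
#' Model-agnostic additive feature attributions. For stepwise linear
#' models the exact linear Shapley values are used:
#' `phi_j = beta_j (x_j - mean(background_j))`, restricted to the features
#' retained by the selection. For SVR / RF / XGB a seeded
#' permutation-sampling estimator is used: for each test row, random
#' feature orderings are telescoped against random background rows, so
#' that the baseline plus the attribution row-sum reproduces the model
#' prediction exactly (up to floating point) by construction.
#'
#' @param model a `biomass_model` from [tune_and_train()].
#' @param background background sample (training rows, standardized scale).
#' @param x test feature rows to explain.
#' @param seed integer seed for the sampling estimator.
#' @param nsim permutations per explained row.
#' @return an object of class `shap_table`: data frame of per-row,
#'   per-feature attributions with attributes `baseline` (per-row baseline
#'   used in the additivity identity) and `predictions`.
#' @export
shap_attributions <- function(model, background, x, seed = 1, nsim = 64) {
  stopifnot(inherits(model, "biomass_model"))
  if (is.null(background) || nrow(background) == 0)
    stop("background sample is empty")
  feats <- model$feature_cols
  bg <- as.matrix(background[, feats, drop = FALSE])
  xm <- as.matrix(x[, feats, drop = FALSE])
  preds <- predict(model, as.data.frame(xm))

  if (model$algorithm == "STEPWISE") {
    beta <- stats::coef(model$model)
    phi <- matrix(0, nrow(xm), length(feats),
                  dimnames = list(NULL, feats))
    for (f in intersect(model$selected_features, feats)) {
      b <- beta[[f]]
      if (!is.na(b)) phi[, f] <- b * (xm[, f] - mean(bg[, f]))
    }
    baseline <- rep(mean(predict(model, as.data.frame(bg))), nrow(xm))
  } else {
    set.seed(derive_seed(seed, "shap"))
    p <- length(feats)
    phi <- matrix(0, nrow(xm), p, dimnames = list(NULL, feats))
    baseline <- numeric(nrow(xm))
    for (i in seq_len(nrow(xm))) {
      perms <- replicate(nsim, sample.int(p), simplify = FALSE)
      bidx <- sample.int(nrow(bg), nsim, replace = TRUE)
      # build all intermediate coalitions for all permutations, one
      # predict call per explained row
      blocks <- matrix(NA_real_, nsim * (p + 1), p,
                       dimnames = list(NULL, feats))
      for (s in seq_len(nsim)) {
        z <- bg[bidx[s], ]
        blocks[(s - 1) * (p + 1) + 1, ] <- z
        for (step in seq_len(p)) {
          z[perms[[s]][step]] <- xm[i, perms[[s]][step]]
          blocks[(s - 1) * (p + 1) + 1 + step, ] <- z
        }
      }
      vals <- predict_one(model$algorithm, model$model, blocks)
      contrib <- rep(0, p)
      for (s in seq_len(nsim)) {
        off <- (s - 1) * (p + 1)
        dv <- diff(vals[off + seq_len(p + 1)])
        contrib[perms[[s]]] <- contrib[perms[[s]]] + dv
      }
      phi[i, ] <- contrib / nsim
      baseline[i] <- mean(vals[(seq_len(nsim) - 1) * (p + 1) + 1])
    }
  }
  out <- as.data.frame(phi)
  structure(out, class = c("shap_table", "data.frame"),
            baseline = baseline, predictions = preds,
            algorithm = model$algorithm)
}
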