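#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is split in half before computing the between/within variance
#' ratio, so within-chain drift registers as apparent non-convergence.
#' With `m` half-chains of length `n`, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.
#'
#' @param x matrix of draws, iterations x chains.
#' @return scalar `Rhat`; `NA` when the draws have (numerically) zero
#'   variance, with a `"degenerate"` attribute set.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) stop("need at least 4 iterations per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n2), j], x[(nrow(x) - n2 + 1):nrow(x), j])))
  n <- nrow(halves); m <- ncol(halves)
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (!is.finite(W) || W <= 1e-300 * max(1, abs(mean(mns)))) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report for posterior draws
#'
#' Computes split-chain Gelman-Rubin statistics and effective sample sizes
#' for every monitored parameter.
#'
#' @param draws a `posterior_draws` object from [fit_hierarchical()], or a
#'   3-d array indexed (chain, draw, parameter) with parameter dimnames.
#' @return an object of class `convergence_report`: data frame
#'   (`parameter`, `rhat`, `ess`) with attributes `max_rhat` and
#'   `n_degenerate`.
#' @export
convergence <- function(draws) {
  arr <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(length(dim(arr)) == 3)
  if (dim(arr)[1] < 2)
    warning("single chain: falling back to split-chain halves only")
  pars <- dimnames(arr)[[3]]
  rh <- numeric(length(pars)); ess <- numeric(length(pars))
  for (p in seq_along(pars)) {
    m <- t(arr[, , p, drop = TRUE])          # iterations x chains
    if (dim(arr)[1] == 1) m <- matrix(arr[1, , p], ncol = 1)
    rh[p] <- split_rhat(m)
    ess[p] <- tryCatch(
      sum(coda::effectiveSize(coda::mcmc.list(
        lapply(seq_len(ncol(m)), function(j) coda::mcmc(m[, j]))))),
      error = function(e) NA_real_)
  }
  out <- data.frame(parameter = pars, rhat = rh, ess = ess,
                    stringsAsFactors = FALSE)
  structure(out, class = c("convergence_report", "data.frame"),
            max_rhat = suppressWarnings(max(rh, na.rm = TRUE)),
            n_degenerate = sum(is.na(rh)))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence over %d parameters: max split-Rhat = %.4f (%d degenerate)\n",
              nrow(x), attr(x, "max_rhat"), attr(x, "n_degenerate")))
  worst <- utils::head(x[order(-x$rhat), ], 5)
  print.data.frame(worst, row.names = FALSE)
  invisible(x)
}
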