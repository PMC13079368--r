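#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Hashes a stage name into an integer offset so that pipeline stages can be
#' re-run independently while remaining reproducible from one global seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x < 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# Lightweight stderr logger used for the warnings the pipeline contract
# requires (empty masks, dropped features, suppressed subgroups, ...).
yp_log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# round-half-up, used for the train/test split size
round_half_up <- function(x) floor(x + 0.5)
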