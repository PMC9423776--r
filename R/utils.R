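#' Clip probabilities away from 0 and 1
#'
#' Probabilities are clipped to `[eps, 1 - eps]` before any logarithm is
#' taken (log-odds, log loss, KL divergence), so that refractory floors and
#' near-zero density estimates cannot produce infinities.
#'
#' @param p numeric vector or matrix of probabilities.
#' @param eps clipping bound; default `1e-12`.
#' @return `p` with values forced into `[eps, 1 - eps]`.
#' @export
clipProb <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

## numerically stable log(1 + exp(x)), single vectorized pass
log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Wrap angles into [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval `[-pi, pi)`.
#' @export
wrapPhase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

## derive a reproducible child seed (< 2^31) from a base seed and a tag
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7907 * as.double(k)) %% 2147483647)
}

## evaluate an expression under a local, restored RNG state
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
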