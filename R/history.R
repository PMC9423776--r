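#' Build a lagged spike-history design
#'
#' For every target-region sample `i` (those at or beyond the history
#' prefix) of every trial, the design row holds the spike indicators at
#' samples `i - 1, ..., i - order` of the same trial; history never crosses
#' trial boundaries. Rows are stored trial-major as a sparse matrix (spike
#' trains at physiological rates are ~1% dense).
#'
#' @param trials a [TrialSet-class].
#' @param order number of history lags: 3 for the short-history (SH) model,
#'   250 for the long-history (LH) model. Must not exceed the history
#'   prefix, which guarantees every lag is observed.
#' @return a `HistoryDesign` list: sparse matrix `X` (rows x order), target
#'   vector `y`, and row bookkeeping (`trial`, `sample`, 1-based sample
#'   index within trial).
#' @examples
#' ts <- TrialSet(matrix(c(0, 0, 1, 0, 0, 0), 1), historyPrefix = 3)
#' d <- buildHistoryDesign(ts, 3)
#' as.matrix(d$X)
#' @export
buildHistoryDesign <- function(trials, order) {
  stopifnot(is(trials, "TrialSet"))
  order <- as.integer(order)
  hp <- historyPrefix(trials)
  if (order > hp) {
    stop(sprintf(
      "order (%d) exceeds the history prefix (%d): history would be undefined",
      order, hp
    ))
  }
  sp <- spikes(trials)
  nt <- nrow(sp)
  ns <- ncol(sp)
  perTrial <- ns - hp
  nRows <- nt * perTrial
  y <- as.vector(t(sp[, (hp + 1):ns, drop = FALSE]))
  if (order > 0L) {
    hits <- which(sp == 1, arr.ind = TRUE)
    ii <- jj <- integer(0)
    if (nrow(hits) > 0L) {
      tr <- rep(hits[, 1], each = order)
      s <- rep(hits[, 2], each = order)
      k <- rep.int(seq_len(order), nrow(hits))
      tgt <- s + k
      keep <- tgt > hp & tgt <= ns
      ii <- (tr[keep] - 1L) * perTrial + (tgt[keep] - hp)
      jj <- k[keep]
    }
    X <- Matrix::sparseMatrix(
      i = ii, j = jj, x = 1, dims = c(nRows, order)
    )
  } else {
    X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nRows, 0L))
  }
  structure(
    list(
      X = X, y = y, order = order,
      trial = rep(seq_len(nt), each = perTrial),
      sample = rep((hp + 1):ns, times = nt),
      historyPrefix = hp
    ),
    class = "HistoryDesign"
  )
}

#' Restrict a history design to a subset of trials
#'
#' Design rows are trial-major and contiguous, so subsetting by trial is a
#' cheap row slice; used to reuse one full-data design across many
#' train/test splits.
#'
#' @param design a [buildHistoryDesign()] result.
#' @param trialIdx trial indices to keep.
#' @return a `HistoryDesign` restricted to those trials.
#' @export
designSubset <- function(design, trialIdx) {
  perTrial <- length(design$y) / max(design$trial)
  rows <- as.vector(vapply(trialIdx, function(t) {
    ((t - 1L) * perTrial + 1L):(t * perTrial)
  }, numeric(perTrial)))
  structure(
    list(
      X = design$X[rows, , drop = FALSE], y = design$y[rows],
      order = design$order, trial = design$trial[rows],
      sample = design$sample[rows], historyPrefix = design$historyPrefix
    ),
    class = "HistoryDesign"
  )
}

#' Fit a spike-history logistic model
#'
#' Minimizes the normalized negative log likelihood of the Bernoulli spike
#' indicator given its lagged values, optionally with an L2 penalty
#' `lambda * ||beta||^2` added to the normalized objective (the long-history
#' convention; `lambda = 1` by default there). The intercept is not
#' penalized unless `penalizeIntercept = TRUE`. The optimizer is a damped
#' Newton iteration from a zero start, converged at gradient max-norm 1e-8.
#'
#' @param design a [buildHistoryDesign()] result.
#' @param lambda L2 strength; 0 (no penalty) for SH fits.
#' @param penalizeIntercept include the intercept in the penalty
#'   (default `FALSE`).
#' @param kind optional model label; inferred as `"SH"`/`"LH"` from the
#'   order when omitted.
#' @return a [FittedGLM-class].
#' @examples
#' ts <- sampleSpikes(makeGroundTruth("refractory_rhythmic", nTrials = 8),
#'                    seed = 1)
#' fit <- fitHistoryGLM(buildHistoryDesign(ts, 3))
#' coef(fit)
#' @export
fitHistoryGLM <- function(design, lambda = 0, penalizeIntercept = FALSE,
                          kind = NULL) {
  stopifnot(inherits(design, "HistoryDesign"))
  if (length(design$y) == 0L) stop("empty design")
  if (is.null(kind)) {
    kind <- if (design$order == 3L && lambda == 0) "SH"
            else if (design$order == 250L && lambda > 0) "LH"
            else "custom"
  }
  fit <- ridgeLogistic(design$X, design$y, lambda = lambda,
                       penalizeIntercept = penalizeIntercept)
  new("FittedGLM",
    coefficients = fit$coefficients, kind = kind, order = design$order,
    lambda = lambda, penalizeIntercept = penalizeIntercept,
    nnll = fit$nnll, converged = fit$converged,
    gradientNorm = fit$gradientNorm
  )
}

#' @describeIn fitHistoryGLM coefficient vector (intercept first).
#' @param object a [FittedGLM-class].
#' @param ... unused.
#' @export
setMethod("coef", "FittedGLM", function(object, ...) object@coefficients)

setMethod("show", "FittedGLM", function(object) {
  cat(sprintf(
    "FittedGLM '%s': order %d, lambda %g, intercept %.4f, NNLL %.6f%s\n",
    object@kind, object@order, object@lambda, object@coefficients[1],
    object@nnll,
    if (object@converged) "" else " (NOT converged)"
  ))
})

#' Predict spike probability from a history model
#'
#' Evaluates `plogis(beta0 + H beta)` row by row.
#'
#' @param model a [FittedGLM-class].
#' @param design a [buildHistoryDesign()] result with matching order.
#' @return probability vector in (0, 1), one entry per design row.
#' @export
predictHistory <- function(model, design) {
  stopifnot(is(model, "FittedGLM"), inherits(design, "HistoryDesign"))
  if (design$order != model@order) {
    stop(sprintf(
      "design order %d does not match model order %d",
      design$order, model@order
    ))
  }
  b <- model@coefficients
  eta <- b[1L]
  if (model@order > 0L) {
    eta <- eta + as.numeric(design$X %*% b[-1L])
  } else {
    eta <- rep(eta, length(design$y))
  }
  plogis(eta)
}
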