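#' Log-odds of a probability series
#'
#' `log(p / (1 - p))` after clipping `p` to `[1e-12, 1 - 1e-12]`; the
#' clipping is part of the contract, so refractory floors and saturated
#' predictions map to large finite log-odds.
#'
#' @param p probabilities in `[0, 1]`.
#' @return natural-log odds, same shape as `p`.
#' @examples
#' logOdds(c(0.5, 0.9))  # 0, 2.197
#' @export
logOdds <- function(p) {
  p <- clipProb(p)
  log(p / (1 - p))
}

#' Fit a combined phase + history model
#'
#' Logistic regression of the spike indicator on exactly two regressors: the
#' log-odds of a history model's predictions and the log-odds of the phase
#' model's posterior, both computed from models trained on the same training
#' split. Only three coefficients are fit; the underlying history
#' coefficients are never refit. Regressors are mean-centered internally
#' (the centering is folded back into the reported intercept), which keeps
#' the fit well-posed when a regressor is constant — its coefficient is then
#' 0 and the intercept absorbs it.
#'
#' @param lHist log-odds of the history-model probabilities ([logOdds()]).
#' @param lPhase log-odds of the phase-model probabilities.
#' @param targets binary spike indicators aligned to the regressors.
#' @param historyKind `"SH"` or `"LH"` (labels the model phaseSH/phaseLH).
#' @return a [CombinedGLM-class].
#' @export
fitCombined <- function(lHist, lPhase, targets, historyKind = "SH") {
  if (length(lHist) != length(targets) || length(lPhase) != length(targets)) {
    stop("regressors and targets must be aligned")
  }
  if (!all(is.finite(lHist)) || !all(is.finite(lPhase))) {
    stop("regressors must be finite (log-odds are clipped upstream)")
  }
  diagnostics <- list()
  sdH <- sd(lHist)
  sdP <- sd(lPhase)
  if (sdH > 0 && sdP > 0) {
    r <- abs(stats::cor(lHist, lPhase))
    if (r > 1 - 1e-8) {
      diagnostics$collinear <- sprintf(
        "history and phase log-odds are collinear (|r| = %.10f)", r
      )
      warning(diagnostics$collinear)
    }
  }
  mH <- mean(lHist)
  mP <- mean(lPhase)
  cols <- cbind(hist = lHist - mH, phase = lPhase - mP)
  keep <- c(sdH > 0, sdP > 0)
  fit <- ridgeLogistic(cols[, keep, drop = FALSE], targets, lambda = 0)
  beta <- numeric(2)
  beta[keep] <- fit$coefficients[-1L]
  beta0 <- fit$coefficients[1L] - beta[1] * mH - beta[2] * mP
  diagnostics$converged <- fit$converged
  diagnostics$gradientNorm <- fit$gradientNorm
  diagnostics$nnll <- fit$nnll
  new("CombinedGLM",
    beta0 = beta0, betaHist = beta[1], betaPhase = beta[2],
    historyKind = historyKind, diagnostics = diagnostics
  )
}

setMethod("show", "CombinedGLM", function(object) {
  cat(sprintf(
    "CombinedGLM phase%s: beta0 %.4f, betaHist %.4f, betaPhase %.4f\n",
    object@historyKind, object@beta0, object@betaHist, object@betaPhase
  ))
})

#' Predict from a combined model
#'
#' `plogis(beta0 + betaHist * lHist + betaPhase * lPhase)`.
#'
#' @param model a [CombinedGLM-class].
#' @param lHist,lPhase aligned log-odds regressors.
#' @return probability series in (0, 1).
#' @export
predictCombined <- function(model, lHist, lPhase) {
  stopifnot(is(model, "CombinedGLM"))
  if (length(lHist) != length(lPhase)) stop("regressors must be aligned")
  bad <- which(!is.finite(lHist) | !is.finite(lPhase))
  if (length(bad)) {
    stop("non-finite regressor at sample ", bad[1])
  }
  plogis(model@beta0 + model@betaHist * lHist + model@betaPhase * lPhase)
}
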