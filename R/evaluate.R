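#' Average log loss in bits per sample
#'
#' `-mean(y log2(yhat) + (1 - y) log2(1 - yhat))` with `yhat` clipped to
#' `[1e-12, 1 - 1e-12]`. Smaller is better; a constant prediction of 0.5
#' scores exactly 1 bit/sample. Callers pass target-region samples only.
#'
#' @param y binary outcomes.
#' @param yHat predicted spike probabilities, same length.
#' @return average log loss (bits/sample).
#' @examples
#' logLoss(c(1, 0), c(0.75, 0.75))  # 1.2075
#' @export
logLoss <- function(y, yHat) {
  if (length(y) != length(yHat)) {
    stop("y and yHat must have equal length (",
         length(y), " vs ", length(yHat), ")")
  }
  yHat <- clipProb(yHat)
  -mean(y * log2(yHat) + (1 - y) * log2(1 - yHat))
}

#' Split-level model comparison by paired held-out log loss
#'
#' One-sample t-test of the per-split log-loss differences
#' `lossA - lossB` against zero. With `tail = "one"` (the default) the test
#' is lower-tailed: it asks whether model A reliably beats model B across
#' splits, at `alpha = 0.001`.
#'
#' @param lossA,lossB held-out log losses per split (same splits, paired).
#' @param modelA,modelB labels.
#' @param tail `"one"` (lower) or `"two"`.
#' @param alpha significance level (default 0.001).
#' @return a [ComparisonResult-class]. Zero-variance differences with a
#'   nonzero mean are reported with a `p = 0` sentinel and a note; all-zero
#'   differences are not significant.
#' @export
compareModels <- function(lossA, lossB, modelA = "A", modelB = "B",
                          tail = c("one", "two"), alpha = 0.001) {
  tail <- match.arg(tail)
  if (length(lossA) != length(lossB) || length(lossA) < 2L) {
    stop("need paired log losses over at least 2 splits")
  }
  d <- lossA - lossB
  note <- ""
  if (var(d) == 0) {
    if (mean(d) == 0) {
      tStat <- 0
      p <- 1
    } else {
      tStat <- if (mean(d) < 0) -Inf else Inf
      p <- 0
      note <- "zero-variance differences with nonzero mean; p = 0 sentinel"
    }
  } else {
    tt <- t.test(d, mu = 0,
                 alternative = if (tail == "one") "less" else "two.sided")
    tStat <- unname(tt$statistic)
    p <- tt$p.value
  }
  significant <- if (tail == "one") {
    p < alpha && mean(d) < 0
  } else {
    p < alpha
  }
  new("ComparisonResult",
    modelA = modelA, modelB = modelB, lossA = lossA, lossB = lossB,
    differences = d, tStatistic = tStat, pValue = p,
    tail = tail, alpha = alpha, significant = significant, note = note
  )
}

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf(
    "ComparisonResult %s vs %s over %d splits: mean diff %.3g bits, t = %.3g, p = %.3g (%s-tailed)%s\n",
    object@modelA, object@modelB, length(object@differences),
    mean(object@differences), object@tStatistic, object@pValue, object@tail,
    if (object@significant) " *" else ""
  ))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Time-windowed model comparison
#'
#' Splits the target region into consecutive non-overlapping windows
#' (50 ms by default), computes each split's mean held-out log-loss
#' difference inside every window, and tests each window's distribution of
#' differences against zero with a two-tailed one-sample t-test at a
#' Bonferroni-corrected level `baseAlpha / nWindows` (0.001 / 25 = 0.00004
#' for a 1,250 ms target region and 50 ms windows).
#'
#' @param perSampleDiff matrix of per-sample log-loss differences
#'   (model A - model B, bits), one row per split, columns in target-region
#'   time order within one trial (differences averaged across trials), OR a
#'   list of per-split matrices `trials x targetSamples`; see
#'   [evaluateModels()] which produces the latter.
#' @param windowLen window length in samples (default 50).
#' @param baseAlpha uncorrected alpha (default 0.001).
#' @return a [WindowedComparison-class].
#' @export
windowedComparison <- function(perSampleDiff, windowLen = 50L,
                               baseAlpha = 0.001) {
  if (is.list(perSampleDiff)) {
    perSampleDiff <- do.call(rbind, lapply(perSampleDiff, colMeans))
  }
  windowLen <- as.integer(windowLen)
  nT <- ncol(perSampleDiff)
  if (nT %% windowLen != 0L) {
    divs <- which(nT %% seq_len(nT) == 0L)
    stop(sprintf(
      "target length %d is not divisible by windowLen %d; valid lengths include %s",
      nT, windowLen, paste(head(divs[divs >= 10], 8), collapse = ", ")
    ))
  }
  nW <- nT %/% windowLen
  wIdx <- rep(seq_len(nW), each = windowLen)
  diffMat <- t(apply(perSampleDiff, 1, function(row) {
    tapply(row, wIdx, mean)
  }))  # splits x windows
  diffMat <- t(diffMat)  # windows x splits
  alphaB <- baseAlpha / nW
  tstat <- pval <- numeric(nW)
  for (w in seq_len(nW)) {
    d <- diffMat[w, ]
    if (var(d) == 0) {
      tstat[w] <- 0
      pval[w] <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(d, mu = 0, alternative = "two.sided")
      tstat[w] <- unname(tt$statistic)
      pval[w] <- tt$p.value
    }
  }
  new("WindowedComparison",
    windowLen = windowLen, nWindows = as.integer(nW), diffMatrix = diffMat,
    tStatistics = tstat, pValues = pval,
    baseAlpha = baseAlpha, bonferroniAlpha = alphaB,
    significant = pval < alphaB,
    medianDiff = apply(diffMat, 1, stats::median)
  )
}

setMethod("show", "WindowedComparison", function(object) {
  cat(sprintf(
    "WindowedComparison: %d windows of %d samples, %d significant at Bonferroni alpha %g\n",
    object@nWindows, object@windowLen, sum(object@significant),
    object@bonferroniAlpha
  ))
})

#' Rayleigh test for nonuniformity of spike phases
#'
#' Mean resultant length
#' `r = sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)` over the `eta` spike
#' phases, resultant `R = eta * r`, Rayleigh statistic `Z = eta * r^2`
#' (the classical definition consistent with the p-value approximation;
#' `variant = "printed"` instead returns `Z = r^2 / eta` for compatibility
#' with a variant form), and approximate p-value
#' `p = exp(sqrt(1 + 4 eta + 4 (eta^2 - R^2)) - (1 + 2 eta))`, capped at 1.
#'
#' @param spikePhases phase angles (radians) at spike times; at least 1.
#' @param variant `"standard"` (default, `Z = eta r^2`) or `"printed"`.
#' @return a [RayleighResult-class].
#' @examples
#' rayleighTest(c(0, pi / 2))@r  # 0.7071
#' @export
rayleighTest <- function(spikePhases, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  eta <- length(spikePhases)
  if (eta < 1L) stop("at least one spike phase is required")
  r <- sqrt(mean(cos(spikePhases))^2 + mean(sin(spikePhases))^2)
  R <- eta * r
  Z <- if (variant == "standard") eta * r^2 else r^2 / eta
  p <- min(1, exp(sqrt(1 + 4 * eta + 4 * (eta^2 - R^2)) - (1 + 2 * eta)))
  new("RayleighResult",
    eta = as.integer(eta), r = r, R = R, Z = Z, p = max(p, 1e-300),
    variant = variant
  )
}

setMethod("show", "RayleighResult", function(object) {
  cat(sprintf(
    "Rayleigh test: eta = %d, r = %.4f, Z = %.4g, p = %.4g\n",
    object@eta, object@r, object@Z, object@p
  ))
})
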