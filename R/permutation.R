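## Within-cycle phase permutation: the null control for phase predictivity.

## cycle labels along one trial's phase series: a new cycle starts at each
## upward crossing through -pi (the sawtooth wrap, where phase drops by ~2pi)
cycleIds <- function(phaseRow) {
  cumsum(c(1, diff(phaseRow) < -pi))
}

#' Permute phases within each oscillation cycle
#'
#' Independently shuffles the phase values inside every cycle of every
#' trial. The multiset of phases per cycle — hence the phase distribution —
#' is preserved, but the alignment between spikes and phase is destroyed.
#'
#' @param phase matrix of phase series (trials x samples).
#' @param seed integer seed.
#' @return permuted phase matrix of the same shape.
#' @export
permutePhaseWithinCycles <- function(phase, seed = 1L) {
  withSeed(seed, {
    out <- phase
    for (tr in seq_len(nrow(phase))) {
      ids <- cycleIds(phase[tr, ])
      for (cyc in unique(ids)) {
        idx <- which(ids == cyc)
        if (length(idx) > 1L) out[tr, idx] <- sample(phase[tr, idx])
      }
    }
    out
  })
}

#' Phase-permutation null control for a phase-based model
#'
#' Refits a phase-based model `nPerm` times on data whose phase series has
#' been shuffled within each cycle (spike history intact), recording the
#' held-out log loss of every permuted refit. The intact model's held-out
#' log loss is reported alongside the null distribution and its empirical
#' quantile within it: a quantile near 0 means intact phase information is
#' doing real predictive work.
#'
#' @param trials a [TrialSet-class] with phase.
#' @param split `list(train =, test =)` trial indices; defaults to the first
#'   of 20 seeded 50/50 splits.
#' @param model `"phaseSH"`, `"phase"`, or `"phaseLH"`.
#' @param nPerm number of permutations (default 100; at least 2).
#' @param seed integer seed driving the permutations.
#' @param lambda,bwGrid,cv see [fitSplitModels()].
#' @return list: `intact` (log loss, bits/sample), `null` (length `nPerm`),
#'   `quantile` (fraction of null values below `intact`), `model`.
#' @export
phasePermutationControl <- function(trials, split = NULL,
                                    model = c("phaseSH", "phase", "phaseLH"),
                                    nPerm = 100L, seed = 1L, lambda = 1,
                                    bwGrid = bandwidthGrid(), cv = "kfold") {
  model <- match.arg(model)
  if (nPerm < 2L) stop("nPerm must be at least 2")
  if (is.null(phaseMatrix(trials))) stop("TrialSet has no phase matrix")
  if (is.null(split)) {
    split <- splits(makeSplits(nTrials(trials), seed = seed))[[1L]]
  }
  hk <- switch(model, phaseSH = "SH", phaseLH = "LH", phase = NA_character_)
  lhOrder <- if (identical(hk, "LH")) 250L else 3L

  ## spike history does not change under phase permutation: fit it once
  histFit <- NULL
  lHistTrain <- lHistTest <- NULL
  yTrain <- yTest <- NULL
  train <- trials[split$train]
  test <- trials[split$test]
  if (!is.na(hk)) {
    order <- if (hk == "SH") 3L else lhOrder
    dTrain <- buildHistoryDesign(train, order)
    dTest <- buildHistoryDesign(test, order)
    histFit <- fitHistoryGLM(dTrain, lambda = if (hk == "LH") lambda else 0)
    lHistTrain <- logOdds(predictHistory(histFit, dTrain))
    lHistTest <- logOdds(predictHistory(histFit, dTest))
    yTrain <- dTrain$y
  }
  yTest <- targetVector(spikes(test), test)

  evalWithPhase <- function(phMat, kdeSeed) {
    trPh <- phMat[split$train, , drop = FALSE]
    tePh <- phMat[split$test, , drop = FALSE]
    trialsPh <- train
    trialsPh@phase <- trPh
    phaseFit <- fitPhaseModel(trialsPh, grid = bwGrid, cv = cv,
                              seed = kdeSeed)
    phiTest <- targetVector(tePh, test)
    pPhaseTest <- posteriorSpikeGivenPhase(phaseFit, phiTest)
    if (is.na(hk)) {
      return(logLoss(yTest, pPhaseTest))
    }
    phiTrain <- targetVector(trPh, train)
    lPhaseTrain <- logOdds(posteriorSpikeGivenPhase(phaseFit, phiTrain))
    comb <- fitCombined(lHistTrain, lPhaseTrain, yTrain, historyKind = hk)
    logLoss(yTest, predictCombined(comb, lHistTest, logOdds(pPhaseTest)))
  }

  intact <- evalWithPhase(phaseMatrix(trials), childSeed(seed, 0L))
  null <- vapply(seq_len(nPerm), function(b) {
    phPerm <- permutePhaseWithinCycles(phaseMatrix(trials),
                                       seed = childSeed(seed, b))
    evalWithPhase(phPerm, childSeed(seed, b))
  }, numeric(1))
  list(
    intact = intact, null = null,
    quantile = mean(null < intact), model = model
  )
}
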