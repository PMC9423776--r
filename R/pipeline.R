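## End-to-end model fitting and held-out evaluation across train/test splits.

modelNamesAll <- c("SH", "LH", "phase", "phaseSH", "phaseLH")

## flatten a trials x samples matrix to the trial-major target-region vector
targetVector <- function(m, trials) {
  as.vector(t(m))[as.vector(t(targetMask(trials)))]
}

perSampleLogLoss <- function(y, p) {
  p <- clipProb(p)
  -(y * log2(p) + (1 - y) * log2(1 - p))
}

#' Fit all models on one train/test split
#'
#' Fits the requested models on the training trials and predicts the
#' held-out trials: short-history (SH, 3 lags, unpenalized), long-history
#' (LH, 250 lags, L2 at `lambda`), the phase model (cross-validated circular
#' KDE + Bayes posterior), and the combined phaseSH/phaseLH models (logistic
#' fits on the log-odds of the history and phase predictions, trained on the
#' same training split). All predictions cover target-region samples only,
#' trial-major.
#'
#' @param trials a [TrialSet-class] (with phase, for phase-based models).
#' @param split `list(train =, test =)` trial indices.
#' @param models subset of `c("SH", "LH", "phase", "phaseSH", "phaseLH")`.
#' @param lambda L2 strength for the LH fit (default 1).
#' @param shOrder,lhOrder history lags (defaults 3 and 250).
#' @param bwGrid,cv,seed passed to [fitPhaseModel()].
#' @param fullDesigns optional precomputed full-data history designs (named
#'   `SH`/`LH`, from [buildHistoryDesign()] on all trials), reused across
#'   splits via [designSubset()].
#' @return list with `testPred` (named list of held-out probability
#'   vectors), `testY`, `logLoss` (named vector, bits/sample), `fits`
#'   (fitted model objects), and the split.
#' @export
fitSplitModels <- function(trials, split, models = modelNamesAll,
                           lambda = 1, shOrder = 3L, lhOrder = 250L,
                           bwGrid = bandwidthGrid(), cv = "kfold",
                           seed = 1L, fullDesigns = NULL) {
  models <- match.arg(models, modelNamesAll, several.ok = TRUE)
  train <- trials[split$train]
  test <- trials[split$test]
  testPred <- list()
  fits <- list()
  needPhase <- any(c("phase", "phaseSH", "phaseLH") %in% models)
  needSH <- any(c("SH", "phaseSH") %in% models)
  needLH <- any(c("LH", "phaseLH") %in% models)

  trainDesign <- list()
  testDesign <- list()
  getDesigns <- function(kind, order) {
    full <- fullDesigns[[kind]]
    if (is.null(full)) full <- buildHistoryDesign(trials, order)
    trainDesign[[kind]] <<- designSubset(full, split$train)
    testDesign[[kind]] <<- designSubset(full, split$test)
  }
  if (needSH) {
    getDesigns("SH", shOrder)
    fits$SH <- fitHistoryGLM(trainDesign$SH, lambda = 0)
  }
  if (needLH) {
    getDesigns("LH", lhOrder)
    fits$LH <- fitHistoryGLM(trainDesign$LH, lambda = lambda)
  }
  if (needPhase) {
    fits$phase <- fitPhaseModel(train, grid = bwGrid, cv = cv, seed = seed)
  }
  if ("SH" %in% models) testPred$SH <- predictHistory(fits$SH, testDesign$SH)
  if ("LH" %in% models) testPred$LH <- predictHistory(fits$LH, testDesign$LH)
  if (needPhase) {
    phiTest <- targetVector(phaseMatrix(test), test)
    phasePredTest <- posteriorSpikeGivenPhase(fits$phase, phiTest)
    if ("phase" %in% models) testPred$phase <- phasePredTest
  }
  for (hk in c("SH", "LH")) {
    nm <- paste0("phase", hk)
    if (!(nm %in% models)) next
    yTrain <- trainDesign[[hk]]$y
    lHistTrain <- logOdds(predictHistory(fits[[hk]], trainDesign[[hk]]))
    phiTrain <- targetVector(phaseMatrix(train), train)
    lPhaseTrain <- logOdds(posteriorSpikeGivenPhase(fits$phase, phiTrain))
    fits[[nm]] <- fitCombined(lHistTrain, lPhaseTrain, yTrain,
                              historyKind = hk)
    lHistTest <- logOdds(predictHistory(fits[[hk]], testDesign[[hk]]))
    testPred[[nm]] <- predictCombined(fits[[nm]], lHistTest,
                                      logOdds(phasePredTest))
  }
  yTest <- targetVector(spikes(test), test)
  list(
    testPred = testPred,
    testY = yTest,
    logLoss = vapply(testPred, function(p) logLoss(yTest, p), numeric(1)),
    fits = fits,
    split = split
  )
}

#' Evaluate models across all splits of a TrialSet
#'
#' Runs [fitSplitModels()] on every split and collects held-out log losses,
#' optional per-sample log-loss matrices (for [windowedComparison()]), and
#' optional KL divergences from a generative probability track.
#'
#' @param trials a [TrialSet-class].
#' @param splitSet a [SplitSet-class] (default: 20 seeded 50/50 splits).
#' @param models,lambda,bwGrid,cv passed to [fitSplitModels()].
#' @param seed base seed for KDE fold assignment (per-split children).
#' @param returnPerSample keep per-split, per-model matrices
#'   (`testTrials x targetSamples`) of per-sample log loss.
#' @param groundTruthProb optional generative probability matrix
#'   (`nTrials x nSamples`, e.g. `metadata$effProb` from [sampleSpikes()]);
#'   when given, held-out KL divergences are computed per model.
#' @return list: `logLoss` (splits x models), `kl` (splits x models or
#'   NULL), `perSample` (list or NULL), `splitSet`.
#' @export
evaluateModels <- function(trials, splitSet = NULL, models = modelNamesAll,
                           lambda = 1, bwGrid = bandwidthGrid(),
                           cv = "kfold", seed = 1L,
                           returnPerSample = FALSE,
                           groundTruthProb = NULL) {
  if (is.null(splitSet)) {
    splitSet <- makeSplits(nTrials(trials), seed = seed)
  }
  if (is.null(groundTruthProb) && !is.null(trials@metadata$effProb)) {
    groundTruthProb <- trials@metadata$effProb
  }
  sps <- splits(splitSet)
  nS <- length(sps)
  ll <- matrix(NA_real_, nS, length(models),
               dimnames = list(NULL, models))
  kl <- if (!is.null(groundTruthProb)) ll else NULL
  perSample <- if (returnPerSample) {
    stats::setNames(vector("list", length(models)), models)
  } else NULL
  nTgt <- nSamples(trials) - historyPrefix(trials)
  fullDesigns <- list()
  if (any(c("SH", "phaseSH") %in% models)) {
    fullDesigns$SH <- buildHistoryDesign(trials, 3L)
  }
  if (any(c("LH", "phaseLH") %in% models)) {
    fullDesigns$LH <- buildHistoryDesign(trials, 250L)
  }
  for (s in seq_len(nS)) {
    res <- fitSplitModels(trials, sps[[s]], models = models, lambda = lambda,
                          bwGrid = bwGrid, cv = cv,
                          seed = childSeed(seed, s), fullDesigns = fullDesigns)
    ll[s, names(res$logLoss)] <- res$logLoss
    if (!is.null(groundTruthProb)) {
      testTS <- trials[sps[[s]]$test]
      pTrue <- targetVector(
        groundTruthProb[sps[[s]]$test, , drop = FALSE], testTS
      )
      for (m in models) {
        kl[s, m] <- klDivergence(pTrue, res$testPred[[m]])$average
      }
    }
    if (returnPerSample) {
      for (m in models) {
        lossVec <- perSampleLogLoss(res$testY, res$testPred[[m]])
        perSample[[m]][[s]] <- matrix(lossVec, ncol = nTgt, byrow = TRUE)
      }
    }
  }
  list(logLoss = ll, kl = kl, perSample = perSample, splitSet = splitSet)
}

#' Detect a spike-phase relationship in one spike train
#'
#' The headline detection procedure: held-out log losses of the phaseSH and
#' SH models across the splits, compared with a lower-tailed one-sample
#' t-test at `alpha` (default 0.001). A significant result means phase
#' information reliably improves held-out prediction beyond refractory
#' spike history.
#'
#' @param trials a [TrialSet-class] with phase.
#' @param splitSet optional [SplitSet-class]; default 20 seeded splits.
#' @param alpha significance level.
#' @param ... passed to [evaluateModels()].
#' @return a [ComparisonResult-class] for phaseSH vs SH.
#' @export
detectPhaseLocking <- function(trials, splitSet = NULL, alpha = 0.001, ...) {
  ev <- evaluateModels(trials, splitSet, models = c("SH", "phase", "phaseSH"),
                       ...)
  compareModels(ev$logLoss[, "phaseSH"], ev$logLoss[, "SH"],
                modelA = "phaseSH", modelB = "SH", tail = "one",
                alpha = alpha)
}
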