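#' @import methods
#' @importFrom stats density plogis approx rbinom runif t.test var sd
#' @importFrom utils read.table write.table head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TrialSet: trial-structured spike, LFP and phase series
#'
#' Aligned per-trial time series on a 1 ms grid: a binary spike matrix, and
#' optional LFP voltage and instantaneous-phase matrices of the same shape.
#' The first `historyPrefix` samples of every trial are history-only: they
#' feed spike-history regressors but are never prediction targets.
#'
#' @slot spikes binary matrix, one row per trial.
#' @slot lfp optional numeric matrix of LFP voltage (same shape).
#' @slot phase optional numeric matrix of phase in `[-pi, pi)` (same shape).
#' @slot fs sampling rate in Hz.
#' @slot historyPrefix number of leading history-only samples per trial.
#' @slot trialIds character labels, one per trial.
#' @slot metadata free-form list (e.g. the effective generative probability
#'   track attached by [sampleSpikes()]).
#' @export
setClass("TrialSet",
  representation(
    spikes = "matrix",
    lfp = "matrixOrNULL",
    phase = "matrixOrNULL",
    fs = "numeric",
    historyPrefix = "integer",
    trialIds = "character",
    metadata = "list"
  )
)

setValidity("TrialSet", function(object) {
  msg <- character()
  sp <- object@spikes
  nonBinary <- !(sp == 0 | sp == 1)
  if (any(nonBinary)) {
    bad <- which(nonBinary, arr.ind = TRUE)[1, ]
    msg <- c(msg, sprintf(
      "spikes must be 0/1; first offending value %g at trial %d, sample %d",
      sp[bad[1], bad[2]], bad[1], bad[2]
    ))
  }
  for (nm in c("lfp", "phase")) {
    m <- slot(object, nm)
    if (!is.null(m) && !identical(dim(m), dim(sp))) {
      msg <- c(msg, sprintf("%s matrix shape must match spikes", nm))
    }
  }
  if (!is.null(object@phase)) {
    ph <- object@phase
    if (any(ph < -pi | ph >= pi, na.rm = TRUE)) {
      msg <- c(msg, "phase values must lie in [-pi, pi)")
    }
  }
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (object@historyPrefix < 0L || object@historyPrefix >= ncol(sp)) {
    msg <- c(msg, "historyPrefix must satisfy 0 <= historyPrefix < n_samples")
  }
  if (length(object@trialIds) != nrow(sp)) {
    msg <- c(msg, "trialIds must have one entry per trial")
  }
  if (length(msg)) msg else TRUE
})

#' SplitSet: repeated train/test partitions of trials
#'
#' @slot nTrials number of trials partitioned.
#' @slot splits list of `list(train =, test =)` integer trial indices.
#' @slot trainFraction proportion of trials assigned to training.
#' @slot seed integer seed that generated the splits.
#' @export
setClass("SplitSet",
  representation(
    nTrials = "integer",
    splits = "list",
    trainFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SplitSet", function(object) {
  msg <- character()
  for (k in seq_along(object@splits)) {
    s <- object@splits[[k]]
    if (!setequal(c(s$train, s$test), seq_len(object@nTrials)) ||
        length(intersect(s$train, s$test)) > 0L) {
      msg <- c(msg, sprintf(
        "split %d: train and test must be disjoint and cover all trials", k
      ))
    }
  }
  if (object@trainFraction <= 0 || object@trainFraction >= 1) {
    msg <- c(msg, "trainFraction must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generative spike probability with optional rhythm
#'
#' Per-sample spike probability tracks for the four simulated spike-train
#' types: atemporal, refractory non-rhythmic, non-refractory rhythmic, and
#' refractory rhythmic. Rhythmic kinds modulate the probability by a von
#' Mises density over the phase of an 8 Hz sawtooth; refractory kinds force
#' the probability to a floor for `refractoryLen` samples after each sampled
#' spike (applied during sampling, not stored in `prob`).
#'
#' @slot kind one of `"atemporal"`, `"refractory_nonrhythmic"`,
#'   `"nonrefractory_rhythmic"`, `"refractory_rhythmic"`.
#' @slot baseRate mean firing rate in Hz.
#' @slot cycleLen oscillation cycle length in samples.
#' @slot kappa von Mises concentration of the rhythmic modulation.
#' @slot refractoryLen refractory period in samples.
#' @slot refractoryFloor probability forced during the refractory period.
#' @slot prob per-sample probability matrix before refractory adjustment.
#' @slot phase matched phase matrix (sawtooth in `[-pi, pi)`).
#' @slot fs sampling rate in Hz.
#' @export
setClass("GroundTruth",
  representation(
    kind = "character",
    baseRate = "numeric",
    cycleLen = "integer",
    kappa = "numeric",
    refractoryLen = "integer",
    refractoryFloor = "numeric",
    prob = "matrix",
    phase = "matrix",
    fs = "numeric"
  )
)

groundTruthKinds <- c(
  "atemporal", "refractory_nonrhythmic",
  "nonrefractory_rhythmic", "refractory_rhythmic"
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!(object@kind %in% groundTruthKinds)) {
    msg <- c(msg, paste("kind must be one of:", paste(groundTruthKinds, collapse = ", ")))
  }
  if (any(object@prob < 0 | object@prob > 1)) {
    msg <- c(msg, "prob must lie in [0, 1]")
  }
  if (!identical(dim(object@prob), dim(object@phase))) {
    msg <- c(msg, "prob and phase matrices must have the same shape")
  }
  if (length(msg)) msg else TRUE
})

#' PhaseEstimator: circular KDE of spike phase with Bayes posterior
#'
#' Holds the Gaussian kernel density estimate of `p(phi | spike)` built on a
#' fixed grid over `[-pi, pi)`, together with the training-set spike prior
#' `p(spike)`, from which [posteriorSpikeGivenPhase()] derives
#' `p(spike | phi)` under a uniform phase prior `1/(2*pi)`.
#'
#' @slot spikePhases training phases co-occurring with spikes (radians).
#' @slot bandwidth kernel standard deviation sigma, radians.
#' @slot grid evaluation grid over `[-pi, pi)`.
#' @slot density likelihood values `p(phi | spike)` on the grid.
#' @slot spikePrior training-set `p(spike)` per sample.
#' @export
setClass("PhaseEstimator",
  representation(
    spikePhases = "numeric",
    bandwidth = "numeric",
    grid = "numeric",
    density = "numeric",
    spikePrior = "numeric"
  )
)

setValidity("PhaseEstimator", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density)) {
    msg <- c(msg, "grid and density must have equal length")
  }
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  if (length(object@spikePrior) == 1L && !is.na(object@spikePrior) &&
      (object@spikePrior <= 0 || object@spikePrior >= 1)) {
    msg <- c(msg, "spikePrior must lie in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' FittedGLM: fitted spike-history logistic model
#'
#' Coefficients of a logistic regression of the spike indicator on its own
#' lagged values: `order = 3` lags for the short-history (SH) model, 250 for
#' the L2-regularized long-history (LH) model. Coefficient 1 is the
#' intercept; coefficient `k + 1` multiplies the spike indicator `k` ms back.
#'
#' @slot coefficients numeric vector `(beta0, beta1, ..., beta_order)`.
#' @slot kind `"SH"`, `"LH"` or a custom label.
#' @slot order number of history lags.
#' @slot lambda L2 penalty strength on the normalized negative log
#'   likelihood (0 for SH).
#' @slot penalizeIntercept whether the intercept entered the penalty.
#' @slot nnll final normalized negative log likelihood (nats/sample, penalty
#'   excluded).
#' @slot converged logical; gradient norm reached tolerance.
#' @slot gradientNorm final max-norm of the objective gradient.
#' @export
setClass("FittedGLM",
  representation(
    coefficients = "numeric",
    kind = "character",
    order = "integer",
    lambda = "numeric",
    penalizeIntercept = "logical",
    nnll = "numeric",
    converged = "logical",
    gradientNorm = "numeric"
  )
)

setValidity("FittedGLM", function(object) {
  if (length(object@coefficients) != object@order + 1L) {
    return("coefficients must have length order + 1 (intercept first)")
  }
  TRUE
})

#' CombinedGLM: phase + history model fit on log-odds
#'
#' Three-coefficient logistic model combining the log-odds of a
#' history-model prediction and of the phase-model posterior:
#' `p = plogis(beta0 + betaHist * l_hist + betaPhase * l_phase)`. The
#' history coefficients themselves are never refit.
#'
#' @slot beta0 intercept.
#' @slot betaHist coefficient on the history-model log-odds.
#' @slot betaPhase coefficient on the phase-model log-odds.
#' @slot historyKind `"SH"` or `"LH"` (model label becomes phaseSH/phaseLH).
#' @slot diagnostics list: convergence info, collinearity warnings.
#' @export
setClass("CombinedGLM",
  representation(
    beta0 = "numeric",
    betaHist = "numeric",
    betaPhase = "numeric",
    historyKind = "character",
    diagnostics = "list"
  )
)

#' ComparisonResult: split-level model comparison by held-out log loss
#'
#' @slot modelA,modelB model labels; the test asks whether A beats B.
#' @slot lossA,lossB per-split held-out log losses (bits/sample).
#' @slot differences `lossA - lossB` per split.
#' @slot tStatistic,pValue one-sample t-test of the differences against 0.
#' @slot tail `"one"` (lower) or `"two"`.
#' @slot alpha significance level.
#' @slot significant logical flag, `pValue < alpha`.
#' @slot note diagnostic note (e.g. zero-variance differences).
#' @export
setClass("ComparisonResult",
  representation(
    modelA = "character", modelB = "character",
    lossA = "numeric", lossB = "numeric",
    differences = "numeric",
    tStatistic = "numeric", pValue = "numeric",
    tail = "character", alpha = "numeric",
    significant = "logical", note = "character"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (length(object@differences) != length(object@lossA)) {
    msg <- c(msg, "differences must have one entry per split")
  }
  if (length(msg)) msg else TRUE
})

#' WindowedComparison: time-resolved model comparison
#'
#' Mean held-out log-loss differences in consecutive non-overlapping windows
#' of the target region, tested per window with a two-tailed one-sample
#' t-test at a Bonferroni-corrected alpha.
#'
#' @slot windowLen window length in samples (ms at 1 kHz).
#' @slot nWindows number of windows.
#' @slot diffMatrix `nWindows x nSplits` mean log-loss differences.
#' @slot tStatistics,pValues per-window test results.
#' @slot baseAlpha uncorrected alpha.
#' @slot bonferroniAlpha `baseAlpha / nWindows`.
#' @slot significant per-window logical flags.
#' @slot medianDiff per-window median difference across splits (display).
#' @export
setClass("WindowedComparison",
  representation(
    windowLen = "integer", nWindows = "integer",
    diffMatrix = "matrix",
    tStatistics = "numeric", pValues = "numeric",
    baseAlpha = "numeric", bonferroniAlpha = "numeric",
    significant = "logical", medianDiff = "numeric"
  )
)

#' RayleighResult: test of circular nonuniformity of spike phases
#'
#' @slot eta spike count.
#' @slot r mean resultant length.
#' @slot R `eta * r`.
#' @slot Z Rayleigh statistic (`eta * r^2` by default; see
#'   [rayleighTest()] for the printed-variant flag).
#' @slot p approximate p-value, capped at 1.
#' @slot variant which Z definition was used.
#' @export
setClass("RayleighResult",
  representation(
    eta = "integer", r = "numeric", R = "numeric",
    Z = "numeric", p = "numeric", variant = "character"
  )
)

setValidity("RayleighResult", function(object) {
  msg <- character()
  if (object@r < 0 || object@r > 1 + 1e-12) msg <- c(msg, "r must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
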