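#' Construct a TrialSet
#'
#' @param spikes binary matrix, one row per trial, one column per 1 ms
#'   sample.
#' @param lfp optional LFP voltage matrix of the same shape.
#' @param phase optional phase matrix in `[-pi, pi)` of the same shape.
#' @param fs sampling rate in Hz (default 1000).
#' @param historyPrefix leading samples per trial used only as spike-history
#'   regressors, never as prediction targets (default 250).
#' @param trialIds optional trial labels.
#' @param metadata optional list of extra data.
#' @return a validated [TrialSet-class] object.
#' @examples
#' ts <- TrialSet(matrix(0, 2, 500), historyPrefix = 100)
#' nTrials(ts)
#' @export
TrialSet <- function(spikes, lfp = NULL, phase = NULL, fs = 1000,
                     historyPrefix = 250L, trialIds = NULL,
                     metadata = list()) {
  spikes <- as.matrix(spikes)
  storage.mode(spikes) <- "double"
  if (is.null(trialIds)) trialIds <- paste0("trial", seq_len(nrow(spikes)))
  if (!is.null(lfp)) {
    lfp <- as.matrix(lfp)
    storage.mode(lfp) <- "double"
  }
  if (!is.null(phase)) {
    phase <- as.matrix(phase)
    storage.mode(phase) <- "double"
  }
  new("TrialSet",
    spikes = spikes, lfp = lfp, phase = phase, fs = as.numeric(fs),
    historyPrefix = as.integer(historyPrefix),
    trialIds = as.character(trialIds), metadata = metadata
  )
}

#' Accessors for TrialSet objects
#'
#' `spikes()`, `lfpSignal()` and `phaseMatrix()` return the trial-by-sample
#' matrices; `samplingRate()`, `historyPrefix()`, `nTrials()`, `nSamples()`
#' and `trialIds()` return the corresponding scalars/labels.
#'
#' @param x a [TrialSet-class].
#' @param value replacement phase matrix.
#' @name TrialSet-accessors
NULL

#' @rdname TrialSet-accessors
#' @export
setMethod("spikes", "TrialSet", function(x) x@spikes)

#' @rdname TrialSet-accessors
#' @export
setMethod("lfpSignal", "TrialSet", function(x) x@lfp)

#' @rdname TrialSet-accessors
#' @export
setMethod("phaseMatrix", "TrialSet", function(x) x@phase)

#' @rdname TrialSet-accessors
#' @export
setMethod("phaseMatrix<-", "TrialSet", function(x, value) {
  x@phase <- value
  validObject(x)
  x
})

#' @rdname TrialSet-accessors
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @rdname TrialSet-accessors
#' @export
setMethod("historyPrefix", "TrialSet", function(x) x@historyPrefix)

#' @rdname TrialSet-accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) nrow(x@spikes))

#' @rdname TrialSet-accessors
#' @export
setMethod("nSamples", "TrialSet", function(x) ncol(x@spikes))

#' @rdname TrialSet-accessors
#' @export
setMethod("trialIds", "TrialSet", function(x) x@trialIds)

setMethod("show", "TrialSet", function(object) {
  cat(sprintf(
    "TrialSet: %d trials x %d samples at %g Hz (%d-sample history prefix)\n",
    nTrials(object), nSamples(object), samplingRate(object),
    historyPrefix(object)
  ))
  cat(sprintf(
    "  spikes: %d total (%.3g Hz mean rate)%s%s\n",
    sum(object@spikes),
    sum(object@spikes) / (length(object@spikes) / samplingRate(object)),
    if (is.null(object@lfp)) "" else "; LFP present",
    if (is.null(object@phase)) "" else "; phase present"
  ))
})

#' Subset a TrialSet by trial
#'
#' @param x a [TrialSet-class].
#' @param i trial indices.
#' @param j,...,drop ignored.
#' @return a [TrialSet-class] with the selected trials.
#' @export
setMethod("[", "TrialSet", function(x, i, j, ..., drop = FALSE) {
  TrialSet(
    spikes = x@spikes[i, , drop = FALSE],
    lfp = if (is.null(x@lfp)) NULL else x@lfp[i, , drop = FALSE],
    phase = if (is.null(x@phase)) NULL else x@phase[i, , drop = FALSE],
    fs = x@fs, historyPrefix = x@historyPrefix,
    trialIds = x@trialIds[i], metadata = x@metadata
  )
})

#' Target-region mask
#'
#' Marks the samples that serve as prediction targets: everything from
#' `historyPrefix` on, in every trial. The history prefix feeds lagged
#' regressors only.
#'
#' @param trials a [TrialSet-class].
#' @return logical matrix of the same shape as `spikes(trials)`; `FALSE` on
#'   the first `historyPrefix(trials)` samples of each trial.
#' @examples
#' ts <- TrialSet(matrix(0, 2, 10), historyPrefix = 4)
#' rowSums(targetMask(ts))  # 6 target samples per trial
#' @export
targetMask <- function(trials) {
  stopifnot(is(trials, "TrialSet"))
  m <- matrix(TRUE, nTrials(trials), nSamples(trials))
  if (historyPrefix(trials) > 0L) m[, seq_len(historyPrefix(trials))] <- FALSE
  m
}

#' Generate repeated train/test splits of trials
#'
#' Partitions trial labels into train and test sets, independently per
#' split, by sampling without replacement. Defaults follow the analysis
#' protocol: 20 splits at a 50/50 partition. The train size is
#' `floor(trainFraction * nTrials)`, clamped to `[1, nTrials - 1]`.
#'
#' @param nTrials number of trials (>= 2).
#' @param nSplits number of independent splits (default 20).
#' @param trainFraction proportion of trials used for training, in (0, 1).
#' @param seed integer seed; the same seed reproduces the same splits.
#' @return a [SplitSet-class].
#' @examples
#' ss <- makeSplits(48, nSplits = 20, seed = 1)
#' lengths(splits(ss)[[1]])  # 24 train, 24 test
#' @export
makeSplits <- function(nTrials, nSplits = 20L, trainFraction = 0.5,
                       seed = 1L) {
  if (nTrials < 2) stop("nTrials must be at least 2")
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1")
  }
  nTrain <- max(1L, min(nTrials - 1L, floor(trainFraction * nTrials)))
  sp <- withSeed(seed, lapply(seq_len(nSplits), function(k) {
    train <- sort(sample.int(nTrials, nTrain))
    list(train = train, test = setdiff(seq_len(nTrials), train))
  }))
  new("SplitSet",
    nTrials = as.integer(nTrials), splits = sp,
    trainFraction = trainFraction, seed = as.integer(seed)
  )
}

#' @rdname makeSplits
#' @param x a [SplitSet-class].
#' @export
setMethod("splits", "SplitSet", function(x) x@splits)

setMethod("show", "SplitSet", function(object) {
  cat(sprintf(
    "SplitSet: %d splits of %d trials (train fraction %.2f, seed %d)\n",
    length(object@splits), object@nTrials, object@trainFraction, object@seed
  ))
})

#' Number of splits in a SplitSet
#' @param x a [SplitSet-class].
#' @return integer count of splits.
#' @export
nSplits <- function(x) length(x@splits)
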