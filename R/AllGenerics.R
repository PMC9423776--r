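#' @rdname TrialSet-accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("lfpSignal", function(x) standardGeneric("lfpSignal"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("phaseMatrix", function(x) standardGeneric("phaseMatrix"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("phaseMatrix<-", function(x, value) standardGeneric("phaseMatrix<-"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("historyPrefix", function(x) standardGeneric("historyPrefix"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TrialSet-accessors
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname makeSplits
#' @export
setGeneric("splits", function(x) standardGeneric("splits"))
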