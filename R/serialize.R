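#' Serialize fitted models to JSON
#'
#' Writes a fitted model's coefficients and recipe so predictions are
#' reproducible end-to-end: kind/order/lambda/coefficients for history
#' models, bandwidth (sigma, radians), spike prior and the grid likelihood
#' table for phase estimators, and the three coefficients plus the
#' underlying history kind for combined models.
#'
#' @param model a [FittedGLM-class], [PhaseEstimator-class] or
#'   [CombinedGLM-class].
#' @param path output path.
#' @param meta optional named list of training metadata (e.g. split seed).
#' @return invisibly, the list that was written.
#' @export
saveModelJSON <- function(model, path, meta = list()) {
  obj <- if (is(model, "FittedGLM")) {
    list(
      type = "history", kind = model@kind, order = model@order,
      lambda = model@lambda, penalizeIntercept = model@penalizeIntercept,
      coefficients = model@coefficients, nnll = model@nnll
    )
  } else if (is(model, "PhaseEstimator")) {
    list(
      type = "phase", bandwidth = model@bandwidth,
      nGrid = length(model@grid), spikePrior = model@spikePrior,
      density = model@density
    )
  } else if (is(model, "CombinedGLM")) {
    list(
      type = paste0("phase", model@historyKind),
      historyKind = model@historyKind,
      coefficients = list(beta0 = model@beta0, betaHist = model@betaHist,
                          betaPhase = model@betaPhase)
    )
  } else {
    stop("unsupported model class: ", class(model))
  }
  obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(obj)
}

#' Read a model written by [saveModelJSON()]
#'
#' @param path JSON path.
#' @return the reconstructed model object.
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    history = new("FittedGLM",
      coefficients = obj$coefficients, kind = obj$kind,
      order = as.integer(obj$order), lambda = obj$lambda,
      penalizeIntercept = obj$penalizeIntercept, nnll = obj$nnll,
      converged = TRUE, gradientNorm = NA_real_
    ),
    phase = new("PhaseEstimator",
      spikePhases = numeric(0), bandwidth = obj$bandwidth,
      grid = kdeGrid(as.integer(obj$nGrid)), density = obj$density,
      spikePrior = obj$spikePrior
    ),
    phaseSH = ,
    phaseLH = {
      cf <- unlist(obj$coefficients)
      new("CombinedGLM",
        beta0 = unname(cf[["beta0"]]),
        betaHist = unname(cf[["betaHist"]]),
        betaPhase = unname(cf[["betaPhase"]]),
        historyKind = obj$historyKind, diagnostics = list()
      )
    },
    stop("unknown model type in ", path)
  )
}
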