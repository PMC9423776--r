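#' Analysis configuration with protocol defaults
#'
#' Collects every tunable constant of the analysis protocol in one place:
#' 1 kHz sampling, 3 ms short history, 250 ms long history, L2 strength 1,
#' theta and low-gamma bands, a 20-candidate kernel bandwidth grid spanning
#' 6-40% of a cycle (FWHM), fivefold KDE cross-validation, 20 train-test
#' splits at 50% training, split-level alpha 0.001 (one-tailed), 50 ms
#' windows at base alpha 0.001 (Bonferroni-corrected by the window count),
#' and 100 phase permutations.
#'
#' @param ... overrides of the defaults (unknown keys are an error).
#' @return a `RunConfig` list.
#' @examples
#' cfg <- runConfig(nSplits = 10)
#' cfg$lambda
#' @export
runConfig <- function(...) {
  cfg <- list(
    fs = 1000,
    historyShort = 3L,
    historyLong = 250L,
    lambda = 1,
    bands = list(theta = c(4, 12), low_gamma = c(35, 55)),
    filterOrder = 3L,
    bwN = 20L, bwFrom = 0.06, bwTo = 0.40, bwUnit = "fwhm_fraction",
    cv = "kfold", nFolds = 5L,
    nSplits = 20L, trainFraction = 0.5,
    alphaSplit = 0.001, splitTail = "one",
    windowMs = 50L, alphaWindowedBase = 0.001,
    nPerm = 100L,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = "RunConfig")
}

#' @rdname runConfig
#' @param cfg a `RunConfig`.
#' @param path file path.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, raw)
}

#' Bandwidth grid from a RunConfig
#' @param cfg a [runConfig()].
#' @return sigma grid, see [bandwidthGrid()].
#' @export
configBandwidthGrid <- function(cfg) {
  bandwidthGrid(cfg$bwN, cfg$bwFrom, cfg$bwTo, unit = cfg$bwUnit)
}
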