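## Circular KDE of p(phi | spike) on a fixed grid over [-pi, pi).
##
## The distribution of spike phases is linearly binned on the grid and
## circularly convolved with a Gaussian kernel wrapped across +/-pi (the
## triple-copy construction: kernel mass at offsets d, d - 2pi, d + 2pi).
## The kernel is renormalized to unit quadrature mass, so the estimate
## integrates to exactly 1 over one cycle on the grid.

kdeGrid <- function(nGrid = 1000L) {
  -pi + 2 * pi * (seq_len(nGrid) - 1L) / nGrid
}

## linear binning of phases onto the circular grid; returns weights
binPhases <- function(phi, nGrid) {
  delta <- 2 * pi / nGrid
  u <- (phi + pi) / delta
  i0 <- floor(u)
  frac <- u - i0
  i0 <- (i0 %% nGrid) + 1L
  i1 <- (i0 %% nGrid) + 1L
  agg <- rowsum(c(1 - frac, frac), group = c(i0, i1))
  w <- numeric(nGrid)
  w[as.integer(rownames(agg))] <- agg[, 1L]
  w
}

## wrapped Gaussian kernel sampled on grid offsets, unit quadrature mass
wrappedKernel <- function(sigma, nGrid) {
  delta <- 2 * pi / nGrid
  d <- wrapPhase(delta * (seq_len(nGrid) - 1L))
  k <- stats::dnorm(d, 0, sigma) +
    stats::dnorm(d - 2 * pi, 0, sigma) +
    stats::dnorm(d + 2 * pi, 0, sigma)
  k / (sum(k) * delta)
}

circularConvolve <- function(w, k) {
  n <- length(w)
  pmax(Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / n, 0)
}

## linear interpolation on the circular grid
interpCircular <- function(grid, values, phi) {
  nGrid <- length(grid)
  delta <- 2 * pi / nGrid
  u <- (phi + pi) / delta
  i0 <- floor(u)
  frac <- u - i0
  i0 <- (i0 %% nGrid) + 1L
  i1 <- (i0 %% nGrid) + 1L
  values[i0] * (1 - frac) + values[i1] * frac
}

#' Candidate kernel bandwidth grid
#'
#' Twenty log-spaced kernel widths from 6% to 40% of a phase cycle,
#' specified as the full width at half maximum (FWHM) of the Gaussian
#' kernel and converted to the kernel standard deviation
#' `sigma = FWHM / (2 sqrt(2 ln 2))`. Pass `unit = "sigma"` to interpret
#' `from`/`to` directly as standard deviations in radians.
#'
#' @param nBandwidths number of candidates (default 20).
#' @param from,to grid limits as cycle fractions at kernel half maximum
#'   (defaults 0.06 and 0.40), or as sigma in radians when
#'   `unit = "sigma"`.
#' @param unit `"fwhm_fraction"` (default) or `"sigma"`.
#' @return ascending numeric vector of kernel standard deviations (radians).
#' @examples
#' range(bandwidthGrid())  # ~0.16 to ~1.07 rad
#' @export
bandwidthGrid <- function(nBandwidths = 20L, from = 0.06, to = 0.40,
                          unit = c("fwhm_fraction", "sigma")) {
  unit <- match.arg(unit)
  g <- exp(seq(log(from), log(to), length.out = nBandwidths))
  if (unit == "fwhm_fraction") {
    g <- g * 2 * pi / (2 * sqrt(2 * log(2)))
  }
  g
}

#' Estimate the circular likelihood p(phi | spike)
#'
#' Kernel density estimate of the distribution of phases at spike times,
#' smoothed with a Gaussian kernel of standard deviation `bandwidth` that is
#' wrapped across the phase seam at +/-pi (equivalently: the spike-phase
#' distribution is repeated at offsets of +/-2 pi, convolved, and
#' renormalized to a single copy). Evaluated on a fixed `nGrid`-point grid
#' over `[-pi, pi)`; arbitrary phases are read off by circular linear
#' interpolation.
#'
#' @param spikePhases phases (radians) co-occurring with spikes; at least 2.
#' @param bandwidth Gaussian kernel standard deviation in radians.
#' @param spikePrior optional training-set `p(spike)` to store for
#'   [posteriorSpikeGivenPhase()].
#' @param nGrid grid resolution (default 1000).
#' @return a [PhaseEstimator-class].
#' @examples
#' est <- estimatePhaseLikelihood(runif(500, -pi, pi), bandwidth = 0.5,
#'                                spikePrior = 0.006)
#' sum(est@density) * 2 * pi / 1000  # integrates to 1
#' @export
estimatePhaseLikelihood <- function(spikePhases, bandwidth,
                                    spikePrior = NA_real_, nGrid = 1000L) {
  spikePhases <- as.numeric(spikePhases)
  if (length(spikePhases) < 2L) {
    stop("at least 2 spike phases are required for the KDE")
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive")
  }
  spikePhases <- wrapPhase(spikePhases)
  w <- binPhases(spikePhases, nGrid)
  f <- circularConvolve(w / length(spikePhases), wrappedKernel(bandwidth, nGrid))
  new("PhaseEstimator",
    spikePhases = spikePhases, bandwidth = bandwidth,
    grid = kdeGrid(nGrid), density = f, spikePrior = spikePrior
  )
}

setMethod("show", "PhaseEstimator", function(object) {
  cat(sprintf(
    "PhaseEstimator: %d spike phases, sigma %.4f rad (FWHM %.1f%% of a cycle), prior %.5g\n",
    length(object@spikePhases), object@bandwidth,
    100 * object@bandwidth * 2 * sqrt(2 * log(2)) / (2 * pi),
    object@spikePrior
  ))
})

#' Evaluate a phase estimator's likelihood at arbitrary phases
#'
#' @param est a [PhaseEstimator-class].
#' @param phi phases in radians (any range; wrapped internally).
#' @return likelihood values `p(phi | spike)`.
#' @export
phaseLikelihood <- function(est, phi) {
  stopifnot(is(est, "PhaseEstimator"))
  interpCircular(est@grid, est@density, wrapPhase(as.numeric(phi)))
}

#' Cross-validated kernel bandwidth selection
#'
#' Splits the spike phases into folds, fits the KDE on each training fold at
#' every candidate bandwidth, and scores the mean log likelihood of the
#' held-out phases; the bandwidth maximizing the mean held-out log
#' likelihood is returned, ties broken toward the larger (smoother)
#' bandwidth. Fivefold CV is the default; `cv = "loo"` gives leave-one-out,
#' intended for sparse spike trains.
#'
#' @param spikePhases spike phases in radians.
#' @param grid ascending candidate bandwidths (sigma, radians); default
#'   [bandwidthGrid()].
#' @param cv `"kfold"` (default, 5 folds) or `"loo"`.
#' @param nFolds fold count for `cv = "kfold"`.
#' @param seed seed for fold assignment.
#' @return the selected bandwidth (scalar), with attribute `"scores"`
#'   holding the per-candidate mean held-out log likelihoods.
#' @export
selectBandwidth <- function(spikePhases, grid = bandwidthGrid(),
                            cv = c("kfold", "loo"), nFolds = 5L, seed = 1L) {
  cv <- match.arg(cv)
  if (length(grid) == 0L) stop("empty bandwidth grid")
  grid <- sort(grid)
  n <- length(spikePhases)
  if (cv == "loo") nFolds <- n
  if (n < max(2L, nFolds)) {
    stop(sprintf(
      "too few spikes (%d) for %d-fold CV; consider cv = \"loo\"", n, nFolds
    ))
  }
  folds <- withSeed(seed, sample(rep_len(seq_len(nFolds), n)))
  scores <- vapply(grid, function(bw) {
    ll <- vapply(seq_len(nFolds), function(f) {
      train <- spikePhases[folds != f]
      held <- spikePhases[folds == f]
      if (length(train) < 2L || length(held) == 0L) return(NA_real_)
      est <- estimatePhaseLikelihood(train, bw)
      mean(log(pmax(phaseLikelihood(est, held), 1e-12)))
    }, numeric(1))
    mean(ll, na.rm = TRUE)
  }, numeric(1))
  best <- max(which(scores >= max(scores) - 1e-12))
  structure(grid[best], scores = scores)
}

#' Bayes posterior probability of spiking given phase
#'
#' Applies `p(spike | phi) = p(phi | spike) p(spike) / p(phi)` with a
#' uniform phase prior `p(phi) = 1 / (2 pi)`, i.e.
#' `p_i = likelihood(phi_i) * spikePrior * 2 pi`, clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param est a fitted [PhaseEstimator-class] whose `spikePrior` is set.
#' @param phase numeric vector or matrix of phases.
#' @return spike probabilities, same shape as `phase`.
#' @export
posteriorSpikeGivenPhase <- function(est, phase) {
  stopifnot(is(est, "PhaseEstimator"))
  if (!is.finite(est@spikePrior)) {
    stop("estimator has no spike prior; fit it with fitPhaseModel() ",
         "or set spikePrior in estimatePhaseLikelihood()")
  }
  p <- clipProb(phaseLikelihood(est, phase) * est@spikePrior * 2 * pi)
  if (is.matrix(phase)) p <- matrix(p, nrow(phase), ncol(phase))
  p
}

#' Fit the phase model on a training TrialSet
#'
#' Collects the phases at spike times within the target region, selects the
#' kernel bandwidth by cross-validation, and builds the
#' [PhaseEstimator-class] with the training spike prior (spikes divided by
#' target-region samples).
#'
#' @param trials a [TrialSet-class] with phase, typically the training
#'   trials of a split.
#' @param grid candidate bandwidths; default [bandwidthGrid()].
#' @param cv,nFolds,seed passed to [selectBandwidth()].
#' @param bandwidth optional fixed bandwidth, skipping CV.
#' @return a fitted [PhaseEstimator-class].
#' @export
fitPhaseModel <- function(trials, grid = bandwidthGrid(),
                          cv = c("kfold", "loo"), nFolds = 5L, seed = 1L,
                          bandwidth = NULL) {
  cv <- match.arg(cv)
  ph <- phaseMatrix(trials)
  if (is.null(ph)) stop("TrialSet has no phase matrix")
  tm <- targetMask(trials)
  sp <- spikes(trials)
  spikePhases <- ph[tm & sp == 1]
  prior <- sum(sp[tm]) / sum(tm)
  if (prior <= 0 || prior >= 1) {
    stop("spike prior must lie in (0, 1); the training set has ",
         sum(sp[tm]), " spikes in ", sum(tm), " target samples")
  }
  if (is.null(bandwidth)) {
    bandwidth <- selectBandwidth(spikePhases, grid, cv = cv,
                                 nFolds = nFolds, seed = seed)
  }
  estimatePhaseLikelihood(spikePhases, as.numeric(bandwidth),
                          spikePrior = prior)
}

#' Evaluate the phase model on held-out trials
#'
#' Predictions for the held-out trials use the TRAINING likelihood and
#' TRAINING spike prior applied to the held-out phase series, so no
#' information from the held-out spikes enters the model.
#'
#' @param est a fitted [PhaseEstimator-class] (from the training split).
#' @param testTrials a [TrialSet-class] carrying phase.
#' @return list: `prob` (predicted spike probability over target-region
#'   samples, trial-major) and `logLoss` (bits/sample, [logLoss()]).
#' @export
evaluatePhaseModel <- function(est, testTrials) {
  ph <- phaseMatrix(testTrials)
  if (is.null(ph)) stop("test trials carry no phase matrix")
  tm <- targetMask(testTrials)
  phi <- as.vector(t(ph))[as.vector(t(tm))]
  y <- as.vector(t(spikes(testTrials)))[as.vector(t(tm))]
  p <- posteriorSpikeGivenPhase(est, phi)
  list(prob = p, logLoss = logLoss(y, p))
}
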