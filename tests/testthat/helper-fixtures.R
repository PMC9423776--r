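## Shared, lazily built fixtures (cached per test run).

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

## one simulated train per kind at study-default parameters
simTrain <- function(kind, seed = 101L) {
  cached(paste0("train_", kind, "_", seed), function() {
    sampleSpikes(makeGroundTruth(kind), seed = seed)
  })
}

## a tiny TrialSet with hand-set spikes
tinyTrials <- function(spikeRows, historyPrefix = 3L, phase = NULL) {
  TrialSet(do.call(rbind, spikeRows), phase = phase,
           historyPrefix = historyPrefix)
}

## independent oracle: literal triple-concatenated pointwise Gaussian KDE
kdeOracle <- function(spikePhases, sigma, phi) {
  vapply(phi, function(g) {
    mean(dnorm(g - spikePhases, 0, sigma) +
           dnorm(g - spikePhases - 2 * pi, 0, sigma) +
           dnorm(g - spikePhases + 2 * pi, 0, sigma))
  }, numeric(1))
}

## independent oracle: NNLL of a logistic model (natural log, normalized)
nnllOracle <- function(beta, X, y) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  mean(-y * eta + log(1 + exp(eta)))
}

## von Mises sampler (rejection, seeded) -- avoids any package dependency
rVonMises <- function(n, mu, kappa, seed) {
  out <- numeric(0)
  set.seed(seed)
  while (length(out) < n) {
    phi <- runif(2 * n, -pi, pi)
    u <- runif(2 * n)
    acc <- u < exp(kappa * (cos(phi - mu) - 1))
    out <- c(out, phi[acc])
  }
  out[seq_len(n)]
}
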