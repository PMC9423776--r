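test_that("likelihood integrates to 1 and matches the pointwise oracle", {
  set.seed(31)
  for (case in list(
    list(phi = runif(500, -pi, pi), bw = 0.3),
    list(phi = rVonMises(300, 1, 3, seed = 4), bw = 0.8),
    list(phi = c(-3, -1, 0, 2, 3), bw = 0.17)
  )) {
    est <- estimatePhaseLikelihood(case$phi, case$bw)
    expect_equal(sum(est@density) * 2 * pi / 1000, 1, tolerance = 1e-6)
    ## independent oracle: literal triple-concatenated Gaussian KDE
    at <- seq(-pi, pi - 0.01, length.out = 25)
    expect_equal(phaseLikelihood(est, at), kdeOracle(case$phi, case$bw, at),
                 tolerance = 2e-3)
  }
  expect_error(estimatePhaseLikelihood(1.2, 0.3), "at least 2")
  expect_error(estimatePhaseLikelihood(c(1, 2), -1), "positive")
})

test_that("a large uniform sample yields a nearly flat likelihood", {
  set.seed(32)
  est <- estimatePhaseLikelihood(runif(10000, -pi, pi), bandwidth = 0.5)
  expect_true(all(abs(est@density - 1 / (2 * pi)) < 0.05 / (2 * pi)))
})

test_that("the mode of a von Mises sample is recovered", {
  phi <- rVonMises(10000, 0, 2, seed = 33)
  est <- estimatePhaseLikelihood(phi, bandwidth = 0.2)
  expect_lt(abs(est@grid[which.max(est@density)]), 0.1)
})

test_that("the estimate is continuous across the +/-pi seam", {
  set.seed(34)
  phi <- wrapPhase(rnorm(400, pi - 0.01, 0.05))
  est <- estimatePhaseLikelihood(phi, bandwidth = 0.15)
  left <- phaseLikelihood(est, pi - 0.02)
  right <- phaseLikelihood(est, -pi + 0.02)
  expect_equal(right / left, 1, tolerance = 0.1)
  expect_gt(left, 1)  # real mass near the seam
})

test_that("cross-validated bandwidth adapts to structure and sample size", {
  grid <- bandwidthGrid()
  ## held-out likelihood CV is a density-estimation selector: its optimum
  ## shrinks as the sample grows (~n^(-1/5)), so a peaked von Mises sample
  ## selects progressively narrower kernels
  phi <- rVonMises(10000, 0, 2, seed = 35)
  bwSmall <- selectBandwidth(phi[1:200], grid, seed = 5)
  bwBig <- selectBandwidth(phi, grid, seed = 5)
  expect_lte(bwBig, bwSmall)
  ## and the big-sample selection sits in the narrow half of the grid
  expect_lte(which(grid == bwBig), 10)

  ## the selected bandwidth beats gross over/undersmoothing on fresh data
  fresh <- rVonMises(2000, 0, 2, seed = 99)
  heldOutLL <- function(bw) {
    est <- estimatePhaseLikelihood(phi, bw)
    mean(log(pmax(phaseLikelihood(est, fresh), 1e-12)))
  }
  expect_gte(heldOutLL(bwBig), heldOutLL(max(grid)) - 1e-9)

  ## uniform phases: smoothest quartile is optimal
  set.seed(36)
  bwU <- selectBandwidth(runif(4000, -pi, pi), grid, seed = 6)
  expect_gte(which(grid == bwU), 15)

  expect_equal(selectBandwidth(phi[1:50], grid = 0.4, seed = 1), 0.4,
               ignore_attr = TRUE)
  expect_error(selectBandwidth(phi[1:3], grid, cv = "kfold"), "loo")
  ## loo works on tiny samples
  expect_true(selectBandwidth(phi[1:4], grid, cv = "loo") %in% grid)
})

test_that("posterior applies Bayes' rule with a uniform phase prior", {
  ## exactly uniform likelihood: posterior equals the spike prior everywhere
  est <- new("PhaseEstimator",
    spikePhases = numeric(0), bandwidth = 0.3, grid = spikephase:::kdeGrid(),
    density = rep(1 / (2 * pi), 1000), spikePrior = 0.006
  )
  phi <- seq(-3, 3, by = 0.1)
  expect_equal(posteriorSpikeGivenPhase(est, phi), rep(0.006, length(phi)))

  ## linearity: doubling the likelihood doubles the posterior
  est2 <- est
  est2@density <- rep(2 / (2 * pi), 1000)
  expect_equal(posteriorSpikeGivenPhase(est2, 0.5), 0.012)

  ## unfitted prior is an error
  estNA <- est
  estNA@spikePrior <- NA_real_
  expect_error(posteriorSpikeGivenPhase(estNA, 0.5), "no spike prior")
})

test_that("posterior time-average over full cycles recovers the spike prior", {
  phi <- rVonMises(2000, 0.5, 2, seed = 37)
  est <- estimatePhaseLikelihood(phi, 0.4, spikePrior = 0.0061)
  sawtooth <- rep(-pi + 2 * pi * (0:124) / 125, 40)  # 40 full cycles
  expect_equal(mean(posteriorSpikeGivenPhase(est, sawtooth)), 0.0061,
               tolerance = 0.01)
})

test_that("posterior is equivariant under joint phase rotation", {
  phi <- rVonMises(800, 0, 2, seed = 38)
  testAt <- seq(-pi, pi - 0.01, length.out = 50)
  a <- estimatePhaseLikelihood(phi, 0.35, spikePrior = 0.006)
  ## offsets on the evaluation grid rotate the estimate exactly
  for (offset in (2 * pi / 1000) * c(111, -334)) {
    b <- estimatePhaseLikelihood(wrapPhase(phi + offset), 0.35,
                                 spikePrior = 0.006)
    expect_equal(
      posteriorSpikeGivenPhase(a, testAt),
      posteriorSpikeGivenPhase(b, wrapPhase(testAt + offset)),
      tolerance = 1e-9
    )
  }
  ## arbitrary offsets are equivariant up to the grid discretization
  b <- estimatePhaseLikelihood(wrapPhase(phi + 0.7), 0.35,
                               spikePrior = 0.006)
  expect_equal(
    posteriorSpikeGivenPhase(a, testAt),
    posteriorSpikeGivenPhase(b, wrapPhase(testAt + 0.7)),
    tolerance = 1e-2
  )
})

test_that("posterior modulation depth converges to the generative ratio", {
  kappa <- 1
  phi <- rVonMises(50000, 0, kappa, seed = 39)
  est <- estimatePhaseLikelihood(phi, bandwidth = 0.15, spikePrior = 0.006)
  ratio <- max(est@density) / min(est@density)
  expect_equal(ratio, exp(2 * kappa), tolerance = 0.1)
})

test_that("held-out phase-model evaluation uses only training information", {
  ts <- simTrain("nonrefractory_rhythmic")
  ss <- splits(makeSplits(nTrials(ts), seed = 2))[[1]]
  train <- ts[ss$train]
  test <- ts[ss$test]
  est <- fitPhaseModel(train, seed = 3)
  ## evaluating the training set reproduces the training log loss
  evTrain <- evaluatePhaseModel(est, train)
  tm <- targetMask(train)
  y <- as.vector(t(spikes(train)))[as.vector(t(tm))]
  expect_equal(evTrain$logLoss, logLoss(y, evTrain$prob))

  ## rhythmic trains: the phase model beats a flat Bernoulli(spike_prior)
  ## predictor on the same held-out spikes, paired across splits
  priorLoss <- function(est, testTS) {
    tm <- targetMask(testTS)
    yT <- as.vector(t(spikes(testTS)))[as.vector(t(tm))]
    logLoss(yT, rep(est@spikePrior, length(yT)))
  }
  diffs <- vapply(splits(makeSplits(nTrials(ts), nSplits = 6, seed = 2)),
    function(s) {
      e <- fitPhaseModel(ts[s$train], seed = 3)
      evaluatePhaseModel(e, ts[s$test])$logLoss - priorLoss(e, ts[s$test])
    }, numeric(1))
  expect_true(all(diffs < 0))

  ## atemporal trains: the phase model matches the flat predictor within 2%
  tsA <- simTrain("atemporal")
  estA <- fitPhaseModel(tsA[ss$train], seed = 3)
  evA <- evaluatePhaseModel(estA, tsA[ss$test])
  expect_equal(evA$logLoss, priorLoss(estA, tsA[ss$test]), tolerance = 0.02)

  expect_error(evaluatePhaseModel(est, TrialSet(matrix(0, 1, 300),
                                                historyPrefix = 100L)),
               "no phase")
})
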