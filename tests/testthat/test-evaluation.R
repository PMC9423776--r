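test_that("log loss matches closed forms", {
  expect_equal(logLoss(c(0, 1, 0, 1), rep(0.5, 4)), 1)
  expect_equal(logLoss(c(1, 0), c(0.75, 0.75)), 1.20752, tolerance = 1e-5)
  y <- c(1, 0, 1, 1, 0)
  expect_lt(logLoss(y, y), 1e-10)
  expect_error(logLoss(c(1, 0), 0.5), "equal length")
})

test_that("split-level comparison flags reliable differences only", {
  identical_ <- compareModels(rep(0.05, 20), rep(0.05, 20))
  expect_false(identical_@significant)
  expect_equal(identical_@pValue, 1)

  set.seed(51)
  a <- rnorm(20, 0.048, 0.001)
  cmp <- compareModels(a, a + 0.005, "phaseSH", "SH")
  expect_true(cmp@significant)
  expect_lt(cmp@pValue, 0.001)
  expect_equal(cmp@differences, rep(-0.005, 20))

  ## one-tailed: A worse than B is never significant
  worse <- compareModels(a + 0.005, a)
  expect_false(worse@significant)

  ## zero-variance nonzero differences: p = 0 sentinel with a note
  sentinel <- compareModels(rep(0.04, 5), rep(0.05, 5))
  expect_true(sentinel@significant)
  expect_equal(sentinel@pValue, 0)
  expect_match(sentinel@note, "zero-variance")

  expect_error(compareModels(0.1, 0.2), "at least 2")
})

test_that("the detection procedure separates rhythmic from non-rhythmic trains", {
  ## scaled-down replication: one train per type, 20 splits
  rhythmic <- detectPhaseLocking(simTrain("refractory_rhythmic"),
                                 makeSplits(48, seed = 8), seed = 9)
  expect_true(rhythmic@significant)
  atemporal <- detectPhaseLocking(simTrain("atemporal"),
                                  makeSplits(48, seed = 8), seed = 9)
  expect_false(atemporal@significant)
})

test_that("windowed comparison sizes windows and corrects alpha", {
  diffs <- matrix(rnorm(20 * 1250, 0, 1e-4), 20)
  wc <- windowedComparison(diffs, windowLen = 50)
  expect_equal(wc@nWindows, 25L)
  expect_equal(wc@bonferroniAlpha, 0.00004)
  expect_equal(dim(wc@diffMatrix), c(25, 20))

  ## comparing a model to itself: nothing significant
  selfCmp <- windowedComparison(matrix(0, 20, 1250), windowLen = 50)
  expect_false(any(selfCmp@significant))

  expect_error(windowedComparison(diffs, windowLen = 33), "not divisible")
})

test_that("overall difference equals the length-weighted window average", {
  set.seed(52)
  diffs <- matrix(rnorm(10 * 1250, 0, 1e-3), 10)
  wc <- windowedComparison(diffs, windowLen = 50)
  expect_equal(colMeans(wc@diffMatrix), rowMeans(diffs), tolerance = 1e-12)
})

test_that("windowed detection localizes a mid-trial onset of rhythm", {
  fx <- makeFixture("changepoint", seed = 53, nTrains = 1)
  ts <- fx$trains[[1]]
  ev <- evaluateModels(ts, makeSplits(nTrials(ts), seed = 10),
                       models = c("SH", "phase", "phaseSH"), seed = 11,
                       returnPerSample = TRUE)
  perDiff <- lapply(seq_len(20), function(s) {
    ev$perSample$phaseSH[[s]] - ev$perSample$SH[[s]]
  })
  wc <- windowedComparison(perDiff, windowLen = 50)
  sig <- which(wc@significant & wc@medianDiff < 0)
  expect_gt(length(sig), 0)
  ## change point at target sample 626 -> window 13 onward
  expect_gte(mean(sig >= 13), 0.8)
})

test_that("Rayleigh statistics match circular geometry", {
  aligned <- rayleighTest(rep(1.3, 25))
  expect_equal(aligned@r, 1)
  expect_equal(aligned@Z, 25)

  balanced <- rayleighTest(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(balanced@r, 0, tolerance = 1e-12)

  pair <- rayleighTest(c(0, pi / 2))
  expect_equal(pair@r, sqrt(0.5), tolerance = 1e-10)

  ## printed-variant compatibility flag
  expect_equal(rayleighTest(rep(1, 10), variant = "printed")@Z, 1 / 10)

  expect_error(rayleighTest(numeric(0)), "at least one")
})

test_that("Rayleigh p-value decreases in r at fixed eta and detects locking", {
  eta <- 40
  rs <- seq(0.05, 0.95, by = 0.1)
  ps <- vapply(rs, function(r) {
    R <- eta * r
    min(1, exp(sqrt(1 + 4 * eta + 4 * (eta^2 - R^2)) - (1 + 2 * eta)))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  ## spike phases from a rhythmic train reject uniformity
  ts <- simTrain("refractory_rhythmic")
  tm <- targetMask(ts)
  phases <- phaseMatrix(ts)[tm & spikes(ts) == 1]
  expect_lt(rayleighTest(phases)@p, 0.001)
  ## and an atemporal train does not
  tsA <- simTrain("atemporal")
  phasesA <- phaseMatrix(tsA)[targetMask(tsA) & spikes(tsA) == 1]
  expect_gt(rayleighTest(phasesA)@p, 0.001)
})

test_that("within-cycle permutation preserves each cycle's phase multiset", {
  ts <- simTrain("refractory_rhythmic")
  ph <- phaseMatrix(ts)[1:3, , drop = FALSE]
  perm <- permutePhaseWithinCycles(ph, seed = 12)
  expect_false(identical(perm, ph))
  for (tr in 1:3) {
    ids <- spikephase:::cycleIds(ph[tr, ])
    for (cyc in unique(ids)) {
      idx <- ids == cyc
      expect_equal(sort(perm[tr, idx]), sort(ph[tr, idx]))
    }
  }
})

test_that("permutation control separates intact rhythm from the null", {
  ## reduced-permutation smoke check; the full 100-permutation control runs
  ## in the acceptance suite
  ts <- simTrain("refractory_rhythmic")
  ctl <- phasePermutationControl(ts, nPerm = 15, seed = 13)
  expect_lt(ctl$intact, min(ctl$null))
  expect_equal(ctl$quantile, 0)
  expect_error(phasePermutationControl(ts, nPerm = 1), "at least 2")
})
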