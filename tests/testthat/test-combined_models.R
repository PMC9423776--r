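test_that("log-odds match closed forms and are antisymmetric", {
  expect_equal(logOdds(0.5), 0)
  expect_equal(logOdds(0.9), log(9), tolerance = 1e-10)
  p <- seq(0.1, 0.9, by = 0.1)
  expect_equal(logOdds(1 - p), -logOdds(p), tolerance = 1e-10)
  ## clipping keeps extreme probabilities finite
  expect_true(is.finite(logOdds(0)))
  expect_true(is.finite(logOdds(1)))
})

test_that("the combined fit recovers known generative coefficients", {
  set.seed(41)
  n <- 2e5
  lHist <- rnorm(n, -5, 1.2)
  lPhase <- rnorm(n, -5, 0.8)
  y <- rbinom(n, 1, plogis(1.0 * lHist + 0 * lPhase))
  fit <- fitCombined(lHist, lPhase, y)
  expect_equal(fit@beta0, 0, tolerance = 0.15)
  expect_equal(fit@betaHist, 1, tolerance = 0.1)
  expect_equal(fit@betaPhase, 0, tolerance = 0.1)
  ## and the fit is the exact MLE: it matches stats::glm to solver precision
  ref <- suppressWarnings(glm(y ~ lHist + lPhase, family = binomial()))
  expect_equal(c(fit@beta0, fit@betaHist, fit@betaPhase),
               unname(coef(ref)), tolerance = 1e-7)
})

test_that("a constant regressor is absorbed by the intercept", {
  set.seed(42)
  n <- 5e4
  lHist <- rnorm(n, -4, 1)
  y <- rbinom(n, 1, plogis(lHist))
  fit <- fitCombined(lHist, rep(-5.2, n), y)
  expect_equal(fit@betaPhase, 0)
  expect_equal(fit@betaHist, 1, tolerance = 0.15)
  ## predictions flow through the reported coefficients unchanged
  p <- predictCombined(fit, lHist, rep(-5.2, n))
  expect_true(all(p > 0 & p < 1))
})

test_that("refitting on the combined model's own log-odds is idempotent", {
  set.seed(43)
  n <- 5e4
  l <- rnorm(n, -4.5, 1)
  y <- rbinom(n, 1, plogis(l))
  first <- fitCombined(l, rep(0, n), y)
  pOwn <- predictCombined(first, l, rep(0, n))
  second <- fitCombined(logOdds(pOwn), rep(0, n), y)
  expect_equal(second@beta0, 0, tolerance = 0.02)
  expect_equal(second@betaHist, 1, tolerance = 0.02)
})

test_that("prediction identities hold for unit coefficient vectors", {
  lHist <- logOdds(c(0.01, 0.2, 0.5, 0.9))
  lPhase <- logOdds(c(0.3, 0.05, 0.6, 0.2))
  mk <- function(b0, bh, bp) new("CombinedGLM",
    beta0 = b0, betaHist = bh, betaPhase = bp,
    historyKind = "SH", diagnostics = list()
  )
  expect_equal(predictCombined(mk(0, 1, 0), lHist, lPhase),
               c(0.01, 0.2, 0.5, 0.9), tolerance = 1e-12)
  expect_equal(predictCombined(mk(0, 0, 1), lHist, lPhase),
               c(0.3, 0.05, 0.6, 0.2), tolerance = 1e-12)
  l <- logOdds(c(0.1, 0.4, 0.8))
  expect_equal(predictCombined(mk(0, 0.5, 0.5), l, l), plogis(l))
  expect_error(predictCombined(mk(0, 1, 0), c(1, NaN), c(0, 0)),
               "sample 2")
})

test_that("collinear regressors are flagged", {
  set.seed(44)
  l <- rnorm(1000, -3, 1)
  y <- rbinom(1000, 1, plogis(l))
  expect_warning(fitCombined(l, l + 1e-12, y), "collinear")
})

test_that("phaseSH captures refractoriness and rhythm together", {
  ts <- simTrain("refractory_rhythmic")
  sp <- splits(makeSplits(nTrials(ts), seed = 4))[[1]]
  res <- fitSplitModels(ts, sp, models = c("SH", "phase", "phaseSH"),
                        seed = 5)
  p <- res$testPred$phaseSH
  test <- ts[sp$test]
  d <- buildHistoryDesign(test, 3)
  afterSpike <- Matrix::rowSums(d$X) > 0
  ## within 3 ms of a spike the prediction is suppressed
  expect_lt(max(p[afterSpike]), 0.01)
  ## away from refractoriness, cycle peaks exceed the mean rate
  prior <- mean(res$fits$phase@spikePrior)
  expect_gt(max(p[!afterSpike]), prior)
})

test_that("on atemporal trains phaseSH costs almost nothing relative to SH", {
  ts <- simTrain("atemporal")
  ev <- evaluateModels(ts, makeSplits(nTrials(ts), nSplits = 10, seed = 6),
                       models = c("SH", "phase", "phaseSH"), seed = 7)
  meanExcess <- mean(ev$logLoss[, "phaseSH"] - ev$logLoss[, "SH"])
  expect_lt(meanExcess, 0.002)
})
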