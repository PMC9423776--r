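test_that("history design rows hold the lagged spikes of the same trial", {
  ts <- tinyTrials(list(c(0, 0, 1, 0, 0, 0)), historyPrefix = 3L)
  d <- buildHistoryDesign(ts, 3)
  expect_equal(unname(as.matrix(d$X)),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(d$y, c(0, 0, 0))
  expect_equal(d$sample, 4:6)

  ## all-zero train: all-zero design
  z <- buildHistoryDesign(tinyTrials(list(rep(0, 6))), 3)
  expect_equal(sum(z$X), 0)
  expect_equal(sum(z$y), 0)

  ## row count: n_trials x (n_samples - prefix)
  ts2 <- TrialSet(matrix(0, 5, 100), historyPrefix = 20L)
  expect_equal(nrow(buildHistoryDesign(ts2, 10)$X), 5 * 80)

  expect_error(buildHistoryDesign(ts2, 21), "exceeds the history prefix")
})

test_that("history never crosses trial boundaries", {
  ## trial 1 ends with a spike; trial 2 must not see it
  ts <- tinyTrials(list(c(0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, 0)),
                   historyPrefix = 3L)
  d <- buildHistoryDesign(ts, 3)
  expect_equal(sum(as.matrix(d$X)[4:6, ]), 0)
})

test_that("designSubset equals building the design on the subset", {
  ts <- simTrain("refractory_rhythmic")
  full <- buildHistoryDesign(ts, 3)
  idx <- c(2, 5, 11)
  sub <- designSubset(full, idx)
  direct <- buildHistoryDesign(ts[idx], 3)
  expect_equal(as.matrix(sub$X), as.matrix(direct$X))
  expect_equal(sub$y, direct$y)
})

test_that("intercept-only fit equals the closed-form Bernoulli logit", {
  ts <- tinyTrials(list(rep(c(1, 0, 0, 0), 50)), historyPrefix = 0L)
  d <- buildHistoryDesign(ts, 0)
  fit <- fitHistoryGLM(d)
  expect_equal(coef(fit), log(0.25 / 0.75), tolerance = 1e-6)
})

test_that("fitted coefficients match a brute-force NNLL grid search", {
  set.seed(14)
  x <- rbinom(200, 1, 0.3)
  eta <- -1 + 1.5 * x
  y <- rbinom(200, 1, plogis(eta))
  ts <- TrialSet(matrix(y, 1), historyPrefix = 0L)
  d <- buildHistoryDesign(ts, 0)
  d$X <- Matrix::Matrix(matrix(x, ncol = 1), sparse = TRUE)
  d$order <- 1L
  fit <- fitHistoryGLM(d, kind = "custom")

  ## oracle: exhaustive grid at step 1e-3 around a coarse optimum
  grid1 <- seq(-3, 3, by = 0.05)
  coarse <- expand.grid(b0 = grid1, b1 = grid1)
  vals <- mapply(function(b0, b1) nnllOracle(c(b0, b1), x, y),
                 coarse$b0, coarse$b1)
  c0 <- coarse[which.min(vals), ]
  fine <- expand.grid(b0 = seq(c0$b0 - 0.06, c0$b0 + 0.06, by = 1e-3),
                      b1 = seq(c0$b1 - 0.06, c0$b1 + 0.06, by = 1e-3))
  valsF <- mapply(function(b0, b1) nnllOracle(c(b0, b1), x, y),
                  fine$b0, fine$b1)
  best <- fine[which.min(valsF), ]
  expect_equal(coef(fit)[1], best$b0, tolerance = 2e-3)
  expect_equal(coef(fit)[2], best$b1, tolerance = 2e-3)
})

test_that("unpenalized fits agree with stats::glm", {
  ## well-conditioned dense toy: coefficients must match glm tightly
  set.seed(61)
  n <- 5000
  x1 <- rbinom(n, 1, 0.3)
  x2 <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x1 - 0.5 * x2))
  d <- structure(list(
    X = Matrix::Matrix(cbind(x1, x2), sparse = TRUE), y = y, order = 2L,
    trial = rep(1L, n), sample = seq_len(n), historyPrefix = 0L
  ), class = "HistoryDesign")
  fit <- fitHistoryGLM(d, kind = "custom")
  ref <- suppressWarnings(
    glm.fit(cbind(1, x1, x2), y, family = binomial())
  )
  expect_equal(coef(fit), unname(ref$coefficients), tolerance = 1e-6)
  ## on a quasi-separated refractory train the PREDICTIONS must still agree
  dr <- buildHistoryDesign(simTrain("refractory_rhythmic")[1:10], 3)
  fitR <- fitHistoryGLM(dr)
  refR <- suppressWarnings(
    glm.fit(cbind(1, as.matrix(dr$X)), dr$y, family = binomial())
  )
  expect_equal(predictHistory(fitR, dr),
               unname(plogis(as.numeric(cbind(1, as.matrix(dr$X)) %*%
                                          refR$coefficients))),
               tolerance = 1e-5)
})

test_that("SH model learns the refractory structure", {
  ts <- simTrain("refractory_rhythmic")
  d <- buildHistoryDesign(ts, 3)
  fit <- fitHistoryGLM(d)
  b <- coef(fit)
  ## p(spike | spike 1 ms ago)
  expect_lt(plogis(b[1] + b[2]), 0.001)
  ## baseline between spikes stays near the firing rate
  expect_equal(plogis(b[1]), 0.006, tolerance = 0.5)
})

test_that("degenerate targets and complete separation are refused", {
  allZero <- tinyTrials(list(rep(0, 20)), historyPrefix = 2L)
  expect_error(fitHistoryGLM(buildHistoryDesign(allZero, 2)),
               "targets are all 0")
  ## complete separation: y perfectly determined by the regressor
  x <- rep(c(0, 1), each = 50)
  d <- structure(list(
    X = Matrix::Matrix(matrix(x, ncol = 1), sparse = TRUE),
    y = x, order = 1L, trial = rep(1L, 100), sample = 1:100,
    historyPrefix = 0L
  ), class = "HistoryDesign")
  expect_error(fitHistoryGLM(d, kind = "custom"), "separation")
  ## ... but an L2 penalty makes it well-posed
  expect_s4_class(fitHistoryGLM(d, lambda = 0.1, kind = "custom"),
                  "FittedGLM")
})

test_that("L2 coefficient magnitudes shrink monotonically in lambda", {
  ts <- simTrain("refractory_rhythmic")
  d <- buildHistoryDesign(ts[1:12], 250)
  norms <- vapply(c(0.1, 1, 10), function(lam) {
    sum(coef(fitHistoryGLM(d, lambda = lam))[-1]^2)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("fitted NNLL never exceeds the intercept-only NNLL (nesting)", {
  ts <- simTrain("refractory_rhythmic")
  d <- buildHistoryDesign(ts[1:8], 3)
  fit <- fitHistoryGLM(d)
  p0 <- mean(d$y)
  nnll0 <- -mean(d$y * log(p0) + (1 - d$y) * log(1 - p0))
  expect_lte(fit@nnll, nnll0)
})

test_that("predictions are exact logistic transforms and behave monotonically", {
  ts <- simTrain("refractory_rhythmic")
  d <- buildHistoryDesign(ts[1:6], 3)
  fit <- fitHistoryGLM(d)
  p <- predictHistory(fit, d)
  expect_true(all(p > 0 & p < 1))
  ## zero-history rows predict plogis(beta0) exactly
  zeroRows <- Matrix::rowSums(d$X) == 0
  expect_equal(unique(p[zeroRows]), plogis(coef(fit)[1]))
  ## raising beta0 raises every prediction
  up <- fit
  up@coefficients[1] <- up@coefficients[1] + 1
  expect_true(all(predictHistory(up, d) > p))
  ## appending zero-coefficient dummy lags leaves predictions unchanged
  d5 <- buildHistoryDesign(ts[1:6], 5)
  ext <- new("FittedGLM",
    coefficients = c(coef(fit), 0, 0), kind = "custom", order = 5L,
    lambda = 0, penalizeIntercept = FALSE, nnll = fit@nnll,
    converged = TRUE, gradientNorm = 0
  )
  expect_equal(predictHistory(ext, d5), p, tolerance = 1e-12)
  expect_error(predictHistory(fit, d5), "does not match")
})

test_that("SH predictions on atemporal trains are near-constant", {
  ts <- simTrain("atemporal")
  d <- buildHistoryDesign(ts, 3)
  p <- predictHistory(fitHistoryGLM(d), d)
  expect_lt(max(p) - min(p), 0.01)
})
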