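#' Deterministic test and demo fixtures
#'
#' Generates small, seeded datasets that emulate the recorded-data trial
#' structure (48 trials x 1,500 ms at 1 kHz, 250 ms history prefix, ~6 Hz
#' rates). Scenarios:
#' \describe{
#'   \item{`fig2_small`}{`nTrains` spike trains per ground-truth kind at the
#'     simulation-study parameters (reduced train count); each train is a
#'     [sampleSpikes()] TrialSet with exact sawtooth phase.}
#'   \item{`lfp_noise`}{spike trains coupled (von Mises, `kappa`) to the
#'     8 Hz component of a synthesized LFP — an 8 Hz and a 45 Hz sinusoid
#'     plus white noise, with per-trial random phase offsets. The TrialSet
#'     carries the raw LFP and no phase: the full
#'     filter-Hilbert-KDE pipeline must recover the coupling.}
#'   \item{`changepoint`}{refractory trains whose rhythmic modulation is
#'     present only in the second half of each trial's target region
#'     (constant rate in the first half), for exercising
#'     [windowedComparison()].}
#' }
#'
#' @param scenario fixture name.
#' @param seed integer seed; outputs are fully determined by the spec.
#' @param nTrains trains per kind (`fig2_small`) or total (others).
#' @param nTrials,nSamples trial grid (defaults 48 x 1500).
#' @param rateHz mean firing rate (default 6).
#' @param kappa von Mises concentration (default 2).
#' @param amp8,amp45,noiseSd LFP synthesis amplitudes for `lfp_noise`.
#' @param out optional directory; when given, each train's spikes (and LFP
#'   and ground-truth probability, where present) are written as wide CSV.
#' @return list with elements `scenario`, `trains` (list of
#'   [TrialSet-class]), `groundTruths` (list of [GroundTruth-class] or
#'   NULL), and `kinds` (character per train).
#' @export
makeFixture <- function(scenario = c("fig2_small", "lfp_noise", "changepoint"),
                        seed = 1L, nTrains = 10L, nTrials = 48L,
                        nSamples = 1500L, rateHz = 6, kappa = 2,
                        amp8 = 1, amp45 = 0.5, noiseSd = 0.5, out = NULL) {
  scenario <- match.arg(scenario)
  fs <- 1000
  res <- switch(scenario,
    fig2_small = {
      trains <- list()
      gts <- list()
      kinds <- character(0)
      i <- 0L
      for (kind in groundTruthKinds) {
        gt <- makeGroundTruth(kind, nTrials = nTrials, nSamples = nSamples,
                              baseRate = rateHz, kappa = kappa, fs = fs)
        for (k in seq_len(nTrains)) {
          i <- i + 1L
          trains[[i]] <- sampleSpikes(gt, seed = childSeed(seed, i))
          gts[[i]] <- gt
          kinds[i] <- kind
        }
      }
      list(trains = trains, groundTruths = gts, kinds = kinds)
    },
    lfp_noise = {
      t <- (seq_len(nSamples) - 1L) / fs
      trains <- lapply(seq_len(nTrains), function(k) {
        withSeed(childSeed(seed, k), {
          theta <- runif(nTrials, -pi, pi)
          theta45 <- runif(nTrials, -pi, pi)
          truePhase <- t(vapply(theta, function(th) {
            wrapPhase(2 * pi * 8 * t + th)
          }, numeric(nSamples)))
          lfp <- t(vapply(seq_len(nTrials), function(tr) {
            amp8 * cos(2 * pi * 8 * t + theta[tr]) +
              amp45 * cos(2 * pi * 45 * t + theta45[tr]) +
              stats::rnorm(nSamples, 0, noiseSd)
          }, numeric(nSamples)))
          prob <- (rateHz / fs) * 2 * pi * dVonMises(truePhase, kappa)
          gt <- new("GroundTruth",
            kind = "refractory_rhythmic", baseRate = rateHz,
            cycleLen = 125L, kappa = kappa, refractoryLen = 3L,
            refractoryFloor = 1e-5, prob = prob, phase = truePhase, fs = fs
          )
          ts <- sampleSpikes(gt, seed = childSeed(seed, 1000L + k))
          ts@lfp <- lfp
          ts@phase <- NULL
          ts@metadata$truePhase <- truePhase
          validObject(ts)
          ts
        })
      })
      list(trains = trains, groundTruths = NULL,
           kinds = rep("lfp_coupled", nTrains))
    },
    changepoint = {
      half <- 250L + (nSamples - 250L) %/% 2L
      trains <- lapply(seq_len(nTrains), function(k) {
        gt <- makeGroundTruth("refractory_rhythmic", nTrials = nTrials,
                              nSamples = nSamples, baseRate = rateHz,
                              kappa = kappa, fs = fs)
        gt@prob[, seq_len(half)] <- rateHz / fs
        sampleSpikes(gt, seed = childSeed(seed, 2000L + k))
      })
      list(trains = trains, groundTruths = NULL,
           kinds = rep("changepoint", nTrains),
           changeSample = half + 1L)
    }
  )
  res$scenario <- scenario
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(res$trains)) {
      base <- file.path(out, sprintf("%s_train%03d", scenario, i))
      ts <- res$trains[[i]]
      saveTrials(ts, paste0(base, "_spikes.csv"),
                 lfpPath = paste0(base, "_lfp.csv"))
      if (!is.null(ts@metadata$effProb)) {
        write.table(ts@metadata$effProb, paste0(base, "_prob.csv"),
                    sep = ",", row.names = FALSE, col.names = FALSE)
      }
    }
  }
  res
}
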