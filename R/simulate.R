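## von Mises density with mean 0
dVonMises <- function(phi, kappa) {
  exp(kappa * cos(phi)) / (2 * pi * besselI(kappa, 0))
}

## sawtooth phase from -pi to pi with the given cycle length, sample 1 at -pi
sawtoothPhase <- function(nSamples, cycleLen) {
  i <- seq_len(nSamples) - 1L
  -pi + 2 * pi * (i %% cycleLen) / cycleLen
}

#' Construct a ground-truth spike probability track
#'
#' Builds the per-sample generative spike probability for one of four
#' simulated spike-train types. Non-rhythmic kinds use a constant
#' probability `baseRate / fs`. Rhythmic kinds modulate it by a von Mises
#' density over a sawtooth phase (peak at phase 0, mid-cycle), scaled so the
#' average over one cycle is exactly `baseRate / fs`:
#' `prob_i = (baseRate / fs) * 2 * pi * dvonmises(phase_i; 0, kappa)`.
#' Refractoriness is a property of the sampler ([sampleSpikes()]), not of
#' this track.
#'
#' @param kind one of `"atemporal"`, `"refractory_nonrhythmic"`,
#'   `"nonrefractory_rhythmic"`, `"refractory_rhythmic"`.
#' @param nTrials,nSamples trial grid (defaults 48 x 1500).
#' @param baseRate mean firing rate in Hz (default 6).
#' @param cycleLen oscillation cycle in samples (default 125: 8 Hz at 1 kHz).
#' @param kappa von Mises concentration (default 2).
#' @param refractoryLen refractory period in samples (default 3).
#' @param refractoryFloor probability forced after a spike (default 1e-5).
#' @param fs sampling rate in Hz (default 1000).
#' @return a [GroundTruth-class].
#' @examples
#' gt <- makeGroundTruth("nonrefractory_rhythmic", nTrials = 2)
#' max(gt@prob)  # ~0.0194: peak of the von Mises modulation
#' @export
makeGroundTruth <- function(kind, nTrials = 48L, nSamples = 1500L,
                            baseRate = 6, cycleLen = 125L, kappa = 2,
                            refractoryLen = 3L, refractoryFloor = 1e-5,
                            fs = 1000) {
  kind <- match.arg(kind, groundTruthKinds)
  p0 <- baseRate / fs
  phase <- sawtoothPhase(nSamples, cycleLen)
  rhythmic <- kind %in% c("nonrefractory_rhythmic", "refractory_rhythmic")
  if (rhythmic) {
    prob <- p0 * 2 * pi * dVonMises(phase, kappa)
    if (max(prob) > 1) {
      stop(sprintf(
        "peak probability %.4g exceeds 1; lower baseRate or kappa", max(prob)
      ))
    }
  } else {
    prob <- rep(p0, nSamples)
  }
  refractory <- kind %in% c("refractory_nonrhythmic", "refractory_rhythmic")
  new("GroundTruth",
    kind = kind, baseRate = baseRate, cycleLen = as.integer(cycleLen),
    kappa = kappa,
    refractoryLen = if (refractory) as.integer(refractoryLen) else 0L,
    refractoryFloor = refractoryFloor,
    prob = matrix(prob, nTrials, nSamples, byrow = TRUE),
    phase = matrix(phase, nTrials, nSamples, byrow = TRUE),
    fs = fs
  )
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth '%s': %d trials x %d samples, %g Hz rate%s%s\n",
    object@kind, nrow(object@prob), ncol(object@prob), object@baseRate,
    if (object@refractoryLen > 0L) {
      sprintf(", %d ms refractory (floor %g)", object@refractoryLen,
              object@refractoryFloor)
    } else "",
    if (object@kind %in% c("nonrefractory_rhythmic", "refractory_rhythmic")) {
      sprintf(", %d-sample cycles (kappa %g)", object@cycleLen, object@kappa)
    } else ""
  ))
})

#' Sample spike trains from a ground truth
#'
#' Draws Bernoulli spikes sequentially within each trial. For refractory
#' kinds, a sampled spike overrides the probability of the next
#' `refractoryLen` samples to `refractoryFloor` before those samples are
#' drawn. The effective (post-override) probability track actually used at
#' every sample is returned in `metadata$effProb`; it is the generative
#' probability of the realized train and the reference for
#' [klDivergence()].
#'
#' @param gt a [GroundTruth-class].
#' @param seed integer seed.
#' @return a [TrialSet-class] with the sampled spikes, the matched phase
#'   matrix, and `metadata$effProb`/`metadata$groundTruthKind`.
#' @examples
#' gt <- makeGroundTruth("refractory_rhythmic", nTrials = 4)
#' ts <- sampleSpikes(gt, seed = 1)
#' sum(spikes(ts))
#' @export
sampleSpikes <- function(gt, seed = 1L) {
  stopifnot(is(gt, "GroundTruth"))
  nt <- nrow(gt@prob)
  ns <- ncol(gt@prob)
  u <- withSeed(seed, matrix(runif(nt * ns), nt, ns))
  sp <- matrix(0, nt, ns)
  eff <- gt@prob
  if (gt@refractoryLen > 0L) {
    for (tr in seq_len(nt)) {
      p <- gt@prob[tr, ]
      for (i in seq_len(ns)) {
        if (u[tr, i] < p[i]) {
          sp[tr, i] <- 1
          if (i < ns) {
            idx <- (i + 1):min(ns, i + gt@refractoryLen)
            p[idx] <- gt@refractoryFloor
          }
        }
      }
      eff[tr, ] <- p
    }
  } else {
    sp[u < gt@prob] <- 1
  }
  TrialSet(sp,
    phase = gt@phase, fs = gt@fs, historyPrefix = 250L,
    metadata = list(
      effProb = eff, groundTruthKind = gt@kind, seed = as.integer(seed)
    )
  )
}

#' Bernoulli Kullback-Leibler divergence in bits
#'
#' Per-sample divergence of the modeled spike probability `q` from the
#' generative probability `p`:
#' `D(p || q) = p log2(p / q) + (1 - p) log2((1 - p) / (1 - q))`.
#' Both arguments are clipped to `[1e-12, 1 - 1e-12]` before the logs.
#'
#' @param p generative (ground-truth) probability series.
#' @param q modeled probability series, same length.
#' @return list with `perSample` divergences and their `average` (bits).
#' @examples
#' klDivergence(0.5, 0.25)$average  # 0.2075 bits
#' @export
klDivergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must have equal length (", length(p), " vs ", length(q), ")")
  }
  p <- clipProb(as.numeric(p))
  q <- clipProb(as.numeric(q))
  d <- p * log2(p / q) + (1 - p) * log2((1 - p) / (1 - q))
  list(perSample = d, average = mean(d))
}
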