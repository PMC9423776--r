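#' Frequency band specification
#'
#' Named presets: `theta` (4-12 Hz) and `low_gamma` (35-55 Hz), the two
#' hippocampal bands the analysis targets; arbitrary bands are allowed.
#'
#' @param name band label, or one of the presets `"theta"`, `"low_gamma"`.
#' @param low,high band edges in Hz (taken from the preset when omitted).
#' @param order Butterworth filter order (default 3).
#' @return a `BandSpec` list with elements `name`, `low`, `high`, `order`.
#' @examples
#' bandSpec("theta")
#' bandSpec("custom", 6, 10)
#' @export
bandSpec <- function(name, low = NULL, high = NULL, order = 3L) {
  presets <- list(theta = c(4, 12), low_gamma = c(35, 55))
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(presets)) {
      stop("unknown band preset '", name, "'; give low and high explicitly")
    }
    low <- presets[[name]][1]
    high <- presets[[name]][2]
  }
  if (!(low > 0 && high > low)) stop("band requires 0 < low < high")
  structure(
    list(name = name, low = low, high = high, order = as.integer(order)),
    class = "BandSpec"
  )
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`band$order` Butterworth bandpass forward and backward
#' (zero phase lag, squared magnitude response) after reflective padding, so
#' 1.5 s trial segments can be filtered independently without strong edge
#' transients.
#'
#' @param x numeric series sampled at `fs`.
#' @param band a [bandSpec()].
#' @param fs sampling rate in Hz.
#' @return filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' y <- bandpass(cos(2 * pi * 8 * t), bandSpec("theta"), fs = 1000)
#' @export
bandpass <- function(x, band, fs) {
  if (band$high >= fs / 2) {
    stop(sprintf(
      "band edge %g Hz is at or above Nyquist (%g Hz)", band$high, fs / 2
    ))
  }
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / band$low)))
  if (n <= 3 * band$order || pad < 3 * band$order) {
    stop("series too short to filter at this band and order")
  }
  bf <- signal::butter(band$order, c(band$low, band$high) / (fs / 2),
                       type = "pass")
  ## reflective padding: mirror the ends (without repeating the end sample)
  left <- x[(pad + 1):2]
  right <- x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

## FFT-based analytic signal (positive-frequency doubling)
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase is the argument of the analytic (Hilbert-transformed) signal:
#' 0 at local maxima of the filtered oscillation, increasing through
#' `pi/2` a quarter cycle after the peak, wrapped to `[-pi, pi)`.
#'
#' @param x filtered (band-limited) numeric series.
#' @return phase series in `[-pi, pi)`, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' ph <- instantaneousPhase(cos(2 * pi * 8 * t))
#' ph[126]  # ~0 at the 125 ms peak
#' @export
instantaneousPhase <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  if (all(x == 0)) stop("phase is undefined for an all-zero signal")
  a <- analyticSignal(x)
  wrapPhase(atan2(Im(a), Re(a)))
}

#' Extract band phase for every trial of a TrialSet
#'
#' Filters each trial's LFP trace independently ([bandpass()]) and derives
#' the instantaneous phase ([instantaneousPhase()]); the result is stored in
#' the TrialSet's phase slot. The first and last 50 ms of each trial are
#' edge-adjacent; their sample indices are recorded in
#' `metadata$edgeSamples` but the samples are retained.
#'
#' @param trials a [TrialSet-class] with an LFP matrix.
#' @param band a [bandSpec()].
#' @return the TrialSet with the phase matrix filled in.
#' @export
extractPhase <- function(trials, band) {
  lfp <- lfpSignal(trials)
  if (is.null(lfp)) stop("TrialSet has no LFP matrix")
  fs <- samplingRate(trials)
  ph <- t(apply(lfp, 1, function(row) {
    instantaneousPhase(bandpass(row, band, fs))
  }))
  edge <- as.integer(round(0.05 * fs))
  trials@phase <- ph
  trials@metadata$edgeSamples <- c(
    seq_len(min(edge, nSamples(trials))),
    seq(max(1L, nSamples(trials) - edge + 1L), nSamples(trials))
  )
  trials@metadata$band <- band
  validObject(trials)
  trials
}
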