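## Delimited-text I/O for TrialSet objects.
##
## Two layouts:
##   wide: no header, one row per trial, one column per sample
##   long: header "trial,sample,value", 0-based samples

readLayout <- function(path, layout, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "wide") {
    rows <- strsplit(readLines(path), sep, fixed = TRUE)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop(sprintf(
        "ragged trials in %s: row lengths %s", path,
        paste(unique(lens), collapse = ", ")
      ))
    }
    m <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
    if (anyNA(m)) stop("non-numeric value in ", path)
    m
  } else if (layout == "long") {
    d <- read.table(path, header = TRUE, sep = sep)
    if (!all(c("trial", "sample", "value") %in% names(d))) {
      stop("long layout requires columns trial, sample, value")
    }
    trials <- sort(unique(d$trial))
    ns <- sort(unique(d$sample))
    counts <- table(d$trial)
    if (length(unique(counts)) != 1L) stop("ragged trials in ", path)
    m <- matrix(NA_real_, length(trials), length(ns))
    m[cbind(match(d$trial, trials), match(d$sample, ns))] <- d$value
    if (anyNA(m)) stop("missing (trial, sample) combinations in ", path)
    m
  } else {
    stop("layout must be 'wide' or 'long'")
  }
}

#' Read a TrialSet from delimited text files
#'
#' @param spikePath path to the spike matrix file.
#' @param lfpPath optional path to a same-shape LFP matrix file.
#' @param phasePath optional path to a same-shape phase matrix file.
#' @param layout `"wide"` (no header, one row per trial) or `"long"`
#'   (columns trial, sample, value).
#' @param sep field separator (default comma).
#' @param fs,historyPrefix see [TrialSet()].
#' @return a validated [TrialSet-class]; non-binary spike values are an
#'   error, never coerced.
#' @seealso [saveTrials()]
#' @export
loadTrials <- function(spikePath, lfpPath = NULL, phasePath = NULL,
                       layout = c("wide", "long"), sep = ",",
                       fs = 1000, historyPrefix = 250L) {
  layout <- match.arg(layout)
  sp <- readLayout(spikePath, layout, sep)
  nonBinary <- !(sp == 0 | sp == 1)
  if (any(nonBinary)) {
    bad <- which(nonBinary, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "spike value %g at trial %d, sample %d is not binary",
      sp[bad[1], bad[2]], bad[1], bad[2]
    ))
  }
  lfp <- if (!is.null(lfpPath)) readLayout(lfpPath, layout, sep) else NULL
  phase <- if (!is.null(phasePath)) readLayout(phasePath, layout, sep) else NULL
  TrialSet(sp, lfp = lfp, phase = phase, fs = fs,
           historyPrefix = historyPrefix)
}

#' Write a TrialSet to delimited text files
#'
#' Numeric matrices are written with 17 significant digits, so a
#' save/load round trip is bit-exact for spikes and reproduces LFP/phase to
#' full double precision.
#'
#' @param trials a [TrialSet-class].
#' @param spikePath output path for the spike matrix.
#' @param lfpPath,phasePath optional output paths for LFP/phase matrices.
#' @param layout,sep see [loadTrials()].
#' @return invisibly, the paths written.
#' @export
saveTrials <- function(trials, spikePath, lfpPath = NULL, phasePath = NULL,
                       layout = c("wide", "long"), sep = ",") {
  layout <- match.arg(layout)
  writeOne <- function(m, path) {
    if (layout == "wide") {
      txt <- apply(m, 1, function(r) {
        paste(formatC(r, digits = 17, format = "g"), collapse = sep)
      })
      writeLines(txt, path)
    } else {
      d <- data.frame(
        trial = rep(seq_len(nrow(m)), each = ncol(m)),
        sample = rep(seq_len(ncol(m)) - 1L, nrow(m)),
        value = formatC(as.vector(t(m)), digits = 17, format = "g")
      )
      write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
    }
  }
  writeOne(spikes(trials), spikePath)
  paths <- spikePath
  if (!is.null(lfpPath) && !is.null(lfpSignal(trials))) {
    writeOne(lfpSignal(trials), lfpPath)
    paths <- c(paths, lfpPath)
  }
  if (!is.null(phasePath) && !is.null(phaseMatrix(trials))) {
    writeOne(phaseMatrix(trials), phasePath)
    paths <- c(paths, phasePath)
  }
  invisible(paths)
}

#' Export a SplitSet as a long table
#'
#' @param splitSet a [SplitSet-class].
#' @param path output path; delimited text with columns
#'   `split_id, trial_id, role`.
#' @param sep field separator.
#' @return invisibly, the data frame written.
#' @export
writeSplits <- function(splitSet, path, sep = ",") {
  rows <- do.call(rbind, lapply(seq_along(splitSet@splits), function(k) {
    s <- splitSet@splits[[k]]
    data.frame(
      split_id = k,
      trial_id = c(s$train, s$test),
      role = rep(c("train", "test"), c(length(s$train), length(s$test)))
    )
  }))
  write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(rows)
}
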