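# Signal conditioning and artifact rejection for intracranial NREM data.

#' Preprocess a recording
#'
#' Conditions each channel for event detection: downsampling to 1 kHz
#' (with an anti-alias low-pass at 0.8 x the target Nyquist), band-stop
#' filters of +/-1 Hz around the line frequency and its harmonics up to
#' 200 Hz, a 0.1-Hz high-pass to remove slow drifts, and polarity inversion
#' so that positive peaks reflect SO up-states. All filters are zero-phase
#' order-3 Butterworth, preserving event latencies.
#'
#' @param recording a [SleepRecording-class] sampled at >= 1 kHz.
#' @param lineHz line frequency, Hz.
#' @param targetFs target sampling rate, Hz.
#' @return the preprocessed [SleepRecording-class] (fs = `targetFs`,
#'   `preprocessed` flag set, artifact mask reset).
#' @export
preprocessSignal <- function(recording, lineHz = 50, targetFs = 1000) {
  fs <- samplingRate(recording)
  if (fs < targetFs) {
    stop("sampling rate ", fs, " Hz is below ", targetFs,
         " Hz; upsampling is not supported")
  }
  sig <- signalMatrix(recording)
  if (fs > targetFs) {
    fac <- fs / targetFs
    if (abs(fac - round(fac)) > 1e-9) {
      stop("fs must be an integer multiple of the ", targetFs, "-Hz target")
    }
    fac <- round(fac)
    keep <- seq(1, nrow(sig), by = fac)
    ds <- matrix(0, length(keep), ncol(sig))
    for (j in seq_len(ncol(sig))) {
      ds[, j] <- .lowpassFilter(sig[, j], fs, 0.8 * targetFs / 2,
                                order = 6)[keep]
    }
    sig <- ds
    fs <- targetFs
  }
  harmonics <- seq(lineHz, 200, by = lineHz)
  for (j in seq_len(ncol(sig))) {
    x <- sig[, j]
    for (h in harmonics) x <- .bandstopFilter(x, fs, c(h - 1, h + 1))
    x <- .highpassFilter(x, fs, 0.1)
    sig[, j] <- -x          # positive peaks = up-states
  }
  out <- SleepRecording(sig, fs, channelInfo(recording),
                        hypnogram(recording))
  out@preprocessed <- TRUE
  out
}

#' Detect artifactual samples
#'
#' Per channel, three signals are formed: the (preprocessed) signal, a
#' 250-Hz high-pass copy and the first-difference gradient. Each is z
#' scored within each sleep stage; a sample is flagged artifactual if
#' |z| > 6 in any one signal, or |z| > 4 in the raw signal together with
#' |z| > 4 in the high-pass or gradient copy. Flagged runs closer than 3 s
#' are merged and every run is padded by 1 s on each side.
#'
#' @param recording a preprocessed [SleepRecording-class] with a hypnogram.
#' @param zHigh,zLow the two z-score thresholds.
#' @param mergeS merge gap, s. @param padS padding per side, s.
#' @return the recording with its `artifactMask` filled.
#' @export
detectArtifacts <- function(recording, zHigh = 6, zLow = 4,
                            mergeS = 3, padS = 1) {
  hyp <- hypnogram(recording)
  if (nrow(hyp) == 0) stop("hypnogram required for artifact detection")
  fs <- samplingRate(recording)
  sig <- signalMatrix(recording)
  n <- nrow(sig)
  stage <- .stagePerSample(hyp, n, fs)
  short <- names(which(table(stage) < 60 * fs))
  if (length(short)) {
    warning("stage(s) with < 60 s of data: ",
            paste(short, collapse = ", "),
            "; z-scores computed anyway")
  }
  mask <- matrix(FALSE, n, ncol(sig))
  stageIdx <- split(seq_len(n), stage)
  for (j in seq_len(ncol(sig))) {
    x <- sig[, j]
    hp <- .highpassFilter(x, fs, 250)
    gr <- c(0, diff(x))
    z <- function(v) {
      out <- numeric(n)
      for (idx in stageIdx) {
        s <- stats::sd(v[idx])
        out[idx] <- if (s > 0) (v[idx] - mean(v[idx])) / s else 0
      }
      abs(out)
    }
    zr <- z(x); zh <- z(hp); zg <- z(gr)
    flag <- (zr > zHigh | zh > zHigh | zg > zHigh) |
      (zr > zLow & (zh > zLow | zg > zLow))
    runs <- .trueRuns(flag)
    if (nrow(runs)) {
      # merge runs < mergeS apart, then pad padS per side
      merged <- runs[1, , drop = FALSE]
      for (k in seq_len(nrow(runs))[-1]) {
        gap <- (runs[k, 1] - merged[nrow(merged), 2] - 1) / fs
        if (gap < mergeS) {
          merged[nrow(merged), 2] <- runs[k, 2]
        } else {
          merged <- rbind(merged, runs[k, , drop = FALSE])
        }
      }
      pad <- round(padS * fs)
      for (k in seq_len(nrow(merged))) {
        lo <- max(1L, merged[k, 1] - pad)
        hi <- min(n, merged[k, 2] + pad)
        mask[lo:hi, j] <- TRUE
      }
    }
  }
  recording@artifactMask <- mask
  recording
}

#' Artifact mask as an interval table
#'
#' @param recording a [SleepRecording-class] after [detectArtifacts()].
#' @return data.frame with `contact_id`, `start_s`, `end_s` per masked run.
#' @export
artifactIntervals <- function(recording) {
  fs <- samplingRate(recording)
  mask <- artifactMask(recording)
  out <- lapply(seq_len(ncol(mask)), function(j) {
    runs <- .trueRuns(mask[, j])
    if (!nrow(runs)) return(NULL)
    data.frame(contact_id = channelInfo(recording)$contact_id[j],
               start_s = (runs[, 1] - 1) / fs, end_s = runs[, 2] / fs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(contact_id = integer(),
                               start_s = numeric(), end_s = numeric())
  else out
}

#' Analyzable NREM sample mask
#'
#' TRUE exactly on samples staged N2 or N3 and not flagged artifactual.
#'
#' @param recording a [SleepRecording-class].
#' @param channel channel index.
#' @return logical vector over samples.
#' @export
nremSamples <- function(recording, channel = 1) {
  n <- nrow(signalMatrix(recording))
  stage <- .stagePerSample(hypnogram(recording), n,
                           samplingRate(recording))
  stage %in% c("N2", "N3") & !artifactMask(recording)[, channel]
}
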