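# Event detectors for NREM field potentials. All thresholds are computed
# per channel from artifact-free NREM samples only, and "exceeds" is
# strict (>) throughout.

.emptyEvents <- function() {
  data.frame(type = character(), contact_id = integer(),
             onset_s = numeric(), center_s = numeric(), max_s = numeric(),
             offset_s = numeric(), trough_amp = numeric(),
             trough_to_peak_amp = numeric(), n_cycles = integer(),
             duration_s = numeric())
}

#' Count oscillatory cycles in a band-passed segment
#'
#' Number of complete cycles, counted as descending (positive-to-negative)
#' zero crossings of the band-pass-filtered event segment.
#'
#' @param segment numeric, band-passed signal over the event span.
#' @return integer cycle count.
#' @examples
#' countCycles(sin(2 * pi * 13 * seq(0, 1, by = 1e-3)))  # 13
#' @export
countCycles <- function(segment) {
  n <- length(segment)
  if (n < 2) return(0L)
  sum(segment[-n] > 0 & segment[-1] <= 0)
}

#' Detect slow oscillations on one channel
#'
#' The signal is band-pass filtered between 0.3 and 1.25 Hz; candidate
#' events are the spans between successive positive-to-negative zero
#' crossings (a down-state followed by an up-state) lasting 0.8 to 2 s and
#' lying entirely in artifact-free NREM. A candidate is kept when both its
#' trough amplitude and its trough-to-peak amplitude strictly exceed the
#' mean plus `ampSd` s.d. of all candidates on the channel. Onset is the
#' first zero crossing, the center the maximal trough (down-state), the
#' maximum the maximal peak after the trough (up-state).
#'
#' @param x numeric channel signal (microvolts, up-states positive).
#' @param fs sampling rate, Hz.
#' @param good logical sample mask from [nremSamples()] (NULL = all good).
#' @param band,durationRange,ampSd detector settings.
#' @return data.frame of events (see [detectEvents()] for columns).
#' @export
detectSlowOscillations <- function(x, fs, good = NULL,
                                   band = c(0.3, 1.25),
                                   durationRange = c(0.8, 2),
                                   ampSd = 1) {
  if (is.null(good)) good <- rep(TRUE, length(x))
  xf <- bandpassFilter(x, fs, band)
  n <- length(xf)
  cross <- which(xf[-n] > 0 & xf[-1] <= 0)    # descending zero crossings
  if (length(cross) < 2) {
    warning("fewer than 2 SO candidates; amplitude s.d. undefined, ",
            "returning no events")
    return(.emptyEvents())
  }
  cand <- list()
  for (k in seq_len(length(cross) - 1L)) {
    i1 <- cross[k]; i2 <- cross[k + 1L]
    dur <- (i2 - i1) / fs
    if (dur < durationRange[1] || dur > durationRange[2]) next
    if (!all(good[i1:i2])) next
    seg <- xf[i1:i2]
    trI <- which.min(seg)
    pkI <- trI + which.max(seg[trI:length(seg)]) - 1L
    cand[[length(cand) + 1L]] <- data.frame(
      onset_s = i1 / fs, offset_s = i2 / fs,
      center_s = (i1 + trI - 1L) / fs, max_s = (i1 + pkI - 1L) / fs,
      trough_amp = -seg[trI], trough_to_peak_amp = seg[pkI] - seg[trI],
      n_cycles = countCycles(seg), duration_s = dur)
  }
  if (length(cand) < 2) {
    warning("fewer than 2 SO candidates; amplitude s.d. undefined, ",
            "returning no events")
    return(.emptyEvents())
  }
  cand <- do.call(rbind, cand)
  thrTr <- mean(cand$trough_amp) + ampSd * stats::sd(cand$trough_amp)
  thrTp <- mean(cand$trough_to_peak_amp) +
    ampSd * stats::sd(cand$trough_to_peak_amp)
  keep <- cand$trough_amp > thrTr & cand$trough_to_peak_amp > thrTp
  out <- cand[keep, , drop = FALSE]
  if (!nrow(out)) return(.emptyEvents())
  cbind(data.frame(type = "so", contact_id = NA_integer_),
        out[, c("onset_s", "center_s", "max_s", "offset_s", "trough_amp",
                "trough_to_peak_amp", "n_cycles", "duration_s")])
}

# shared RMS-envelope detector for spindles and ripples
.detectRmsEvents <- function(x, fs, good, band, rmsWindowS, thrSd,
                             upperSd, durationRange, minCycles, type) {
  if (is.null(good)) good <- rep(TRUE, length(x))
  if (!any(good)) stop("no analyzable NREM samples on this channel")
  xf <- bandpassFilter(x, fs, band)
  env <- runningRMS(xf, fs, rmsWindowS, smooth = TRUE)
  mu <- mean(env[good]); s <- stats::sd(env[good])
  thr <- mu + thrSd * s
  upper <- mu + upperSd * s
  runs <- .trueRuns(env > thr)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    dur <- (i2 - i1 + 1L) / fs
    if (dur < durationRange[1] || dur > durationRange[2]) next
    if (!all(good[i1:i2])) next
    if (any(env[i1:i2] > upper)) next
    seg <- xf[i1:i2]
    if (countCycles(seg) < minCycles) next
    trI <- which.min(seg)
    pkI <- which.max(seg)
    out[[length(out) + 1L]] <- data.frame(
      type = type, contact_id = NA_integer_,
      onset_s = (i1 - 1L) / fs, center_s = (i1 + trI - 2L) / fs,
      max_s = (i1 + pkI - 2L) / fs, offset_s = i2 / fs,
      trough_amp = -seg[trI], trough_to_peak_amp = seg[pkI] - seg[trI],
      n_cycles = countCycles(seg), duration_s = dur)
  }
  if (!length(out)) .emptyEvents() else do.call(rbind, out)
}

#' Detect sleep spindles on one channel
#'
#' Band-pass 12-16 Hz; RMS over a 200-ms window with an additional 200-ms
#' moving-average smoothing; events are supra-threshold runs (mean + 1 s.d.
#' of the smoothed RMS over artifact-free NREM samples) lasting 0.4 to 3 s,
#' rejected if any sample exceeds the mean + 9 s.d. upper cutoff or fewer
#' than 6 cycles are present. Onset/offset are the threshold crossings;
#' the center is the maximal trough of the filtered signal.
#'
#' @inheritParams detectSlowOscillations
#' @param rmsWindowS RMS and smoothing window, s.
#' @param thrSd,upperSd detection and upper-cutoff multipliers.
#' @param minCycles minimum cycle count.
#' @return data.frame of events.
#' @export
detectSpindles <- function(x, fs, good = NULL, band = c(12, 16),
                           rmsWindowS = 0.2, thrSd = 1, upperSd = 9,
                           durationRange = c(0.4, 3), minCycles = 6) {
  .detectRmsEvents(x, fs, good, band, rmsWindowS, thrSd, upperSd,
                   durationRange, minCycles, "spindle")
}

#' Detect ripples on one channel
#'
#' As [detectSpindles()] but band-passed 80-120 Hz with 20-ms RMS and
#' smoothing windows, detection threshold mean + 3 s.d., upper cutoff
#' mean + 9 s.d., admissible duration 38-200 ms (38 ms = three cycles at
#' 80 Hz) and at least 3 cycles.
#'
#' @inheritParams detectSpindles
#' @return data.frame of events.
#' @export
detectRipples <- function(x, fs, good = NULL, band = c(80, 120),
                          rmsWindowS = 0.02, thrSd = 3, upperSd = 9,
                          durationRange = c(0.038, 0.2), minCycles = 3) {
  .detectRmsEvents(x, fs, good, band, rmsWindowS, thrSd, upperSd,
                   durationRange, minCycles, "ripple")
}

#' Detect SOs, spindles and ripples across channels
#'
#' Runs the per-channel detectors over the requested channels of a
#' preprocessed recording, using each channel's artifact-free NREM mask.
#'
#' @param recording a preprocessed [SleepRecording-class].
#' @param types subset of `c("so", "spindle", "ripple")`.
#' @param channels channel indices (default: all).
#' @return data.frame, one row per event: `type`, `contact_id`, `onset_s`,
#'   `center_s` (maximal trough / down-state), `max_s` (maximal peak /
#'   up-state), `offset_s`, `trough_amp`, `trough_to_peak_amp`,
#'   `n_cycles`, `duration_s`.
#' @export
detectEvents <- function(recording, types = c("so", "spindle", "ripple"),
                         channels = NULL) {
  types <- match.arg(types, .EVENT_TYPES, several.ok = TRUE)
  if (!recording@preprocessed) {
    warning("recording is not preprocessed; detectors assume up-states ",
            "positive and a conditioned signal")
  }
  if (is.null(channels)) channels <- seq_len(ncol(signalMatrix(recording)))
  fs <- samplingRate(recording)
  out <- list()
  for (ch in channels) {
    x <- signalMatrix(recording)[, ch]
    good <- nremSamples(recording, ch)
    cid <- channelInfo(recording)$contact_id[ch]
    for (ty in types) {
      ev <- switch(ty,
        so = detectSlowOscillations(x, fs, good),
        spindle = detectSpindles(x, fs, good),
        ripple = detectRipples(x, fs, good))
      if (nrow(ev)) {
        ev$contact_id <- cid
        out[[length(out) + 1L]] <- ev
      }
    }
  }
  if (!length(out)) .emptyEvents() else do.call(rbind, out)
}

#' Match detections against ground truth
#'
#' Greedy one-to-one matching of detected to planted events of the same
#' type and contact; a detection matches a planted event when their
#' centers differ by less than half the planted duration.
#'
#' @param detected,planted event data.frames.
#' @return list with `sensitivity`, `precision`, `nMatched`.
#' @export
matchToTruth <- function(detected, planted) {
  nM <- 0L
  for (ty in unique(planted$type)) {
    for (ci in unique(planted$contact_id)) {
      p <- planted[planted$type == ty & planted$contact_id == ci, ]
      d <- detected[detected$type == ty & detected$contact_id == ci, ]
      used <- logical(nrow(d))
      for (k in seq_len(nrow(p))) {
        if (!nrow(d)) break
        dd <- abs(d$center_s - p$center_s[k])
        dd[used] <- Inf
        j <- which.min(dd)
        if (dd[j] < p$duration_s[k] / 2) {
          used[j] <- TRUE
          nM <- nM + 1L
        }
      }
    }
  }
  list(sensitivity = if (nrow(planted)) nM / nrow(planted) else NA_real_,
       precision = if (nrow(detected)) nM / nrow(detected) else NA_real_,
       nMatched = nM)
}
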