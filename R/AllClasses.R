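#' @import methods
NULL

.STAGES <- c("W", "N1", "N2", "N3", "REM")
.REGIONS <- c("AH", "PH", "A", "EC", "PHC")
.EVENT_TYPES <- c("so", "spindle", "ripple")
.EPOCH_S <- 30

#' Multichannel intracranial sleep recording
#'
#' Container for a multichannel field-potential recording together with its
#' sampling rate, per-channel metadata, a per-epoch hypnogram and a
#' per-sample artifact mask. Channels are macro contacts; the signal is in
#' microvolts, oriented (after [preprocessSignal()]) so that positive peaks
#' reflect slow-oscillation up-states.
#'
#' @slot signal numeric matrix, samples x channels, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with one row per channel: `contact_id`,
#'   `region` (one of AH, PH, A, EC, PHC) and `hemisphere` (L or R).
#' @slot hypnogram data.frame with `epoch_start_s` and `stage`
#'   (W, N1, N2, N3 or REM), 30-s epochs covering the whole recording.
#' @slot artifactMask logical matrix, same shape as `signal`; `TRUE` marks
#'   artifactual samples. All `FALSE` until [detectArtifacts()] is run.
#' @slot preprocessed logical flag set by [preprocessSignal()].
#'
#' @seealso [SleepRecording()], [preprocessSignal()], [detectArtifacts()]
#' @export
setClass("SleepRecording",
  representation(
    signal = "matrix",
    fs = "numeric",
    channels = "data.frame",
    hypnogram = "data.frame",
    artifactMask = "matrix",
    preprocessed = "logical"
  )
)

setValidity("SleepRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal)) msg <- c(msg, "signal must be numeric")
  if (length(object@fs) != 1L || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (nrow(object@channels) != ncol(object@signal)) {
    msg <- c(msg, "channels must have one row per signal column")
  }
  need <- c("contact_id", "region", "hemisphere")
  if (!all(need %in% names(object@channels))) {
    msg <- c(msg, sprintf("channels needs columns: %s",
                          paste(need, collapse = ", ")))
  } else {
    if (!all(object@channels$hemisphere %in% c("L", "R"))) {
      msg <- c(msg, "hemisphere must be 'L' or 'R'")
    }
  }
  hyp <- object@hypnogram
  if (!all(c("epoch_start_s", "stage") %in% names(hyp))) {
    msg <- c(msg, "hypnogram needs columns epoch_start_s, stage")
  } else {
    bad <- setdiff(unique(hyp$stage), .STAGES)
    if (length(bad)) {
      msg <- c(msg, sprintf(
        "unknown stage label(s): %s (admissible: %s)",
        paste(bad, collapse = ", "), paste(.STAGES, collapse = ", ")))
    }
    if (nrow(hyp) > 0) {
      starts <- hyp$epoch_start_s
      if (starts[1] != 0 ||
          (nrow(hyp) > 1 && any(diff(starts) != .EPOCH_S))) {
        msg <- c(msg, "hypnogram epochs must be contiguous 30-s epochs from 0")
      }
      if (max(starts) + .EPOCH_S < nrow(object@signal) / object@fs - 1e-9) {
        msg <- c(msg, "hypnogram does not span the signal")
      }
    }
  }
  if (!identical(dim(object@artifactMask), dim(object@signal))) {
    msg <- c(msg, "artifactMask must match signal dimensions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SleepRecording
#'
#' @param signal numeric matrix (samples x channels), microvolts.
#' @param fs sampling rate, Hz.
#' @param channels data.frame with `contact_id`, `region`, `hemisphere`.
#' @param hypnogram data.frame with `epoch_start_s`, `stage` (30-s epochs).
#' @return a [SleepRecording-class] object with an all-`FALSE` artifact mask.
#' @examples
#' rec <- SleepRecording(matrix(rnorm(2000), ncol = 1), fs = 1000,
#'   channels = data.frame(contact_id = "c1", region = "AH", hemisphere = "L"),
#'   hypnogram = data.frame(epoch_start_s = 0, stage = "N2"))
#' @export
SleepRecording <- function(signal, fs, channels, hypnogram) {
  signal <- as.matrix(signal)
  mask <- matrix(FALSE, nrow(signal), ncol(signal))
  new("SleepRecording", signal = signal, fs = fs,
      channels = as.data.frame(channels),
      hypnogram = as.data.frame(hypnogram),
      artifactMask = mask, preprocessed = FALSE)
}

#' Spike trains recorded from microwires
#'
#' Spike times per microwire, grouped by the macro contact whose bundle the
#' wire belongs to. Times are seconds from recording start; each train is
#' strictly increasing (duplicate timestamps within a wire are dropped on
#' construction).
#'
#' @slot times list of numeric vectors, one per wire.
#' @slot wires data.frame with `contact_id` and `wire_id`, one row per wire.
#'
#' @seealso [SpikeTrains()], [wireInclusion()], [firingRatePeth()]
#' @export
setClass("SpikeTrains",
  representation(times = "list", wires = "data.frame"))

setValidity("SpikeTrains", function(object) {
  msg <- character()
  if (length(object@times) != nrow(object@wires)) {
    msg <- c(msg, "one wires row per spike-time vector required")
  }
  if (!all(c("contact_id", "wire_id") %in% names(object@wires))) {
    msg <- c(msg, "wires needs columns contact_id, wire_id")
  }
  for (tr in object@times) {
    if (length(tr) && (is.unsorted(tr, strictly = TRUE) || any(tr < 0))) {
      msg <- c(msg, "spike times must be nonnegative and strictly increasing")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrains object
#'
#' @param times list of numeric vectors of spike times (s), one per wire.
#'   Unsorted vectors are sorted with a warning; exact duplicates within a
#'   wire are dropped.
#' @param wires data.frame with `contact_id`, `wire_id`.
#' @return a [SpikeTrains-class] object.
#' @export
SpikeTrains <- function(times, wires) {
  times <- lapply(times, as.numeric)
  for (i in seq_along(times)) {
    if (is.unsorted(times[[i]])) {
      warning("spike times of wire ", i, " were unsorted; sorting")
      times[[i]] <- sort(times[[i]])
    }
    times[[i]] <- times[[i]][!duplicated(times[[i]])]
  }
  new("SpikeTrains", times = times, wires = as.data.frame(wires))
}

#' Peri-event time histogram
#'
#' Event- or firing-rate histogram around an anchor point, built at 1-ms
#' resolution, Gaussian-smoothed and corrected to a pre-event baseline
#' window. `rate` holds the baseline-corrected smoothed rate in Hz;
#' `rateUncorrected` the smoothed rate before baseline subtraction.
#'
#' @slot anchorType,targetType character labels (e.g. "so", "ripple", "mua").
#' @slot anchorPoint one of "onset", "center", "maximum", "offset".
#' @slot binCenters numeric, seconds relative to the anchor.
#' @slot rate baseline-corrected smoothed rate, Hz.
#' @slot rateUncorrected smoothed rate before baseline correction, Hz.
#' @slot rateRaw unsmoothed, uncorrected rate, Hz.
#' @slot baselineWindow numeric length-2, seconds.
#' @slot nAnchors number of anchor events that entered the histogram.
#' @slot smoothingMs total width of the Gaussian smoothing window, ms.
#' @export
setClass("Peth",
  representation(
    anchorType = "character", targetType = "character",
    anchorPoint = "character", binCenters = "numeric",
    rate = "numeric", rateUncorrected = "numeric", rateRaw = "numeric",
    baselineWindow = "numeric", nAnchors = "integer", smoothingMs = "numeric"
  )
)

setValidity("Peth", function(object) {
  msg <- character()
  n <- length(object@binCenters)
  if (length(object@rate) != n || length(object@rateRaw) != n) {
    msg <- c(msg, "rate vectors must match binCenters length")
  }
  if (n > 1) {
    dt <- diff(object@binCenters)
    if (max(abs(dt - dt[1])) > 1e-9) msg <- c(msg, "bins must be equispaced")
  }
  if (object@nAnchors <= 0L) msg <- c(msg, "nAnchors must be positive")
  if (!object@anchorPoint %in% c("onset", "center", "maximum", "offset")) {
    msg <- c(msg, "invalid anchorPoint")
  }
  if (length(msg)) msg else TRUE
})

#' Event-locked spike cross-correlogram
#'
#' Lag-resolved co-firing of microwire pairs within event-centered windows,
#' with the raw layer, the shift predictor (event n vs n + 1), the same two
#' layers computed on matched non-event surrogates, and the fully corrected
#' curve `(raw - shift) - (surrogateRaw - surrogateShift)`. Units are
#' coincidences per second of lag-valid window time, per event and wire pair.
#'
#' @slot lagsMs lag bin centers, ms (-50..50 at 1-ms spacing by default).
#' @slot raw,shiftPredictor,surrogateRaw,surrogateShift,corrected numeric
#'   vectors over lags (smoothed with a 5-ms Gaussian kernel).
#' @slot nPairs number of wire pairs; @slot nEvents number of events.
#' @slot smoothingMs Gaussian smoothing width, ms.
#' @export
setClass("CcgResult",
  representation(
    lagsMs = "numeric", raw = "numeric", shiftPredictor = "numeric",
    surrogateRaw = "numeric", surrogateShift = "numeric",
    corrected = "numeric", nPairs = "integer", nEvents = "integer",
    smoothingMs = "numeric"
  )
)

setValidity("CcgResult", function(object) {
  n <- length(object@lagsMs)
  ok <- all(vapply(list(object@raw, object@shiftPredictor, object@corrected),
                   length, 1L) == n)
  if (!ok) "layers must match lagsMs length" else TRUE
})

#' Time-frequency phase-locking-value map
#'
#' Event-locked phase-locking values between two channels on a time x
#' frequency grid (25-ms steps, 1-Hz steps by default). The analysis window
#' per frequency spans a whole number of cycles, at least five cycles and at
#' least 100 ms. `baselineCorrected` subtracts the frequency-wise mean PLV
#' over the baseline time bins.
#'
#' @slot timesS time-bin centers relative to the anchor, s.
#' @slot freqsHz analysis frequencies, Hz.
#' @slot plv matrix freqs x times, raw PLV in [0, 1].
#' @slot baselineCorrected matrix freqs x times.
#' @slot nEvents anchors used. @slot seedType anchor label.
#' @slot baselineWindow numeric length-2, s.
#' @export
setClass("PlvMap",
  representation(
    timesS = "numeric", freqsHz = "numeric", plv = "matrix",
    baselineCorrected = "matrix", nEvents = "integer",
    seedType = "character", baselineWindow = "numeric"
  )
)

setValidity("PlvMap", function(object) {
  msg <- character()
  if (!identical(dim(object@plv),
                 c(length(object@freqsHz), length(object@timesS)))) {
    msg <- c(msg, "plv must be freqs x times")
  }
  if (any(object@plv < -1e-9 | object@plv > 1 + 1e-9)) {
    msg <- c(msg, "plv must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Time-by-time correlation map between firing rates and event occurrences
#'
#' Pearson correlations, across the contacts of a session, between
#' seed-locked mean firing rates in interval t1 and seed-locked target
#' event rates in interval t2, over a grid of 500-ms intervals. Cells with
#' zero variance in either variable are NA (undefined, excluded from
#' statistics downstream).
#'
#' @slot seedType,targetType labels.
#' @slot time1,time2 interval centers, s (rows resp. columns of `r`).
#' @slot r matrix of Pearson r in [-1, 1] (NA = undefined).
#' @slot nContacts contacts entering each correlation.
#' @export
setClass("CorrelationMap",
  representation(
    seedType = "character", targetType = "character",
    time1 = "numeric", time2 = "numeric", r = "matrix",
    nContacts = "integer"
  )
)

setValidity("CorrelationMap", function(object) {
  msg <- character()
  if (!identical(dim(object@r),
                 c(length(object@time1), length(object@time2)))) {
    msg <- c(msg, "r must be time1 x time2")
  }
  rr <- object@r[!is.na(object@r)]
  if (length(rr) && any(rr < -1 - 1e-9 | rr > 1 + 1e-9)) {
    msg <- c(msg, "r must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Cluster-based permutation test result
#'
#' One-sample t statistics across sessions per cell, contiguous
#' supra-threshold clusters (lag neighbours in 1-D, 4-neighbourhood in 2-D),
#' cluster mass (sum of t) tested against a sign-flip permutation null of
#' the maximal cluster mass, two-tailed.
#'
#' @slot statistic numeric vector or matrix of t values.
#' @slot clusterId integer labels, 0 = sub-threshold.
#' @slot clusterP numeric p value per cluster (named by cluster id).
#' @slot mask logical, TRUE where a significant cluster lies.
#' @slot nPermutations,clusterAlpha,finalAlpha test settings.
#' @export
setClass("ClusterResult",
  representation(
    statistic = "ANY", clusterId = "ANY", clusterP = "numeric",
    mask = "ANY", nPermutations = "integer",
    clusterAlpha = "numeric", finalAlpha = "numeric"
  )
)

setValidity("ClusterResult", function(object) {
  lo <- 1 / (object@nPermutations + 1)
  if (length(object@clusterP) &&
      any(object@clusterP < lo - 1e-12 | object@clusterP > 1 + 1e-12)) {
    "cluster p values must lie in [1/(n_permutations+1), 1]"
  } else TRUE
})
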