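#' @rdname SleepRecording-class
setMethod("samplingRate", "SleepRecording", function(x) x@fs)

#' @rdname SleepRecording-class
setMethod("signalMatrix", "SleepRecording", function(x) x@signal)

#' @rdname SleepRecording-class
setMethod("channelInfo", "SleepRecording", function(x) x@channels)

#' @rdname SleepRecording-class
setMethod("hypnogram", "SleepRecording", function(x) x@hypnogram)

#' @rdname SleepRecording-class
setMethod("artifactMask", "SleepRecording", function(x) x@artifactMask)

#' @rdname SleepRecording-class
setMethod("dim", "SleepRecording", function(x) dim(x@signal))

#' Recording duration in seconds
#' @rdname SleepRecording-class
#' @export
recordingDuration <- function(x) nrow(x@signal) / x@fs

setMethod("show", "SleepRecording", function(object) {
  stages <- table(object@hypnogram$stage)
  cat(sprintf(
    "SleepRecording: %d channels x %.1f min at %g Hz%s\n",
    ncol(object@signal), recordingDuration(object) / 60, object@fs,
    if (object@preprocessed) " (preprocessed)" else ""))
  cat("  regions:", paste(unique(object@channels$region), collapse = ", "),
      "\n")
  cat("  stages: ",
      paste(sprintf("%s:%d", names(stages), stages), collapse = " "), "\n")
  cat(sprintf("  artifact samples flagged: %.2f%%\n",
              100 * mean(object@artifactMask)))
})

#' @rdname SpikeTrains-class
setMethod("spikeTimes", "SpikeTrains", function(x) x@times)

#' @rdname SpikeTrains-class
setMethod("wireInfo", "SpikeTrains", function(x) x@wires)

#' @rdname SpikeTrains-class
#' @export
setMethod("length", "SpikeTrains", function(x) length(x@times))

setMethod("show", "SpikeTrains", function(object) {
  n <- vapply(object@times, length, 1L)
  cat(sprintf("SpikeTrains: %d wires on %d contacts, %d spikes\n",
              length(object@times),
              length(unique(object@wires$contact_id)), sum(n)))
})

#' @rdname Peth-class
#' @param ... for `rates`, `corrected = TRUE` selects the baseline-corrected
#'   layer, `corrected = FALSE` the smoothed uncorrected rate.
setMethod("rates", "Peth", function(x, corrected = TRUE) {
  if (corrected) x@rate else x@rateUncorrected
})

#' @rdname Peth-class
setMethod("binCenters", "Peth", function(x) x@binCenters)

#' @rdname Peth-class
setMethod("nAnchors", "Peth", function(x) x@nAnchors)

setMethod("show", "Peth", function(object) {
  cat(sprintf(
    "Peth: %s (%s-locked) -> %s | %d anchors | [%g, %g] s, %d bins\n",
    object@anchorType, object@anchorPoint, object@targetType,
    object@nAnchors, min(object@binCenters), max(object@binCenters),
    length(object@binCenters)))
  cat(sprintf("  baseline [%g, %g] s, %g-ms Gaussian smoothing\n",
              object@baselineWindow[1], object@baselineWindow[2],
              object@smoothingMs))
})

#' @rdname CcgResult-class
setMethod("lags", "CcgResult", function(x) x@lagsMs)

setMethod("show", "CcgResult", function(object) {
  cat(sprintf(
    "CcgResult: %d wire pairs x %d events, lags %g..%g ms\n",
    object@nPairs, object@nEvents, min(object@lagsMs), max(object@lagsMs)))
  cat(sprintf("  corrected peak %.4g at %g ms\n",
              max(object@corrected),
              object@lagsMs[which.max(object@corrected)]))
})

#' @rdname scale01
setMethod("scale01", "CcgResult", function(x) scale01(x@corrected))

#' @rdname scale01
setMethod("scale01", "numeric", function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("cannot scale a constant curve between 0 and 1")
  (x - rng[1]) / diff(rng)
})

setMethod("show", "PlvMap", function(object) {
  cat(sprintf(
    "PlvMap: %s-locked, %d events | %d freqs x %d times | max PLV %.3f\n",
    object@seedType, object@nEvents, length(object@freqsHz),
    length(object@timesS), max(object@plv)))
})

setMethod("show", "ClusterResult", function(object) {
  nsig <- sum(object@clusterP <= object@finalAlpha)
  cat(sprintf(
    "ClusterResult: %d cluster(s), %d significant at alpha=%g (%d permutations)\n",
    length(object@clusterP), nsig, object@finalAlpha, object@nPermutations))
})

#' Significant clusters of a ClusterResult
#' @param x a [ClusterResult-class].
#' @return logical mask of cells in clusters with p <= finalAlpha.
#' @export
significantMask <- function(x) x@mask

#' @rdname significantMask
#' @export
clusterPValues <- function(x) x@clusterP
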