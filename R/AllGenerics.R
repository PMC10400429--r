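#' @rdname SleepRecording-class
#' @param object,x an object.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname SleepRecording-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname SleepRecording-class
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname SleepRecording-class
#' @export
setGeneric("hypnogram", function(x) standardGeneric("hypnogram"))

#' @rdname SleepRecording-class
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' @rdname SpikeTrains-class
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname SpikeTrains-class
#' @export
setGeneric("wireInfo", function(x) standardGeneric("wireInfo"))

#' @rdname Peth-class
#' @export
setGeneric("rates", function(x, ...) standardGeneric("rates"))

#' @rdname Peth-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname Peth-class
#' @export
setGeneric("nAnchors", function(x) standardGeneric("nAnchors"))

#' @rdname CcgResult-class
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' Scale a corrected cross-correlogram between 0 and 1
#'
#' @param x a [CcgResult-class] object (or numeric vector).
#' @return numeric vector: `(x - min) / (max - min)` of the corrected layer.
#' @export
setGeneric("scale01", function(x) standardGeneric("scale01"))
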