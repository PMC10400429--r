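# Peri-event time histogram machinery: 1-ms binning across anchors,
# Gaussian smoothing, pre-event baseline correction.

# counts of target occurrences per relative-time bin, pooled over anchors;
# anchors whose window leaves [0, durationS] or touches a bad interval are
# dropped (not truncated), keeping per-bin denominators uniform
.relCounts <- function(anchors, targets, windowS, binWidthS,
                       durationS = NULL, badIntervals = NULL) {
  nb <- round(diff(windowS) / binWidthS)
  keep <- rep(TRUE, length(anchors))
  if (!is.null(durationS)) {
    keep <- anchors + windowS[1] >= 0 & anchors + windowS[2] <= durationS
  }
  if (!is.null(badIntervals) && nrow(badIntervals)) {
    for (k in seq_len(nrow(badIntervals))) {
      keep <- keep & (anchors + windowS[2] <= badIntervals[k, 1] |
                      anchors + windowS[1] >= badIntervals[k, 2])
    }
  }
  anchors <- anchors[keep]
  counts <- numeric(nb)
  targets <- sort(targets)
  for (a in anchors) {
    i1 <- findInterval(a + windowS[1], targets) + 1L
    i2 <- findInterval(a + windowS[2], targets)
    if (i2 < i1) next
    rel <- targets[i1:i2] - a - windowS[1]
    b <- floor(rel / binWidthS) + 1L
    b <- b[b >= 1L & b <= nb]
    if (length(b)) {
      tb <- tabulate(b, nbins = nb)
      counts <- counts + tb
    }
  }
  list(counts = counts, nAnchors = length(anchors),
       centers = windowS[1] + (seq_len(nb) - 0.5) * binWidthS)
}

.buildPeth <- function(counts, centers, nAnchors, perAnchorScale,
                       binWidthS, smoothingMs, baselineWindowS,
                       anchorType, targetType, anchorPoint) {
  if (nAnchors < 1) stop("no usable anchor events")
  if (baselineWindowS[1] < centers[1] - binWidthS / 2 ||
      baselineWindowS[2] > centers[length(centers)] + binWidthS / 2) {
    stop("baseline window lies outside the histogram window")
  }
  rateRaw <- counts / (nAnchors * perAnchorScale * binWidthS)
  widthBins <- round(smoothingMs / 1000 / binWidthS)
  sm <- gaussianSmooth(rateRaw, widthBins)
  base <- centers >= baselineWindowS[1] & centers < baselineWindowS[2]
  if (!any(base)) stop("baseline window contains no bins")
  corrected <- sm - mean(sm[base])
  new("Peth", anchorType = anchorType, targetType = targetType,
      anchorPoint = anchorPoint, binCenters = centers,
      rate = corrected, rateUncorrected = sm, rateRaw = rateRaw,
      baselineWindow = as.numeric(baselineWindowS),
      nAnchors = as.integer(nAnchors), smoothingMs = smoothingMs)
}

#' Event-locked event-rate histogram
#'
#' Rate of target events around anchor events: occurrences are binned at
#' 1-ms resolution across anchors, converted to Hz (per anchor), smoothed
#' with a 100-ms Gaussian kernel and corrected by subtracting the mean
#' rate over a pre-event baseline window. Anchors whose window crosses the
#' recording edge or a bad interval are dropped.
#'
#' @param anchors numeric anchor times, s (already resolved to the wanted
#'   anchor point: onset, center, maximum or offset).
#' @param targets numeric target times, s.
#' @param windowS length-2 window around the anchor, s.
#' @param baselineWindowS length-2 baseline window, s (e.g. c(-2.5, -2)
#'   for SO- and spindle-locked rates, c(-1.5, -1) for ripple-locked).
#' @param binWidthS bin width, s. @param smoothingMs Gaussian width, ms.
#' @param durationS recording duration for edge dropping (NULL = keep all).
#' @param badIntervals optional matrix of (start, end) intervals, s.
#' @param anchorType,targetType,anchorPoint labels stored in the result.
#' @return a [Peth-class].
#' @export
eventLockedRate <- function(anchors, targets,
                            windowS = c(-2.5, 2.5),
                            baselineWindowS = c(-2.5, -2),
                            binWidthS = 0.001, smoothingMs = 100,
                            durationS = NULL, badIntervals = NULL,
                            anchorType = "event", targetType = "event",
                            anchorPoint = "center") {
  if (!length(anchors)) stop("no anchor events supplied")
  rc <- .relCounts(anchors, targets, windowS, binWidthS, durationS,
                   badIntervals)
  .buildPeth(rc$counts, rc$centers, rc$nAnchors, 1, binWidthS,
             smoothingMs, baselineWindowS, anchorType, targetType,
             anchorPoint)
}

#' Event-locked multiunit firing-rate histogram
#'
#' Spike counts around anchors, pooled over the wires of a contact,
#' converted to Hz per wire, smoothed and baseline-corrected as in
#' [eventLockedRate()].
#'
#' @param spikes a [SpikeTrains-class].
#' @param anchors anchor times, s.
#' @param contact contact id to pool wires over (NULL = all wires).
#' @inheritParams eventLockedRate
#' @return a [Peth-class] (targetType = "mua").
#' @export
firingRatePeth <- function(spikes, anchors,
                           windowS = c(-2.5, 2.5),
                           baselineWindowS = c(-2.5, -2),
                           contact = NULL,
                           binWidthS = 0.001, smoothingMs = 100,
                           durationS = NULL, badIntervals = NULL,
                           anchorType = "event",
                           anchorPoint = "center") {
  sel <- if (is.null(contact)) seq_len(length(spikes))
         else which(wireInfo(spikes)$contact_id == contact)
  if (!length(sel)) stop("no wires available for this contact")
  if (!length(anchors)) stop("no anchor events supplied")
  counts <- NULL
  nA <- 0L
  centers <- NULL
  for (w in sel) {
    rc <- .relCounts(anchors, spikeTimes(spikes)[[w]], windowS,
                     binWidthS, durationS, badIntervals)
    if (is.null(counts)) {
      counts <- rc$counts; centers <- rc$centers; nA <- rc$nAnchors
    } else counts <- counts + rc$counts
  }
  .buildPeth(counts, centers, nA, length(sel), binWidthS, smoothingMs,
             baselineWindowS, anchorType, "mua", anchorPoint)
}
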