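# Event-event temporal coupling: contingency splits, peak latencies,
# onset/offset rate contrasts.

#' Split seed events by target contingency
#'
#' Partitions seed events into "coupled" (at least one target event center
#' within +/- `windowS` of the seed center) and "uncoupled".
#'
#' @param seedCenters,targetCenters numeric center times, s.
#' @param windowS half-window, s (the +/-1-s contingency rule).
#' @return list with `coupled` and `uncoupled` (indices into
#'   `seedCenters`).
#' @examples
#' splitByContingency(c(10, 20), c(10.5, 30))  # seed 1 coupled
#' @export
splitByContingency <- function(seedCenters, targetCenters, windowS = 1) {
  if (!length(seedCenters)) {
    return(list(coupled = integer(), uncoupled = integer()))
  }
  coupled <- vapply(seedCenters, function(s) {
    any(abs(targetCenters - s) <= windowS)
  }, logical(1))
  list(coupled = which(coupled), uncoupled = which(!coupled))
}

#' Latency of the maximal rate within a search window
#'
#' Bin center of the maximal (baseline-corrected) rate inside
#' `searchWindowS`; ties are broken to the earliest bin.
#'
#' @param peth a [Peth-class].
#' @param searchWindowS length-2 window, s (default -2 to 0).
#' @return latency in seconds.
#' @export
peakLatency <- function(peth, searchWindowS = c(-2, 0)) {
  ctr <- binCenters(peth)
  sel <- ctr >= searchWindowS[1] & ctr <= searchWindowS[2]
  if (!any(sel)) stop("search window contains no histogram bins")
  r <- rates(peth)[sel]
  ctr[sel][which.max(r)]
}

#' Target rate before versus after an anchor point
#'
#' Mean target event rate in the `halfWindowS` window before versus after
#' the anchor (e.g. ripple rates in 250-ms windows around spindle onsets
#' or offsets), for paired testing across sessions.
#'
#' @param anchors anchor times (onsets or offsets), s.
#' @param targets target event times, s.
#' @param halfWindowS window length per side, s.
#' @return named numeric: `before` and `after`, Hz.
#' @export
onsetOffsetRateContrast <- function(anchors, targets,
                                    halfWindowS = 0.25) {
  if (!length(anchors)) {
    return(c(before = 0, after = 0))
  }
  nBefore <- sum(vapply(anchors, function(a) {
    sum(targets >= a - halfWindowS & targets < a)
  }, numeric(1)))
  nAfter <- sum(vapply(anchors, function(a) {
    sum(targets > a & targets <= a + halfWindowS)
  }, numeric(1)))
  c(before = nBefore / (length(anchors) * halfWindowS),
    after = nAfter / (length(anchors) * halfWindowS))
}
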