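# Event-locked cross-correlograms with shift-predictor and surrogate
# corrections. Coincidences are tallied within 150-ms windows centered on
# event maxima, at 1-ms lag bins up to +/- 50 ms, pooled over both
# orderings of each unordered wire pair (symmetric by construction), and
# expressed per second of lag-valid window time per event and wire pair.

# relative spike times per wire within one centered window
.relSpikes <- function(trains, center, halfWin) {
  lapply(trains, function(tt) {
    tt[tt >= center - halfWin & tt <= center + halfWin] - center
  })
}

# one CCG layer; centersB = centersA gives the raw layer, a rotation the
# shift predictor. Counts are symmetrized: every cross-wire spike pair
# contributes at +d and -d.
.ccgLayer <- function(trains, centersA, centersB, halfWin, maxLagMs,
                      binMs) {
  nb <- 2L * as.integer(maxLagMs / binMs) + 1L
  mid <- as.integer(maxLagMs / binMs) + 1L
  counts <- numeric(nb)
  nw <- length(trains)
  for (e in seq_along(centersA)) {
    relA <- .relSpikes(trains, centersA[e], halfWin)
    relB <- if (centersB[e] == centersA[e]) relA
            else .relSpikes(trains, centersB[e], halfWin)
    for (i in seq_len(nw - 1L)) {
      for (j in (i + 1L):nw) {
        a <- relA[[i]]; b <- relB[[j]]
        if (length(a) && length(b)) {
          d <- round(outer(b, a, "-") * 1000 / binMs)
          d <- d[abs(d) <= maxLagMs / binMs]
          if (length(d)) {
            counts <- counts + tabulate(d + mid, nbins = nb) +
              tabulate(-d + mid, nbins = nb)
          }
        }
        # the reversed ordering of the pair under a shift predictor
        if (centersB[e] != centersA[e]) {
          a2 <- relA[[j]]; b2 <- relB[[i]]
          if (length(a2) && length(b2)) {
            d <- round(outer(b2, a2, "-") * 1000 / binMs)
            d <- d[abs(d) <= maxLagMs / binMs]
            if (length(d)) {
              counts <- counts + tabulate(d + mid, nbins = nb) +
                tabulate(-d + mid, nbins = nb)
            }
          }
        }
      }
    }
  }
  nPairs <- nw * (nw - 1L) / 2L
  # per-lag valid window time (no zero-padding inflation); the reversed
  # ordering and the +/-d symmetrization each double the tally
  lagS <- (seq_len(nb) - mid) * binMs / 1000
  overlap <- 2 * halfWin - abs(lagS)
  denom <- nPairs * length(centersA) * overlap * 2
  if (any(centersB != centersA)) denom <- denom * 2
  counts / denom
}

#' Event-locked cross-correlogram of microwire spike trains
#'
#' Computes, for all unordered pairs of the supplied wires, the
#' coincidence rate per lag within `windowS`-long windows centered on
#' event maxima; subtracts a shift predictor (wire 1 during event n versus
#' wire 2 during event n + 1, the last event wrapping to the first) to
#' remove event-locked rate covariation; and subtracts the identically
#' computed (shift-predictor-corrected) CCG of matched non-event
#' surrogates. All layers are smoothed with a `smoothingMs` Gaussian
#' kernel. The corrected layer is
#' `(raw - shiftPredictor) - (surrogateRaw - surrogateShift)`.
#'
#' @param spikes a [SpikeTrains-class] (apply [wireInclusion()] first).
#' @param eventMaxima event maximum times, s (>= 2 events).
#' @param surrogateCenters surrogate epoch centers, s (NULL skips the
#'   surrogate layers).
#' @param contact restrict to wires of this contact (NULL = all).
#' @param windowS full window length, s. @param maxLagMs maximal lag, ms.
#' @param binMs lag bin width, ms. @param smoothingMs Gaussian width, ms.
#' @return a [CcgResult-class].
#' @export
eventLockedCcg <- function(spikes, eventMaxima, surrogateCenters = NULL,
                           contact = NULL, windowS = 0.15, maxLagMs = 50,
                           binMs = 1, smoothingMs = 5) {
  sel <- if (is.null(contact)) seq_len(length(spikes))
         else which(wireInfo(spikes)$contact_id == contact)
  if (length(sel) < 2) stop("at least 2 wires required for a CCG")
  if (length(eventMaxima) < 2) {
    stop("at least 2 events required (the shift predictor pairs event n ",
         "with event n + 1)")
  }
  trains <- spikeTimes(spikes)[sel]
  halfWin <- windowS / 2
  shiftOf <- function(ctr) ctr[c(seq_along(ctr)[-1], 1L)]
  raw <- .ccgLayer(trains, eventMaxima, eventMaxima, halfWin, maxLagMs,
                   binMs)
  shift <- .ccgLayer(trains, eventMaxima, shiftOf(eventMaxima), halfWin,
                     maxLagMs, binMs)
  if (!is.null(surrogateCenters) && length(surrogateCenters) >= 2) {
    surRaw <- .ccgLayer(trains, surrogateCenters, surrogateCenters,
                        halfWin, maxLagMs, binMs)
    surShift <- .ccgLayer(trains, surrogateCenters,
                          shiftOf(surrogateCenters), halfWin, maxLagMs,
                          binMs)
  } else {
    surRaw <- numeric(length(raw))
    surShift <- numeric(length(raw))
  }
  wb <- round(smoothingMs / binMs)
  smooth <- function(v) gaussianSmooth(v, wb)
  rawS <- smooth(raw); shiftS <- smooth(shift)
  surRawS <- smooth(surRaw); surShiftS <- smooth(surShift)
  corrected <- (rawS - shiftS) - (surRawS - surShiftS)
  nb <- length(raw)
  mid <- as.integer(maxLagMs / binMs) + 1L
  new("CcgResult",
      lagsMs = (seq_len(nb) - mid) * binMs,
      raw = rawS, shiftPredictor = shiftS, surrogateRaw = surRawS,
      surrogateShift = surShiftS, corrected = corrected,
      nPairs = as.integer(length(sel) * (length(sel) - 1L) / 2L),
      nEvents = length(eventMaxima), smoothingMs = smoothingMs)
}

#' Width of the significant co-firing cluster across sessions
#'
#' Cluster-based permutation test (sign-flip, two-tailed) of the corrected
#' CCG across sessions against zero; returns the width in ms of the
#' largest significant positive lag cluster, or 0 when none reaches
#' significance.
#'
#' @param ccgMatrix sessions x lags matrix of corrected CCGs.
#' @param binMs lag bin width, ms.
#' @param nPermutations,clusterAlpha,finalAlpha,seed test settings passed
#'   to [clusterPermutationVsZero()].
#' @return significant span, ms (a multiple of `binMs`).
#' @export
significantSpan <- function(ccgMatrix, binMs = 1, nPermutations = 1000,
                            clusterAlpha = 0.05, finalAlpha = 0.05,
                            seed = NULL) {
  if (nrow(ccgMatrix) < 2) stop("at least 2 sessions required")
  cr <- clusterPermutationVsZero(ccgMatrix, nPermutations = nPermutations,
                                 clusterAlpha = clusterAlpha,
                                 finalAlpha = finalAlpha, seed = seed)
  ids <- unique(cr@clusterId[cr@mask & cr@statistic > 0])
  ids <- ids[ids > 0]
  if (!length(ids)) return(0)
  max(vapply(ids, function(i) sum(cr@clusterId == i), numeric(1))) * binMs
}
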