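# Cross-regional analyses: event co-occurrence histograms, time-frequency
# phase-locking-value maps, and firing-rate network edges.

.sameHemiPairs <- function(channels, regionA, regionB) {
  pairs <- list()
  for (h in unique(channels$hemisphere)) {
    ia <- which(channels$region == regionA & channels$hemisphere == h)
    ib <- which(channels$region == regionB & channels$hemisphere == h)
    for (a in ia) for (b in ib) {
      if (a != b) pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  pairs
}

#' Cross-regional event-rate histogram
#'
#' Rate of target-region event centers around seed-region event centers,
#' pooled over all same-hemisphere contact pairs in both directions
#' (which makes the histogram symmetric in expectation), smoothed and
#' baseline-corrected as in [eventLockedRate()].
#'
#' @param events event data.frame ([detectEvents()] columns).
#' @param channels channel metadata (`contact_id`, `region`,
#'   `hemisphere`).
#' @param regionA,regionB region labels (seed and target; both directions
#'   are pooled).
#' @param type event type to use.
#' @param smoothingMs Gaussian width, ms (100 default; 10 for the
#'   high-resolution view of co-occurrence precision).
#' @inheritParams eventLockedRate
#' @return a [Peth-class].
#' @export
crossRegionalEventRate <- function(events, channels, regionA, regionB,
                                   type = "ripple",
                                   windowS = c(-1.5, 1.5),
                                   baselineWindowS = c(-1.5, -1),
                                   smoothingMs = 100, binWidthS = 0.001,
                                   durationS = NULL) {
  pairs <- .sameHemiPairs(channels, regionA, regionB)
  if (!length(pairs)) {
    stop("no same-hemisphere contact pairs between ", regionA, " and ",
         regionB)
  }
  ev <- events[events$type == type, ]
  counts <- NULL; nA <- 0L; centers <- NULL
  for (p in pairs) {
    for (dir in list(p, rev(p))) {
      seeds <- ev$center_s[ev$contact_id == channels$contact_id[dir[1]]]
      targets <- ev$center_s[ev$contact_id == channels$contact_id[dir[2]]]
      if (!length(seeds)) next
      rc <- .relCounts(seeds, targets, windowS, binWidthS, durationS)
      if (is.null(counts)) {
        counts <- rc$counts; centers <- rc$centers
      } else counts <- counts + rc$counts
      nA <- nA + rc$nAnchors
    }
  }
  if (is.null(counts) || nA == 0L) {
    stop("no seed events of type '", type, "' on the paired contacts")
  }
  .buildPeth(counts, centers, nA, 1, binWidthS, smoothingMs,
             baselineWindowS, paste0(regionA, ":", type),
             paste0(regionB, ":", type), "center")
}

#' Analysis-window length in cycles for a PLV frequency
#'
#' Whole number of cycles spanning at least five cycles and at least
#' 100 ms at frequency `f`.
#'
#' @param f frequency, Hz.
#' @return integer cycle count.
#' @export
plvWindowCycles <- function(f) {
  as.integer(ceiling(pmax(5, 0.1 * f) - 1e-9))
}

#' Event-locked time-frequency phase-locking-value map
#'
#' For each time step (25 ms) and frequency (1-150 Hz in 1-Hz steps by
#' default), the phase of each channel is estimated with a single
#' Hanning-tapered window spanning [plvWindowCycles()] cycles, and the PLV
#' is the modulus of the event-average unit phasor of the phase difference
#' between the two channels. The baseline-corrected map subtracts the
#' frequency-wise mean PLV over the baseline time bins. Anchors whose
#' largest analysis window leaves the recording are dropped.
#'
#' @param sigA,sigB numeric channel signals (same hemisphere).
#' @param fs sampling rate, Hz.
#' @param anchors event anchor times, s (>= 10 recommended).
#' @param timesS time-bin centers relative to the anchor, s.
#' @param freqsHz analysis frequencies, Hz.
#' @param baselineWindowS baseline time window, s (reuses the rate-PETH
#'   baselines).
#' @param seedType label stored in the result.
#' @return a [PlvMap-class].
#' @export
plvMap <- function(sigA, sigB, fs, anchors,
                   timesS = seq(-1.5, 1.5, by = 0.025),
                   freqsHz = 1:150,
                   baselineWindowS = c(-1.5, -1),
                   seedType = "event") {
  n <- length(sigA)
  if (length(sigB) != n) stop("channel signals must have equal length")
  maxWin <- max(plvWindowCycles(freqsHz) / freqsHz)
  ok <- anchors + min(timesS) - maxWin / 2 > 0 &
    anchors + max(timesS) + maxWin / 2 < n / fs
  dropped <- sum(!ok)
  if (dropped) {
    message(dropped, " anchor(s) dropped: analysis window exceeds the ",
            "recording")
  }
  anchors <- anchors[ok]
  if (length(anchors) < 2) stop("fewer than 2 usable anchors")
  nT <- length(timesS); nF <- length(freqsHz)
  plv <- matrix(0, nF, nT)
  for (fi in seq_len(nF)) {
    f <- freqsHz[fi]
    L <- round(plvWindowCycles(f) / f * fs)
    taper <- .hann(L)
    basis <- taper * exp(-2i * pi * f * (seq_len(L) - 1L) / fs)
    half <- floor(L / 2)
    for (ti in seq_len(nT)) {
      start <- round((anchors + timesS[ti]) * fs) - half
      idx <- rep(start, each = L) + seq_len(L) - 1L
      segA <- matrix(sigA[idx], nrow = L)
      segB <- matrix(sigB[idx], nrow = L)
      cA <- as.vector(crossprod(segA, basis))
      cB <- as.vector(crossprod(segB, basis))
      ph <- cA * Conj(cB)
      m <- Mod(ph)
      m[m == 0] <- 1
      plv[fi, ti] <- Mod(mean(ph / m))
    }
  }
  base <- timesS >= baselineWindowS[1] & timesS < baselineWindowS[2]
  if (!any(base)) stop("baseline window contains no time bins")
  corrected <- plv - rowMeans(plv[, base, drop = FALSE])
  new("PlvMap", timesS = timesS, freqsHz = as.numeric(freqsHz),
      plv = plv, baselineCorrected = corrected,
      nEvents = length(anchors), seedType = seedType,
      baselineWindow = as.numeric(baselineWindowS))
}

#' Cross-regional firing-rate network edge
#'
#' For each session, the baseline-corrected target-region firing rate in a
#' `windowMs` window centered on the seed-region event maximum, averaged
#' over all same-hemisphere contact pairs in both directions and over
#' hemispheres; the edge strength is the one-sample t value of the session
#' values against zero (both directions combined, so the edge is symmetric
#' in region order).
#'
#' @param sessions list of sessions, each a list with `events` (detected
#'   events data.frame), `spikes` ([SpikeTrains-class]), `channels`
#'   (channel metadata) and `durationS`.
#' @param regionA,regionB region labels.
#' @param type seed event type.
#' @param windowMs firing-rate window centered on the event maximum, ms.
#' @param baselineWindowS pre-event baseline window, s.
#' @return list: `regionPair`, `type`, `sessionValues` (Hz), `t`, `p`,
#'   `df`, `significant` (p < 0.05, two-tailed, uncorrected).
#' @export
crossRegionalFrEdge <- function(sessions, regionA, regionB,
                                type = "ripple", windowMs = 100,
                                baselineWindowS = c(-1.5, -1)) {
  if (length(sessions) < 2) stop("at least 2 sessions required")
  hw <- windowMs / 1000 / 2
  vals <- vapply(sessions, function(se) {
    pairs <- .sameHemiPairs(se$channels, regionA, regionB)
    if (!length(pairs)) return(NA_real_)
    ev <- se$events[se$events$type == type, ]
    wires <- wireInfo(se$spikes)
    pairVals <- c()
    for (p in pairs) {
      for (dir in list(p, rev(p))) {
        seedContact <- se$channels$contact_id[dir[1]]
        targContact <- se$channels$contact_id[dir[2]]
        anchors <- ev$max_s[ev$contact_id == seedContact]
        ww <- which(wires$contact_id == targContact)
        if (!length(anchors) || !length(ww)) next
        tt <- sort(unlist(spikeTimes(se$spikes)[ww]))
        nW <- length(ww)
        inWin <- vapply(anchors, function(a) {
          sum(tt >= a - hw & tt <= a + hw)
        }, numeric(1))
        inBase <- vapply(anchors, function(a) {
          sum(tt >= a + baselineWindowS[1] & tt < a + baselineWindowS[2])
        }, numeric(1))
        frWin <- mean(inWin) / (nW * 2 * hw)
        frBase <- mean(inBase) / (nW * diff(baselineWindowS))
        pairVals <- c(pairVals, frWin - frBase)
      }
    }
    if (!length(pairVals)) NA_real_ else mean(pairVals)
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) {
    stop("same-hemisphere ", regionA, "-", regionB,
         " pairs exist in fewer than 2 sessions")
  }
  if (stats::sd(vals) == 0) stop("zero variance across session values")
  tt <- stats::t.test(vals)
  list(regionPair = sort(c(regionA, regionB)), type = type,
       sessionValues = vals, t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter),
       significant = tt$p.value < 0.05)
}
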