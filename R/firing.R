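# Multiunit firing-rate analyses: wire inclusion, maximal event-locked
# rates, and time-by-time firing-rate x event-rate correlation maps.

#' Filter wires by minimum NREM firing rate
#'
#' Keeps wires whose firing rate over artifact-free NREM time is at least
#' `minFrHz` (the boundary is inclusive). With a recording, the NREM mask
#' of each wire's parent contact defines the usable time; without one,
#' `durationS` is used as the denominator.
#'
#' @param spikes a [SpikeTrains-class].
#' @param recording optional [SleepRecording-class].
#' @param minFrHz inclusion threshold, Hz.
#' @param durationS fallback duration, s, when no recording is given.
#' @return filtered [SpikeTrains-class]; errors if all wires drop out.
#' @export
wireInclusion <- function(spikes, recording = NULL, minFrHz = 1,
                          durationS = NULL) {
  w <- wireInfo(spikes)
  fr <- numeric(length(spikes))
  if (!is.null(recording)) {
    fs <- samplingRate(recording)
    chanOf <- match(w$contact_id, channelInfo(recording)$contact_id)
    masks <- list()
    for (i in seq_len(length(spikes))) {
      ch <- chanOf[i]
      key <- as.character(ch)
      if (is.null(masks[[key]])) masks[[key]] <- nremSamples(recording, ch)
      good <- masks[[key]]
      tt <- spikeTimes(spikes)[[i]]
      idx <- pmin(length(good), floor(tt * fs) + 1L)
      fr[i] <- sum(good[idx]) / (sum(good) / fs)
    }
  } else {
    if (is.null(durationS)) stop("durationS required without a recording")
    fr <- vapply(spikeTimes(spikes), length, 1L) / durationS
  }
  keep <- fr >= minFrHz
  if (!any(keep)) {
    stop("all wires fall below the ", minFrHz, "-Hz inclusion threshold")
  }
  SpikeTrains(spikeTimes(spikes)[keep], w[keep, , drop = FALSE])
}

#' Maximal baseline-corrected firing rate around an event
#'
#' @param peth a [Peth-class] from [firingRatePeth()].
#' @param windowS search window, s (default +/- 2 s of the event center).
#' @return maximal corrected rate in the window, Hz.
#' @export
maxFiringRate <- function(peth, windowS = c(-2, 2)) {
  ctr <- binCenters(peth)
  sel <- ctr >= windowS[1] & ctr <= windowS[2]
  if (!any(sel)) stop("window contains no histogram bins")
  max(rates(peth)[sel])
}

#' Interval means of an event-locked quantity
#'
#' Tiles the corrected rate of a [Peth-class] into non-overlapping
#' intervals (default 500 ms across +/- 2 s) and returns the mean per
#' interval, for the correlation-map analysis.
#'
#' @param peth a [Peth-class].
#' @param intervalS interval length, s. @param windowS tiled span, s.
#' @return named numeric, one mean per interval (names = centers, s).
#' @export
intervalMeans <- function(peth, intervalS = 0.5, windowS = c(-2, 2)) {
  edges <- seq(windowS[1], windowS[2], by = intervalS)
  ctr <- binCenters(peth)
  r <- rates(peth)
  out <- numeric(length(edges) - 1L)
  for (k in seq_along(out)) {
    sel <- ctr >= edges[k] & ctr < edges[k + 1L]
    out[k] <- mean(r[sel])
  }
  names(out) <- (edges[-length(edges)] + edges[-1]) / 2
  out
}

#' Time-by-time correlation of seed firing rates and target event rates
#'
#' For every pair of intervals (t1, t2), the Pearson correlation across
#' contacts between the seed-locked mean firing rate in t1 and the
#' seed-locked target event rate in t2. Positive cells below the diagonal
#' (t1 < t2) indicate firing rates that precede event occurrences. Cells
#' where either variable has zero variance across contacts are NA.
#'
#' @param frByContact matrix contacts x intervals of seed-locked mean
#'   firing rates (e.g. rows of [intervalMeans()] per contact).
#' @param rateByContact matrix contacts x intervals of seed-locked target
#'   event rates, same interval grid.
#' @param time1,time2 interval centers, s (defaults from column names).
#' @param seedType,targetType labels.
#' @return a [CorrelationMap-class].
#' @export
frEventRateCorrelation <- function(frByContact, rateByContact,
                                   time1 = NULL, time2 = NULL,
                                   seedType = "seed",
                                   targetType = "target") {
  frByContact <- as.matrix(frByContact)
  rateByContact <- as.matrix(rateByContact)
  if (nrow(frByContact) != nrow(rateByContact)) {
    stop("both matrices need one row per contact")
  }
  if (nrow(frByContact) < 3) {
    stop("at least 3 contacts required for the correlation map")
  }
  if (is.null(time1)) {
    time1 <- as.numeric(colnames(frByContact))
    if (any(is.na(time1))) time1 <- seq_len(ncol(frByContact))
  }
  if (is.null(time2)) {
    time2 <- as.numeric(colnames(rateByContact))
    if (any(is.na(time2))) time2 <- seq_len(ncol(rateByContact))
  }
  r <- matrix(NA_real_, ncol(frByContact), ncol(rateByContact))
  for (i in seq_len(ncol(frByContact))) {
    x <- frByContact[, i]
    if (stats::sd(x) == 0) next
    for (j in seq_len(ncol(rateByContact))) {
      y <- rateByContact[, j]
      if (stats::sd(y) == 0) next
      r[i, j] <- stats::cor(x, y)
    }
  }
  new("CorrelationMap", seedType = seedType, targetType = targetType,
      time1 = time1, time2 = time2, r = r,
      nContacts = nrow(frByContact))
}
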