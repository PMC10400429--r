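# Internal signal-conditioning helpers. All IIR filtering is zero-phase
# (forward-backward) Butterworth with odd-reflection padding so that edge
# transients and DC offsets do not leak into event timing.

.padLen <- function(n, fs, lowCornerHz) {
  # settle length ~ a few time constants of the lowest corner frequency
  want <- if (is.null(lowCornerHz) || lowCornerHz <= 0) round(fs)
          else round(3 * fs / lowCornerHz)
  min(n - 1L, max(100L, want))
}

.zeroPhase <- function(x, filt, fs, lowCornerHz = NULL) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  p <- .padLen(n, fs, lowCornerHz)
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' Two-pass (zero-phase) order-3 Butterworth band-pass with odd-reflection
#' edge padding.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2, corner frequencies in Hz.
#' @param order filter order (per pass).
#' @return filtered signal, same length as `x`.
#' @export
bandpassFilter <- function(x, fs, band, order = 3) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            band[2] < fs / 2)
  bf <- signal::butter(order, band * 2 / fs, type = "pass")
  .zeroPhase(x, bf, fs, band[1])
}

.highpassFilter <- function(x, fs, corner, order = 3) {
  bf <- signal::butter(order, corner * 2 / fs, type = "high")
  .zeroPhase(x, bf, fs, corner)
}

.lowpassFilter <- function(x, fs, corner, order = 3) {
  bf <- signal::butter(order, corner * 2 / fs, type = "low")
  .zeroPhase(x, bf, fs, corner)
}

.bandstopFilter <- function(x, fs, band, order = 3) {
  bf <- signal::butter(order, band * 2 / fs, type = "stop")
  .zeroPhase(x, bf, fs, band[1])
}

# centered moving average over an odd window, edges renormalized to the
# samples actually available (cumsum implementation)
.runningMean <- function(x, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding root-mean-square envelope
#'
#' RMS of `x` over a centered window of `windowS` seconds, optionally
#' followed by moving-average smoothing with the same window length (the
#' convention used by the spindle and ripple detectors).
#'
#' @param x numeric signal (typically band-pass filtered).
#' @param fs sampling rate, Hz.
#' @param windowS window length in seconds.
#' @param smooth logical; apply the extra moving-average pass.
#' @return numeric envelope, same length as `x`.
#' @export
runningRMS <- function(x, fs, windowS, smooth = TRUE) {
  w <- max(3L, round(windowS * fs))
  env <- sqrt(.runningMean(x^2, w))
  if (smooth) env <- .runningMean(env, w)
  env
}

# Gaussian kernel of total width `widthBins` bins, s.d. = width/5,
# truncated at the window edge and renormalized to unit sum
.gaussKernel <- function(widthBins) {
  h <- max(1L, floor(widthBins / 2))
  s <- widthBins / 5
  k <- exp(-0.5 * ((-h):h / s)^2)
  k / sum(k)
}

#' Gaussian smoothing with truncated-kernel edge renormalization
#'
#' Convolves `x` with a Gaussian window of total width `widthBins` bins
#' (s.d. = width / 5). At the edges the kernel is truncated to the samples
#' available and renormalized, so a flat input stays flat and interior mass
#' is conserved.
#'
#' @param x numeric vector.
#' @param widthBins total kernel width in bins.
#' @return smoothed vector, same length.
#' @export
gaussianSmooth <- function(x, widthBins) {
  if (widthBins < 2) return(x)
  k <- .gaussKernel(widthBins)
  n <- length(x)
  num <- stats::filter(c(x), k, sides = 2)
  den <- stats::filter(rep(1, n), k, sides = 2)
  y <- as.numeric(num / den)
  # stats::filter leaves NAs where the kernel would overhang; fill by
  # explicit truncated sums
  h <- (length(k) - 1L) %/% 2L
  nas <- which(is.na(y))
  for (i in nas) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    kk <- k[(lo - i + h + 1L):(hi - i + h + 1L)]
    y[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  y
}

# stage label per sample, from a 30-s-epoch hypnogram
.stagePerSample <- function(hyp, n, fs) {
  epoch <- pmin(nrow(hyp), floor((seq_len(n) - 1L) / fs / .EPOCH_S) + 1L)
  hyp$stage[epoch]
}

# half-open interval membership: TRUE for samples with time in [start, end)
.intervalMask <- function(n, fs, starts, ends) {
  m <- logical(n)
  if (!length(starts)) return(m)
  i0 <- pmax(1L, floor(starts * fs) + 1L)
  i1 <- pmin(n, ceiling(ends * fs))
  for (k in seq_along(i0)) if (i0[k] <= i1[k]) m[i0[k]:i1[k]] <- TRUE
  m
}

# runs of TRUE as a two-column matrix of sample indices [start, end]
.trueRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
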