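# Synthetic NREM session generator: 1/f background + planted SO half-wave
# pairs, waxing-waning spindles and sharp-wave ripple bursts, plus
# event-gain-modulated inhomogeneous Poisson multiunit spike trains.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 1/f^exponent Gaussian background of unit s.d.; returns the signal and the
# squared amplitude profile over positive frequencies (for in-band s.d.
# bookkeeping). The profile is flat below 0.1 Hz to avoid the DC divergence.
.shapedBackground <- function(n, fs, exponent) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  a <- pmax(f, 0.1)^(-exponent / 2)
  a[1] <- 0
  x <- stats::rnorm(n)
  y <- Re(stats::fft(stats::fft(x) * a, inverse = TRUE)) / n
  pos <- seq_len(floor(n / 2))
  list(x = y / stats::sd(y), amp2 = a[pos]^2, freqs = f[pos])
}

.bandSdFraction <- function(bg, band) {
  sel <- bg$freqs >= band[1] & bg$freqs <= band[2]
  sqrt(sum(bg$amp2[sel]) / sum(bg$amp2))
}

# event kernels in analysis convention (positive peaks = up-states)
.soKernel <- function(fs, freq, amp) {
  t <- seq(0, 1 / freq, by = 1 / fs)
  -amp * sin(2 * pi * freq * t)
}

.hann <- function(L) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L))

# tapered-cosine (Tukey) envelope: cosine ramps over `taper` of each end,
# flat plateau in between — the waxing/waning shape the detectors see
.tukey <- function(L, taper = 0.25) {
  t <- seq(0, 1, length.out = L)
  env <- rep(1, L)
  lo <- t < taper
  hi <- t > 1 - taper
  env[lo] <- 0.5 * (1 - cos(pi * t[lo] / taper))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - t[hi]) / taper))
  env
}

.spindleKernel <- function(fs, freq, dur, amp) {
  L <- round(dur * fs) + 1L
  t <- seq_len(L) / fs
  amp * .tukey(L) * sin(2 * pi * freq * t)
}

.rippleKernel <- function(fs, freq, dur, amp, sharpAmp) {
  L <- round(dur * fs) + 1L
  t <- seq_len(L) / fs
  burst <- amp * .tukey(L) * sin(2 * pi * freq * t)
  sw <- -sharpAmp * exp(-0.5 * ((t - dur / 2) / (dur / 3))^2)
  burst + sw
}

# uniform placement with minimum separation and forbidden intervals;
# errors naming the binding constraint when the session cannot host the
# requested count
.placeCenters <- function(count, duration, margin, minSep,
                          forbidden = NULL, avoid = numeric(),
                          avoidSep = 0, what = "event") {
  if (count == 0) return(numeric())
  lo <- margin; hi <- duration - margin
  if (hi <= lo) {
    stop("duration_s too short to place ", what,
         "s: needs > ", 2 * margin, " s")
  }
  placed <- numeric()
  tries <- 0L
  maxTries <- 200L * count
  while (length(placed) < count && tries < maxTries) {
    tries <- tries + 1L
    cand <- stats::runif(1, lo, hi)
    if (length(placed) && min(abs(placed - cand)) < minSep) next
    if (length(avoid) && min(abs(avoid - cand)) < avoidSep) next
    if (!is.null(forbidden) && nrow(forbidden) &&
        any(cand >= forbidden[, 1] & cand <= forbidden[, 2])) next
    placed <- c(placed, cand)
  }
  if (length(placed) < count) {
    stop(sprintf(
      paste0("duration too short to place the requested %d %ss ",
             "(placed %d; binding constraint: %.3g-s minimum separation ",
             "within %.3g usable seconds)"),
      count, what, length(placed), minSep, hi - lo))
  }
  sort(placed)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0 || hi <= lo) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.defaultHypnogram <- function(duration, wakeBlocks = 0) {
  nEp <- ceiling(duration / .EPOCH_S)
  stage <- rep(rep(c("N2", "N3"), each = 10), length.out = nEp)
  if (wakeBlocks > 0) {
    at <- round(seq(1, nEp - 1, length.out = wakeBlocks + 2))[-c(1, wakeBlocks + 2)]
    for (a in at) stage[a:min(nEp, a + 1)] <- "W"
  }
  data.frame(epoch_start_s = (seq_len(nEp) - 1) * .EPOCH_S, stage = stage)
}

.eventRow <- function(type, contact, onset, center, mx, offset, amp, gain) {
  data.frame(type = type, contact_id = contact, onset_s = onset,
             center_s = center, max_s = mx, offset_s = offset,
             amp = amp, gain = gain, duration_s = offset - onset)
}

#' Simulate a synthetic NREM session
#'
#' Generates a ground-truth session: multichannel LFP (1/f background with
#' planted SOs, spindles and ripples, plus optional high-amplitude artifact
#' transients), an all-N2/N3 hypnogram (optionally interrupted by wake
#' blocks) and inhomogeneous-Poisson multiunit spike trains whose rate is
#' multiplied by the configured gain inside each planted event (and
#' suppressed in SO down-states). Identical seeds give identical output.
#'
#' @param config a [simConfig()] object.
#' @param convention `"analysis"` (default) emits the signal with positive
#'   peaks as up-states and marks the recording preprocessed, ready for the
#'   detectors; `"recorded"` emits the inverted raw polarity for exercising
#'   [preprocessSignal()].
#' @return list with elements `recording` ([SleepRecording-class]),
#'   `spikes` ([SpikeTrains-class]) and `truth` (list: `events` data.frame
#'   with planted type/contact/onset/center/max/offset/amplitude/gain,
#'   `artifacts` data.frame of planted artifact intervals, `bandSd` the
#'   per-band background s.d. used for amplitude scaling).
#' @examples
#' sess <- simulateSession(simConfig(duration_s = 120, n_contacts = 1,
#'                                   artifact_rate = 0, seed = 3))
#' sess$recording
#' @export
simulateSession <- function(config, convention = c("analysis", "recorded")) {
  validateSimConfig(config)
  convention <- match.arg(convention)
  .withSeed(config$seed, {
    fs <- config$fs
    dur <- config$duration_s
    n <- round(dur * fs)
    nc <- config$n_contacts
    minutes <- dur / 60

    hyp <- .defaultHypnogram(dur, config$wake_blocks)
    wake <- hyp[hyp$stage %in% c("W", "N1", "REM"), , drop = FALSE]
    wakeIv <- if (nrow(wake))
      cbind(wake$epoch_start_s - 1.5, wake$epoch_start_s + .EPOCH_S + 1.5)
    else matrix(numeric(), 0, 2)

    soDur <- 1 / config$so_freq
    spDur <- config$spindle_duration_s
    ripDur <- config$ripple_duration_s

    # per-contact gain heterogeneity (common factor on FR-gain excess and
    # nesting probability; drives the FR x event-rate correlation surface)
    gmul <- if (config$contact_gain_spread > 0)
      exp(stats::rnorm(nc, 0, config$contact_gain_spread)) else rep(1, nc)

    sig <- matrix(0, n, nc)
    events <- list()
    arts <- list()
    bandSd <- NULL

    for (ci in seq_len(nc)) {
      bg <- .shapedBackground(n, fs, config$background_exponent)
      if (is.null(bandSd)) {
        bandSd <- c(
          so = config$background_sd * .bandSdFraction(bg, c(0.3, 1.25)),
          spindle = config$background_sd * .bandSdFraction(bg, c(12, 16)),
          ripple = config$background_sd * .bandSdFraction(bg, c(80, 120)))
      }
      x <- bg$x * config$background_sd

      # artifacts first: events must avoid them
      nArt <- stats::rpois(1, config$artifact_rate * minutes)
      artC <- if (nArt > 0)
        .placeCenters(nArt, dur, margin = 5, minSep = 10,
                      forbidden = wakeIv, what = "artifact")
      else numeric()
      for (a in artC) {
        idx <- round((a - 0.1) * fs):round((a + 0.1) * fs)
        idx <- idx[idx >= 1 & idx <= n]
        t0 <- idx / fs - a
        x[idx] <- x[idx] + sample(c(-1, 1), 1) * 8 * config$background_sd *
          exp(-0.5 * (t0 / 0.025)^2)
      }
      if (length(artC)) {
        arts[[ci]] <- data.frame(contact_id = ci, start_s = artC - 0.1,
                                 end_s = artC + 0.1)
      }
      forb <- rbind(wakeIv,
                    if (length(artC)) cbind(artC - 2, artC + 2))

      gSo <- 1 + gmul[ci] * (config$gain_so - 1)
      gSp <- 1 + gmul[ci] * (config$gain_spindle - 1)
      gRip <- 1 + gmul[ci] * (config$gain_ripple - 1)
      pRip <- min(1, config$p_ripple_in_spindle * gmul[ci])

      ev <- list()

      # --- SOs ---
      nSo <- stats::rpois(1, config$so_rate * minutes)
      soOn <- .placeCenters(nSo, dur, margin = 3, minSep = soDur + 3,
                            forbidden = forb, what = "SO") - soDur / 4
      for (s in soOn) {
        ev[[length(ev) + 1L]] <- .eventRow(
          "so", ci, s, s + soDur / 4, s + 3 * soDur / 4, s + soDur,
          config$event_snr * bandSd["so"], gSo)
      }

      # --- spindles: nested in SO up-states + independent ---
      spC <- numeric()
      for (s in soOn) {
        if (stats::runif(1) < config$p_spindle_in_so) {
          mx <- s + 3 * soDur / 4
          spC <- c(spC, .rtruncnorm(1, mx + config$so_spindle_lag_s,
                                    config$so_spindle_lag_sd_s,
                                    mx - soDur / 8, mx + soDur / 8))
        }
      }
      nSpInd <- stats::rpois(1, config$spindle_rate * minutes)
      soCenters <- soOn + soDur / 4
      spInd <- if (nSpInd > 0)
        .placeCenters(nSpInd, dur, margin = 3, minSep = spDur + 3,
                      forbidden = forb,
                      avoid = c(soCenters, spC), avoidSep = 2.5,
                      what = "spindle")
      else numeric()
      spC <- sort(c(spC, spInd))
      for (s in spC) {
        ev[[length(ev) + 1L]] <- .eventRow(
          "spindle", ci, s - spDur / 2, s, s, s + spDur / 2,
          config$event_snr * bandSd["spindle"], gSp)
      }

      # --- ripples: nested strictly inside spindles + independent ---
      ripC <- numeric()
      for (s in spC) {
        if (stats::runif(1) < pRip) {
          lo <- s - spDur / 2 + ripDur / 2 + 0.01
          hi <- s + spDur / 2 - ripDur / 2 - 0.01
          ripC <- c(ripC, .rtruncnorm(1, s + config$spindle_ripple_lag_s,
                                      config$spindle_ripple_lag_sd_s,
                                      lo, hi))
        }
      }
      nRipInd <- stats::rpois(1, config$ripple_rate * minutes)
      ripInd <- if (nRipInd > 0)
        .placeCenters(nRipInd, dur, margin = 3, minSep = 1,
                      forbidden = forb,
                      avoid = c(spC, ripC),
                      avoidSep = spDur / 2 + 1.5, what = "ripple")
      else numeric()
      ripC <- sort(c(ripC, ripInd))
      for (s in ripC) {
        ev[[length(ev) + 1L]] <- .eventRow(
          "ripple", ci, s - ripDur / 2, s, s, s + ripDur / 2,
          config$event_snr * bandSd["ripple"], gRip)
      }
      events[[ci]] <- if (length(ev)) do.call(rbind, ev) else NULL
      sig[, ci] <- x
    }

    evAll <- do.call(rbind, events)
    if (is.null(evAll)) {
      evAll <- .eventRow(character(), integer(), numeric(), numeric(),
                         numeric(), numeric(), numeric(), numeric())
    }

    # cross-contact mirroring on same-hemisphere contacts
    if (config$cross_sync_prob > 0 && nc > 1 && nrow(evAll)) {
      extra <- list()
      for (k in seq_len(nrow(evAll))) {
        e <- evAll[k, ]
        mates <- which(config$hemispheres ==
                         config$hemispheres[e$contact_id])
        mates <- setdiff(mates, e$contact_id)
        for (m in mates) {
          if (stats::runif(1) >= config$cross_sync_prob) next
          shift <- stats::rnorm(1, 0, config$cross_sync_jitter_s)
          cand <- e
          cand$contact_id <- m
          cand[c("onset_s", "center_s", "max_s", "offset_s")] <-
            cand[c("onset_s", "center_s", "max_s", "offset_s")] + shift
          if (cand$onset_s < 1 || cand$offset_s > dur - 1) next
          same <- evAll[evAll$contact_id == m & evAll$type == e$type, ]
          sep <- if (e$type == "ripple") 1 else 3
          if (nrow(same) &&
              min(abs(same$center_s - cand$center_s)) < sep) next
          extra[[length(extra) + 1L]] <- cand
        }
      }
      if (length(extra)) evAll <- rbind(evAll, do.call(rbind, extra))
    }
    evAll <- evAll[order(evAll$contact_id, evAll$onset_s), ]
    rownames(evAll) <- NULL

    # stamp kernels
    for (k in seq_len(nrow(evAll))) {
      e <- evAll[k, ]
      kern <- switch(e$type,
        so = .soKernel(fs, config$so_freq, e$amp),
        spindle = .spindleKernel(fs, config$spindle_freq, spDur, e$amp),
        ripple = .rippleKernel(fs, config$ripple_freq, ripDur, e$amp,
                               1.5 * config$background_sd))
      i0 <- round(e$onset_s * fs) + 1L
      idx <- i0:(i0 + length(kern) - 1L)
      keep <- idx >= 1 & idx <= n
      sig[idx[keep], e$contact_id] <- sig[idx[keep], e$contact_id] +
        kern[keep]
    }

    # spike trains: per-contact gain grid at 1-ms resolution
    gridFs <- 1000
    ng <- ceiling(dur * gridFs)
    wires <- data.frame(
      contact_id = rep(seq_len(nc), each = config$n_wires_per_contact),
      wire_id = rep(seq_len(config$n_wires_per_contact), nc))
    trains <- vector("list", nrow(wires))
    gi <- function(t) pmin(ng, pmax(1L, floor(t * gridFs) + 1L))
    for (ci in seq_len(nc)) {
      gain <- rep(1, ng)
      ce <- evAll[evAll$contact_id == ci, , drop = FALSE]
      for (k in seq_len(nrow(ce))) {
        e <- ce[k, ]
        if (e$type == "so") {
          dn <- gi(e$center_s - 0.25):gi(e$center_s + 0.25)
          up <- gi(e$max_s - 0.25):gi(e$max_s + 0.25)
          gain[dn] <- gain[dn] * config$gain_so_down
          gain[up] <- gain[up] * e$gain
        } else {
          span <- gi(e$onset_s):gi(e$offset_s)
          gain[span] <- gain[span] * e$gain
          if (e$type == "ripple" && config$ripple_ramp_s > 0) {
            ramp <- gi(e$onset_s - config$ripple_ramp_s):gi(e$onset_s)
            gain[ramp] <- gain[ramp] *
              seq(1, e$gain, length.out = length(ramp))
          }
        }
      }
      gmax <- max(gain)
      for (wi in which(wires$contact_id == ci)) {
        nSp <- stats::rpois(1, config$baseline_spike_rate * gmax * dur)
        tt <- sort(stats::runif(nSp, 0, dur))
        keep <- stats::runif(nSp) < gain[gi(tt)] / gmax
        trains[[wi]] <- tt[keep]
      }
    }

    if (convention == "recorded") sig <- -sig
    chan <- data.frame(contact_id = seq_len(nc),
                       region = config$region_labels,
                       hemisphere = config$hemispheres)
    rec <- SleepRecording(sig, fs, chan, hyp)
    rec@preprocessed <- convention == "analysis"
    spikes <- SpikeTrains(trains, wires)
    truth <- list(
      events = evAll,
      artifacts = if (length(arts)) do.call(rbind, arts)
                  else data.frame(contact_id = integer(),
                                  start_s = numeric(), end_s = numeric()),
      bandSd = bandSd, config = config)
    list(recording = rec, spikes = spikes, truth = truth)
  })
}

#' Inject short-latency co-firing into simulated spike trains
#'
#' Within each planted event, adds `cofire_pairs_per_event` synchronous
#' spike pairs across randomly chosen wire pairs of the event's contact,
#' with the second spike lagged by a zero-mean normal draw of s.d.
#' `cofire_jitter_ms[type]`. Existing spikes are conserved.
#'
#' @param spikes a [SpikeTrains-class] from [simulateSession()].
#' @param truth the `truth` element returned by [simulateSession()].
#' @param config the session's [simConfig()].
#' @return a new [SpikeTrains-class] with the injected pairs.
#' @export
plantCofiring <- function(spikes, truth, config) {
  if (any(config$cofire_jitter_ms < 0)) {
    stop("cofire_jitter_ms must be >= 0")
  }
  ev <- truth$events
  trains <- spikes@times
  wires <- spikes@wires
  .withSeed(config$seed + 999983L, {
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      ww <- which(wires$contact_id == e$contact_id)
      if (length(ww) < 2) next
      jit <- config$cofire_jitter_ms[[e$type]] / 1000
      for (p in seq_len(config$cofire_pairs_per_event)) {
        pick <- sample(ww, 2)
        tref <- stats::runif(1, e$onset_s, e$offset_s)
        lag <- if (jit > 0) stats::rnorm(1, 0, jit) else 0
        trains[[pick[1]]] <- c(trains[[pick[1]]], tref)
        trains[[pick[2]]] <- c(trains[[pick[2]]], tref + lag)
      }
    }
    SpikeTrains(lapply(trains, sort), wires)
  })
}
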