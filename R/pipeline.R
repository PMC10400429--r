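# End-to-end driver and the frozen default configuration.

#' Default analysis configuration
#'
#' All detector, histogram, CCG, PLV and statistics settings with their
#' standard values: SO band 0.3-1.25 Hz with 0.8-2-s candidates and a
#' mean + 1 s.d. amplitude criterion; spindle band 12-16 Hz with 200-ms
#' RMS windows, 0.4-3-s durations, 6 cycles and a mean + 9 s.d. upper
#' cutoff; ripple band 80-120 Hz with 20-ms windows, mean + 3 s.d.
#' detection and + 9 s.d. cutoff, 38-200-ms durations and 3 cycles;
#' +/-1-Hz line-noise notches; 1-ms histogram bins with a 100-ms Gaussian
#' kernel and pre-event baselines (-2.5 to -2 s for SOs and spindles,
#' -1.5 to -1 s for ripples); +/-50-ms CCG lags in 150-ms windows with a
#' 5-ms kernel and a 1-Hz wire-inclusion floor; PLV over 1-150 Hz in 1-Hz
#' and 25-ms steps; 1,000 permutations at cluster and final thresholds of
#' 0.05, two-tailed.
#'
#' @return nested list of settings.
#' @export
pipelineConfig <- function() {
  list(
    preprocess = list(target_fs = 1000, line_hz = 50,
                      notch_halfwidth_hz = 1, highpass_hz = 0.1),
    artifact = list(z_high = 6, z_low = 4, merge_s = 3, pad_s = 1),
    so = list(band_hz = c(0.3, 1.25), duration_s = c(0.8, 2),
              amp_sd = 1),
    spindle = list(band_hz = c(12, 16), rms_window_s = 0.2,
                   duration_s = c(0.4, 3), min_cycles = 6, thr_sd = 1,
                   upper_sd = 9),
    ripple = list(band_hz = c(80, 120), rms_window_s = 0.02,
                  duration_s = c(0.038, 0.2), min_cycles = 3, thr_sd = 3,
                  upper_sd = 9),
    peth = list(bin_s = 0.001, smoothing_ms = 100,
                baseline_s = list(so = c(-2.5, -2),
                                  spindle = c(-2.5, -2),
                                  ripple = c(-1.5, -1))),
    ccg = list(window_s = 0.15, max_lag_ms = 50, bin_ms = 1,
               smoothing_ms = 5, min_wire_fr_hz = 1),
    surrogate = list(window_s = 600, sd_s = 150, pad_s = 1.5),
    plv = list(freq_range_hz = c(1, 150), freq_step_hz = 1,
               time_step_s = 0.025, min_cycles = 5, min_window_s = 0.1),
    stats = list(n_permutations = 1000, cluster_alpha = 0.05,
                 final_alpha = 0.05, tails = 2)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, " stage failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline on one session directory
#'
#' Reads a session (see [readSession()]), preprocesses and artifact-masks
#' the signal, detects SOs, spindles and ripples on every channel, draws
#' ripple surrogates, and writes event tables, event-coupling and
#' firing-rate histograms, per-contact ripple CCGs and a run manifest to
#' `outDir`. Stage failures abort with a stage-named diagnostic.
#'
#' @param inputDir session directory.
#' @param outDir output directory (created).
#' @param config settings from [pipelineConfig()].
#' @param seed integer seed for surrogate draws.
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(inputDir, outDir, config = pipelineConfig(),
                        seed = 1) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", outDir)
  sess <- .stage("read", readSession(inputDir))
  rec <- sess$recording
  if (!rec@preprocessed) {
    rec <- .stage("preprocess",
                  preprocessSignal(rec, config$preprocess$line_hz,
                                   config$preprocess$target_fs))
  }
  rec <- .stage("artifact", detectArtifacts(
    rec, config$artifact$z_high, config$artifact$z_low,
    config$artifact$merge_s, config$artifact$pad_s))
  events <- .stage("detect", detectEvents(rec))
  writeEventsTsv(events, file.path(outDir, "events.tsv"))
  writeEventsTsv(artifactIntervals(rec),
                 file.path(outDir, "artifacts.tsv"))
  dur <- recordingDuration(rec)
  fs <- samplingRate(rec)
  chans <- channelInfo(rec)

  # per-type coupling and firing-rate histograms, contacts aggregated
  # with event-count weights
  .stage("couple", {
    combos <- list(c("so", "spindle"), c("so", "ripple"),
                   c("spindle", "ripple"))
    for (cb in combos) {
      base <- config$peth$baseline_s[[cb[1]]]
      win <- c(-2.5, 2.5)
      acc <- NULL; wts <- c()
      for (ch in seq_len(nrow(chans))) {
        cid <- chans$contact_id[ch]
        A <- events$center_s[events$type == cb[1] &
                               events$contact_id == cid]
        B <- events$center_s[events$type == cb[2] &
                               events$contact_id == cid]
        if (length(A) < 1) next
        p <- eventLockedRate(A, B, win, base,
                             binWidthS = config$peth$bin_s,
                             smoothingMs = config$peth$smoothing_ms,
                             durationS = dur, anchorType = cb[1],
                             targetType = cb[2])
        acc <- rbind(acc, rates(p))
        wts <- c(wts, nAnchors(p))
      }
      if (is.null(acc)) next
      sessionRate <- apply(acc, 2, aggregateSessions, counts = wts)
      utils::write.table(
        data.frame(bin_center_s = binCenters(p), rate_hz = sessionRate),
        file.path(outDir, sprintf("peth_%s_%s.tsv", cb[1], cb[2])),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  })

  if (!is.null(sess$spikes)) {
    .stage("fr", {
      spk <- wireInclusion(sess$spikes, rec,
                           config$ccg$min_wire_fr_hz)
      for (ty in .EVENT_TYPES) {
        base <- config$peth$baseline_s[[ty]]
        acc <- NULL; wts <- c(); p <- NULL
        for (ch in seq_len(nrow(chans))) {
          cid <- chans$contact_id[ch]
          A <- events$center_s[events$type == ty &
                                 events$contact_id == cid]
          if (length(A) < 1) next
          if (!any(wireInfo(spk)$contact_id == cid)) next
          p <- firingRatePeth(spk, A, c(-2.5, 2.5), base,
                              contact = cid,
                              binWidthS = config$peth$bin_s,
                              smoothingMs = config$peth$smoothing_ms,
                              durationS = dur, anchorType = ty)
          acc <- rbind(acc, rates(p))
          wts <- c(wts, nAnchors(p))
        }
        if (is.null(acc)) next
        sessionRate <- apply(acc, 2, aggregateSessions, counts = wts)
        utils::write.table(
          data.frame(bin_center_s = binCenters(p),
                     fr_hz = sessionRate),
          file.path(outDir, sprintf("fr_peth_%s.tsv", ty)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    })

    .stage("ccg", {
      spk <- wireInclusion(sess$spikes, rec, config$ccg$min_wire_fr_hz)
      for (ch in seq_len(nrow(chans))) {
        cid <- chans$contact_id[ch]
        ev <- events[events$type == "ripple" &
                       events$contact_id == cid, ]
        if (nrow(ev) < 2 ||
            sum(wireInfo(spk)$contact_id == cid) < 2) next
        sur <- matchSurrogates(ev, ev, dur,
                               good = nremSamples(rec, ch), fs = fs,
                               seed = seed + ch,
                               windowS = config$surrogate$window_s,
                               sdS = config$surrogate$sd_s,
                               padS = config$surrogate$pad_s)
        ccg <- eventLockedCcg(spk, ev$max_s, sur$center_s,
                              contact = cid,
                              windowS = config$ccg$window_s,
                              maxLagMs = config$ccg$max_lag_ms,
                              binMs = config$ccg$bin_ms,
                              smoothingMs = config$ccg$smoothing_ms)
        utils::write.table(
          data.frame(lag_ms = lags(ccg), raw = ccg@raw,
                     shift_predictor = ccg@shiftPredictor,
                     corrected = ccg@corrected),
          file.path(outDir, sprintf("ccg_ripple_contact%s.tsv", cid)),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepCoupling")),
    r_version = R.version.string,
    seed = seed,
    input = normalizePath(inputDir),
    config = config,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}
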