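test_that("identical seeds give identical sessions", {
  cfg <- simConfig(duration_s = 120, n_contacts = 1, so_rate = 2,
                   spindle_rate = 1, ripple_rate = 2, seed = 7)
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(signalMatrix(a$recording), signalMatrix(b$recording))
  expect_identical(spikeTimes(a$spikes), spikeTimes(b$spikes))
  expect_identical(a$truth$events, b$truth$events)
})

test_that("zero event rates give pure background and empty ground truth", {
  cfg <- simConfig(duration_s = 120, n_contacts = 1, so_rate = 0,
                   spindle_rate = 0, ripple_rate = 0, artifact_rate = 0,
                   seed = 3)
  sess <- simulateSession(cfg)
  expect_equal(nrow(sess$truth$events), 0)
  x <- signalMatrix(sess$recording)[, 1]
  # background s.d. close to the configured broadband level
  expect_lt(abs(sd(x) - cfg$background_sd) / cfg$background_sd, 0.1)
  # spikes at the baseline rate
  fr <- length(spikeTimes(sess$spikes)[[1]]) / 120
  expect_lt(abs(fr - cfg$baseline_spike_rate), 3 * sqrt(5 * 120) / 120)
})

test_that("planted independent-ripple counts follow the Poisson law", {
  cfg <- simConfig(duration_s = 1800, n_contacts = 1, so_rate = 0,
                   spindle_rate = 0, ripple_rate = 3,
                   p_spindle_in_so = 0, p_ripple_in_spindle = 0,
                   artifact_rate = 0, seed = 19)
  sess <- simulateSession(cfg)
  n <- sum(sess$truth$events$type == "ripple")
  bounds <- qpois(c(0.005, 0.995), 3 * 30)
  expect_gte(n, bounds[1])
  expect_lte(n, bounds[2])
})

test_that("spike-rate gain inside events matches the configured gain", {
  cfg <- simConfig(duration_s = 1800, n_contacts = 2, so_rate = 0,
                   spindle_rate = 4, ripple_rate = 0,
                   p_spindle_in_so = 0, p_ripple_in_spindle = 0,
                   cross_sync_prob = 0, artifact_rate = 0,
                   gain_spindle = 2, seed = 23)
  sess <- simulateSession(cfg)
  ev <- sess$truth$events
  expect_gt(nrow(ev), 150)
  w <- wireInfo(sess$spikes)
  nIn <- nOut <- tIn <- tOut <- 0
  for (ci in 1:2) {
    e <- ev[ev$contact_id == ci, ]
    tt <- sort(unlist(spikeTimes(sess$spikes)[w$contact_id == ci]))
    inside <- rep(FALSE, length(tt))
    span <- 0
    for (k in seq_len(nrow(e))) {
      inside <- inside | (tt >= e$onset_s[k] & tt <= e$offset_s[k])
      span <- span + e$duration_s[k]
    }
    nW <- sum(w$contact_id == ci)
    nIn <- nIn + sum(inside); tIn <- tIn + span * nW
    nOut <- nOut + sum(!inside); tOut <- tOut + (1800 - span) * nW
  }
  ratio <- (nIn / tIn) / (nOut / tOut)
  se <- ratio * sqrt(1 / nIn + 1 / nOut)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("planted spectral peaks fall inside the detection bands", {
  sess <- smallSession()
  x <- signalMatrix(sess$recording)[, 1]
  ev <- sess$truth$events
  fs <- 1000
  peakFreq <- function(type, search) {
    e <- ev[ev$type == type, ][1, ]
    idx <- round(e$onset_s * fs):round(e$offset_s * fs)
    seg <- x[idx] - mean(x[idx])
    sp <- Mod(fft(seg))^2
    fr <- (seq_along(sp) - 1) * fs / length(sp)
    sel <- fr >= search[1] & fr <= search[2]
    fr[sel][which.max(sp[sel])]
  }
  f <- peakFreq("spindle", c(5, 45))
  expect_gte(f, 12); expect_lte(f, 16)
  f <- peakFreq("ripple", c(40, 200))
  expect_gte(f, 80); expect_lte(f, 120)
})

test_that("ground truth obeys the nesting and artifact invariants", {
  sd <- detectedSession()
  sess <- sd$sess
  ev <- sess$truth$events
  dur <- recordingDuration(sess$recording)
  expect_true(all(ev$onset_s > 0 & ev$offset_s < dur))
  expect_true(all(ev$onset_s < ev$offset_s))
  # no planted event intersects a planted artifact
  art <- sess$truth$artifacts
  for (k in seq_len(nrow(art))) {
    same <- ev[ev$contact_id == art$contact_id[k], ]
    expect_false(any(same$onset_s < art$end_s[k] &
                       same$offset_s > art$start_s[k]))
  }
  # ripples whose center lies in a spindle lie strictly inside its span
  sp <- ev[ev$type == "spindle", ]
  rp <- ev[ev$type == "ripple", ]
  for (k in seq_len(nrow(rp))) {
    host <- sp[sp$contact_id == rp$contact_id[k] &
                 sp$onset_s <= rp$center_s[k] &
                 sp$offset_s >= rp$center_s[k], ]
    if (nrow(host)) {
      expect_gt(rp$onset_s[k], host$onset_s[1])
      expect_lt(rp$offset_s[k], host$offset_s[1])
    }
  }
  # nested spindle centers sit in the SO up-state window
  so <- ev[ev$type == "so", ]
  for (k in seq_len(nrow(sp))) {
    host <- so[so$contact_id == sp$contact_id[k] &
                 abs(so$max_s - sp$center_s[k]) <= 0.5, ]
    if (nrow(host)) {
      expect_gte(sp$center_s[k], host$center_s[1])
      expect_lte(sp$center_s[k], host$offset_s[1] + 0.2)
    }
  }
})

test_that("a session too short for the requested events errors clearly", {
  cfg <- simConfig(duration_s = 60.5, n_contacts = 1, so_rate = 60,
                   artifact_rate = 0, seed = 2)
  expect_error(simulateSession(cfg), "duration too short")
})

test_that("zero cofiring jitter injects exactly synchronous pairs", {
  cfg <- simConfig(duration_s = 120, n_contacts = 1, so_rate = 0,
                   spindle_rate = 2, ripple_rate = 0,
                   p_spindle_in_so = 0, p_ripple_in_spindle = 0,
                   baseline_spike_rate = 0, artifact_rate = 0,
                   cofire_jitter_ms = c(so = 0, spindle = 0, ripple = 0),
                   cofire_pairs_per_event = 3, seed = 13)
  sess <- simulateSession(cfg)
  spk <- plantCofiring(sess$spikes, sess$truth, cfg)
  tt <- sort(unlist(spikeTimes(spk)))
  nEv <- nrow(sess$truth$events)
  expect_equal(length(tt), 2 * 3 * nEv)
  # every injected timestamp appears exactly twice (one pair, two wires)
  expect_true(all(table(tt) == 2))
  # negative jitter is rejected
  bad <- cfg
  bad$cofire_jitter_ms <- c(so = -1, spindle = 0, ripple = 0)
  expect_error(plantCofiring(sess$spikes, sess$truth, bad), "jitter")
})

test_that("fixture write/read round-trips the session", {
  sess <- smallSession()
  dir <- withr::local_tempdir()
  writeFixture(sess$recording, sess$spikes, sess$truth, dir)
  back <- readSession(dir)
  expect_equal(signalMatrix(back$recording),
               signalMatrix(sess$recording), tolerance = 1e-6)
  expect_equal(samplingRate(back$recording),
               samplingRate(sess$recording))
  expect_equal(channelInfo(back$recording)$region,
               channelInfo(sess$recording)$region)
  expect_equal(unname(unlist(spikeTimes(back$spikes))),
               unlist(spikeTimes(sess$spikes)), tolerance = 1e-6)
  # ground-truth TSV rows equal planted events
  tsv <- read.delim(file.path(dir, "events_truth.tsv"))
  expect_equal(nrow(tsv), nrow(sess$truth$events))
  # hypnogram covers the session in contiguous 30-s epochs
  hyp <- read.delim(file.path(dir, "hypnogram.tsv"))
  expect_equal(hyp$epoch_start_s, seq(0, by = 30,
                                      length.out = nrow(hyp)))
  expect_gte(max(hyp$epoch_start_s) + 30,
             recordingDuration(sess$recording))
})
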