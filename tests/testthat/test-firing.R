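poissonTrains <- function(nWires, rateHz, durS, contact = 1, seed = 1) {
  set.seed(seed)
  SpikeTrains(
    lapply(seq_len(nWires), function(i) {
      sort(runif(rpois(1, rateHz * durS), 0, durS))
    }),
    data.frame(contact_id = contact, wire_id = seq_len(nWires)))
}

test_that("event-independent spikes give a flat corrected FR histogram", {
  spk <- poissonTrains(8, 5, 3600, seed = 31)
  set.seed(32)
  # non-overlapping anchor windows so per-bin counts are independent
  anchors <- seq(10, 3590, by = 12) + runif(299, 0, 3)
  p <- firingRatePeth(spk, anchors, c(-2.5, 2.5), c(-2.5, -2),
                      durationS = 3600)
  # per-bin s.e. of the smoothed rate: the 100-ms Gaussian kernel
  # (s.d. 20 ms) averages over sqrt(4*pi)*20 ~ 71 ms effectively
  se <- sqrt(5 / (length(anchors) * 8 * 0.071))
  z <- rates(p) / se
  expect_lt(mean(abs(z) > 3), 0.05)
  expect_lt(max(abs(z)), 5)
})

test_that("SO down-state suppression produces below-baseline firing", {
  cfg <- simConfig(duration_s = 900, n_contacts = 1, spindle_rate = 0,
                   ripple_rate = 0, p_spindle_in_so = 0,
                   artifact_rate = 0, cross_sync_prob = 0,
                   gain_so_down = 0.2, seed = 33)
  sess <- simulateSession(cfg)
  ev <- sess$truth$events
  p <- firingRatePeth(sess$spikes, ev$center_s[ev$type == "so"],
                      c(-2.5, 2.5), c(-2.5, -2), durationS = 900)
  ctr <- binCenters(p)
  down <- ctr > -0.15 & ctr < 0.15    # inside the down-state window
  expect_lt(mean(rates(p)[down]), 0)
  # up-state above baseline
  mx <- mean(ev$max_s[ev$type == "so"] - ev$center_s[ev$type == "so"])
  up <- abs(ctr - mx) < 0.15
  expect_gt(mean(rates(p)[up]), 0)
})

test_that("no spikes give an identically zero uncorrected FR", {
  spk <- SpikeTrains(list(numeric(0), numeric(0)),
                     data.frame(contact_id = 1, wire_id = 1:2))
  p <- firingRatePeth(spk, c(50, 60), c(-1, 1), c(-1, -0.5),
                      durationS = 100)
  expect_true(all(p@rateRaw == 0))
})

test_that("FR histograms are linear over wire pooling", {
  spk <- poissonTrains(4, 5, 600, seed = 34)
  anchors <- c(100, 200, 300, 400, 500)
  pooled <- firingRatePeth(spk, anchors, c(-1, 1), c(-1, -0.5),
                           durationS = 600)
  per <- lapply(1:4, function(w) {
    one <- SpikeTrains(spikeTimes(spk)[w],
                       data.frame(contact_id = 1, wire_id = w))
    firingRatePeth(one, anchors, c(-1, 1), c(-1, -0.5), durationS = 600)
  })
  mean4 <- Reduce("+", lapply(per, function(p) p@rateRaw)) / 4
  expect_equal(pooled@rateRaw, mean4, tolerance = 1e-12)
})

test_that("maximal corrected FR recovers a planted peak height", {
  # a known-height raw peak, wide enough to survive 100-ms smoothing
  spk <- poissonTrains(1, 2, 2000, seed = 35)
  set.seed(36)
  anchors <- sort(runif(400, 10, 1990))
  tt <- sort(c(spikeTimes(spk)[[1]],
               rep(anchors, each = 12) +
                 runif(4800, -0.15, 0.15)))
  spk2 <- SpikeTrains(list(tt), wireInfo(spk))
  p <- firingRatePeth(spk2, anchors, c(-2.5, 2.5), c(-2.5, -2),
                      durationS = 2000)
  # planted plateau adds 12 spikes / 0.3 s = 40 Hz over baseline
  expect_lt(abs(maxFiringRate(p) - 40) / 40, 0.15)
  pz <- firingRatePeth(spk, anchors, c(-2.5, 2.5), c(-2.5, -2),
                       durationS = 2000)
  expect_lt(abs(maxFiringRate(pz)), 1)
})

test_that("FR gain staircase is recovered from a simulated session", {
  cfg <- simConfig(duration_s = 900, n_contacts = 1, artifact_rate = 0,
                   cross_sync_prob = 0, seed = 37)
  sess <- simulateSession(cfg)
  ev <- sess$truth$events
  mf <- sapply(c("so", "spindle", "ripple"), function(ty) {
    base <- if (ty == "ripple") c(-1.5, -1) else c(-2.5, -2)
    p <- firingRatePeth(sess$spikes, ev$center_s[ev$type == ty],
                        c(-2.5, 2.5), base, durationS = 900)
    maxFiringRate(p)
  })
  expect_lt(mf["so"], mf["spindle"])
  expect_lt(mf["spindle"], mf["ripple"])
})

test_that("wire inclusion applies the 1-Hz NREM floor inclusively", {
  trains <- list(sort(runif(50, 0, 100)),    # 0.5 Hz -> dropped
                 seq(0.5, 99.5, by = 1),     # exactly 1.0 Hz -> kept
                 sort(runif(500, 0, 100)),   # 5 Hz -> kept
                 numeric(0))                 # empty -> dropped
  spk <- SpikeTrains(trains, data.frame(contact_id = 1, wire_id = 1:4))
  kept <- wireInclusion(spk, durationS = 100)
  expect_equal(wireInfo(kept)$wire_id, c(2L, 3L))
  expect_error(wireInclusion(
    SpikeTrains(trains[c(1, 4)],
                data.frame(contact_id = 1, wire_id = 1:2)),
    durationS = 100), "threshold")
})

test_that("correlation maps separate shared gain from independence", {
  set.seed(38)
  nC <- 10
  gain <- exp(rnorm(nC, 0, 0.5))
  fr <- outer(gain, rep(1, 8)) + matrix(rnorm(nC * 8, 0, 0.05), nC)
  rate <- outer(gain, rep(1, 8)) + matrix(rnorm(nC * 8, 0, 0.05), nC)
  cm <- frEventRateCorrelation(fr, rate, time1 = 1:8, time2 = 1:8)
  expect_true(all(cm@r > 0))
  # independent quantities: |r| within the permutation null bound
  frI <- matrix(rnorm(nC * 8), nC)
  rtI <- matrix(rnorm(nC * 8), nC)
  cmI <- frEventRateCorrelation(frI, rtI, 1:8, 1:8)
  expect_lt(mean(abs(cmI@r) > 2 / sqrt(nC - 3)), 0.15)
  # constant FR across contacts: undefined cells, not NaN propagation
  frC <- matrix(1, nC, 8)
  cmC <- frEventRateCorrelation(frC, rtI, 1:8, 1:8)
  expect_true(all(is.na(cmC@r)))
  expect_error(frEventRateCorrelation(frI[1:2, ], rtI[1:2, ]),
               "3 contacts")
})

test_that("interval means tile the corrected PETH into 500-ms cells", {
  p <- eventLockedRate(c(100), c(99.25, 100.25, 100.3), c(-2, 2),
                       c(-2, -1.5), smoothingMs = 0, durationS = 200)
  im <- intervalMeans(p)
  expect_equal(length(im), 8)
  expect_equal(names(im)[1], "-1.75")
  expect_gt(im["0.25"], im["-1.25"])
})
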