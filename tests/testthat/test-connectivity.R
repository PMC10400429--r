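test_that("a constant-lag narrowband pair gives near-unit PLV", {
  fs <- 1000
  set.seed(51)
  t <- seq_len(120 * fs) / fs
  carrier <- sin(2 * pi * 13 * t)
  sigA <- carrier + rnorm(length(t), sd = 0.1)
  sigB <- c(rep(0, 10), carrier[seq_len(length(t) - 10)]) +
    rnorm(length(t), sd = 0.1)
  anchors <- seq(5, 115, by = 2.5)
  m <- plvMap(sigA, sigB, fs, anchors, timesS = seq(-0.5, 0.5, 0.025),
              freqsHz = 10:16, baselineWindowS = c(-0.5, -0.25))
  expect_gte(max(m@plv[m@freqsHz == 13, ]), 0.99)
  # PLV is invariant to per-channel amplitude scaling
  m2 <- plvMap(10 * sigA, 0.3 * sigB, fs, anchors,
               timesS = seq(-0.5, 0.5, 0.025), freqsHz = 10:16,
               baselineWindowS = c(-0.5, -0.25))
  expect_equal(m@plv, m2@plv, tolerance = 1e-9)
})

test_that("independent noise channels follow the Rayleigh expectation", {
  fs <- 1000
  set.seed(52)
  n <- 200
  dur <- 3 * n + 20
  sigA <- rnorm(dur * fs)
  sigB <- rnorm(dur * fs)
  anchors <- seq(10, dur - 10, length.out = n)
  m <- plvMap(sigA, sigB, fs, anchors, timesS = seq(-0.2, 0.2, 0.1),
              freqsHz = c(10, 25, 60, 110),
              baselineWindowS = c(-0.2, -0.1))
  expect_lt(abs(mean(m@plv) - sqrt(pi) / 2 / sqrt(n)),
            0.2 * sqrt(pi) / 2 / sqrt(n))
})

test_that("PLV analysis windows span whole cycles, >= 5 and >= 100 ms", {
  f <- 1:150
  ncyc <- plvWindowCycles(f)
  expect_true(all(ncyc == ceiling(pmax(5, 0.1 * f) - 1e-9)))
  win <- ncyc / f
  expect_true(all(win >= 0.1 - 1e-9))
  expect_true(all(ncyc >= 5))
  # low frequencies: exactly five cycles; high: 100 ms rounded up to
  # whole cycles (within one cycle of 100 ms)
  expect_true(all(ncyc[f <= 10] == 5))
  expect_true(all(win[f >= 50] < 0.1 + 1 / f[f >= 50]))
})

test_that("baseline-corrected PLV is near zero for stationary signals", {
  fs <- 1000
  set.seed(53)
  sigA <- rnorm(400 * fs)
  sigB <- rnorm(400 * fs)
  anchors <- seq(10, 390, by = 4)
  m <- plvMap(sigA, sigB, fs, anchors, timesS = seq(-1, 1, 0.25),
              freqsHz = c(15, 80), baselineWindowS = c(-1, -0.5))
  expect_lt(max(abs(m@baselineCorrected)), 0.1)
})

test_that("cross-regional event histograms pool pairs symmetrically", {
  set.seed(54)
  chans <- data.frame(contact_id = 1:4,
                      region = c("AH", "EC", "AH", "EC"),
                      hemisphere = c("L", "L", "R", "R"))
  # synchronous ripples across regions with +/-10-ms scatter
  base <- sort(runif(300, 10, 1790))
  ev <- rbind(
    data.frame(type = "ripple", contact_id = 1, center_s = base),
    data.frame(type = "ripple", contact_id = 2,
               center_s = base + rnorm(300, 0, 0.01)))
  p10 <- crossRegionalEventRate(ev, chans, "AH", "EC", "ripple",
                                smoothingMs = 10, durationS = 1800)
  ctr <- binCenters(p10)
  expect_lt(abs(ctr[which.max(rates(p10))]), 0.02)
  # peak with 10-ms smoothing is much sharper than with 100-ms
  p100 <- crossRegionalEventRate(ev, chans, "AH", "EC", "ripple",
                                 smoothingMs = 100, durationS = 1800)
  expect_gt(max(rates(p10)), 2 * max(rates(p100)))
  # independent regional streams: corrected rate ~ 0
  evI <- rbind(
    data.frame(type = "ripple", contact_id = 1, center_s = base),
    data.frame(type = "ripple", contact_id = 2,
               center_s = sort(runif(300, 0, 1800))))
  pI <- crossRegionalEventRate(evI, chans, "AH", "EC", "ripple",
                               durationS = 1800)
  expect_lt(max(abs(rates(pI))), 3 * sqrt((300 / 1800) / (600 * 0.071)))
  expect_error(crossRegionalEventRate(ev, chans, "AH", "PHC", "ripple",
                                      durationS = 1800), "pairs")
})

mkFrSession <- function(gainB, seed) {
  set.seed(seed)
  chans <- data.frame(contact_id = 1:2, region = c("AH", "EC"),
                      hemisphere = c("L", "L"))
  anchors <- sort(runif(120, 10, 890))
  ev <- data.frame(type = "ripple", contact_id = 1,
                   onset_s = anchors - 0.05, center_s = anchors,
                   max_s = anchors, offset_s = anchors + 0.05)
  trains <- lapply(1:4, function(i) {
    tt <- runif(rpois(1, 5 * 900), 0, 900)
    if (gainB > 1) {
      extra <- unlist(lapply(anchors, function(a) {
        runif(rpois(1, 5 * (gainB - 1) * 0.1), a - 0.05, a + 0.05)
      }))
      tt <- c(tt, extra)
    }
    sort(tt)
  })
  spikes <- SpikeTrains(trains,
                        data.frame(contact_id = 2, wire_id = 1:4))
  list(events = ev, spikes = spikes, channels = chans, durationS = 900)
}

test_that("cross-regional FR edges detect planted gain and stay symmetric", {
  sessions <- lapply(1:10, function(s) mkFrSession(2, 60 + s))
  edge <- crossRegionalFrEdge(sessions, "AH", "EC", "ripple")
  expect_gt(edge$t, 2)
  expect_true(edge$significant)
  edgeRev <- crossRegionalFrEdge(sessions, "EC", "AH", "ripple")
  expect_equal(edge$sessionValues, edgeRev$sessionValues)
  expect_equal(edge$t, edgeRev$t)
  # independent regions: small t for this null draw
  nullSessions <- lapply(1:10, function(s) mkFrSession(1, 80 + s))
  edgeN <- crossRegionalFrEdge(nullSessions, "AH", "EC", "ripple")
  expect_lt(abs(edgeN$t), 3)
  expect_error(crossRegionalFrEdge(sessions[1], "AH", "EC", "ripple"),
               "2 sessions")
})
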