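# brute-force coincidence counter: independent nested-loop reimplementation
# of the raw CCG layer for tiny instances
bruteRawCcg <- function(trains, centers, halfWin = 0.075, maxLag = 50) {
  counts <- numeric(2 * maxLag + 1)
  nw <- length(trains)
  for (c0 in centers) {
    for (i in seq_len(nw - 1)) {
      for (j in (i + 1):nw) {
        for (a in trains[[i]]) {
          if (a < c0 - halfWin || a > c0 + halfWin) next
          for (b in trains[[j]]) {
            if (b < c0 - halfWin || b > c0 + halfWin) next
            d <- round((b - a) * 1000)
            if (abs(d) <= maxLag) {
              counts[d + maxLag + 1] <- counts[d + maxLag + 1] + 1
              counts[-d + maxLag + 1] <- counts[-d + maxLag + 1] + 1
            }
          }
        }
      }
    }
  }
  lagS <- (seq_along(counts) - maxLag - 1) / 1000
  counts / (nw * (nw - 1) / 2 * length(centers) *
              (2 * halfWin - abs(lagS)) * 2)
}

burstTrains <- function(nWires, centers, perEvent, baseRate, durS,
                        seed = 1) {
  set.seed(seed)
  lapply(seq_len(nWires), function(i) {
    tt <- runif(rpois(1, baseRate * durS), 0, durS)
    for (c0 in centers) tt <- c(tt, runif(perEvent, c0 - 0.075, c0 + 0.075))
    sort(tt)
  })
}

# sessions with injected co-firing at a given jitter, CCG per session
jitterSessions <- function(nSessions, jitterMs, seedBase) {
  t(sapply(seq_len(nSessions), function(s) {
    set.seed(seedBase + s)
    centers <- seq(10, 10 + 150 * 3, by = 3)
    nw <- 6
    trains <- lapply(seq_len(nw), function(i) runif(rpois(1, 5 * 470), 0, 470))
    for (c0 in centers) {
      for (p in 1:6) {
        pick <- sample(nw, 2)
        tref <- runif(1, c0 - 0.05, c0 + 0.05)
        trains[[pick[1]]] <- c(trains[[pick[1]]], tref)
        trains[[pick[2]]] <- c(trains[[pick[2]]],
                               tref + rnorm(1, 0, jitterMs / 1000))
      }
    }
    spk <- SpikeTrains(lapply(trains, sort),
                       data.frame(contact_id = 1, wire_id = seq_len(nw)))
    eventLockedCcg(spk, centers, centers + 1.5)@corrected
  }))
}

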