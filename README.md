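# sleepCoupling

Analysis of coupled NREM sleep rhythms — slow oscillations (SOs), sleep
spindles and ripples — in intracranial field potentials with simultaneous
microwire multiunit activity (MUA). The package is aimed at sleep and
memory-consolidation researchers working with human depth-electrode
recordings (or realistic simulations of them) who need the full chain
from raw multichannel LFP to group-level statistics:

* signal conditioning (1-kHz downsampling, line-noise notches, 0.1-Hz
  high-pass, up-state-positive polarity) and stage-wise z-score artifact
  rejection (|z| > 6 in the signal, its 250-Hz high-pass copy or its
  gradient; or |z| > 4 in the signal plus one other; runs merged < 3 s
  apart and padded by 1 s);
* event detection on artifact-free N2/N3 data — SOs as 0.8–2-s
  positive-to-negative zero-crossing spans of the 0.3–1.25-Hz signal
  whose trough and trough-to-peak amplitudes exceed the candidate-pool
  mean + 1 s.d.; spindles as 0.4–3-s, ≥ 6-cycle threshold crossings of
  the smoothed 12–16-Hz RMS envelope (mean + 1 s.d., upper cutoff
  mean + 9 s.d.); ripples as 38–200-ms, ≥ 3-cycle crossings of the
  80–120-Hz envelope (mean + 3 s.d., cutoff mean + 9 s.d.);
* peri-event time histograms (1-ms bins, 100-ms Gaussian smoothing,
  pre-event baselines), duration-matched non-event surrogates,
  contingency splits and peak latencies;
* event-locked spike cross-correlograms (±50-ms lags in 150-ms windows
  on event maxima) corrected by a shift predictor (event *n* vs *n*+1)
  and by surrogate CCGs;
* cross-regional co-occurrence, Hanning-taper phase-locking-value maps
  (1–150 Hz, 25-ms steps, ≥ 5 cycles and ≥ 100 ms per window) and
  firing-rate network edges;
* cluster-based permutation statistics across sessions (sign-flip null,
  summed-*t* cluster mass, two-tailed) and event-count-weighted session
  aggregation.

A synthetic-session generator (`simulateSession()`) plants SOs, spindles
and ripples with configurable nesting on a 1/f background and emits
event-gain-modulated Poisson spike trains, so every analysis can be
validated against ground truth without patient data.

## Worked example

```r
library(sleepCoupling)

cfg  <- simConfig(duration_s = 600, n_contacts = 2, seed = 42)
sess <- simulateSession(cfg)
rec  <- detectArtifacts(sess$recording)
rec
#> SleepRecording: 2 channels x 10.0 min at 1000 Hz (preprocessed)
#>   regions: AH, PH
#>   stages:  N2:10 N3:10
#>   artifact samples flagged: 0.50%

events <- detectEvents(rec)
table(events$type)
#>
#>  ripple      so spindle
#>     137      96     103

# how well did detection recover the planted ground truth?
matchToTruth(events[events$type == "ripple", ],
             sess$truth$events[sess$truth$events$type == "ripple", ])
#> $sensitivity
#> [1] 0.9577465
#> $precision
#> [1] 0.9927007
#> $nMatched
#> [1] 136

# ripple rate around SO up-state maxima, baseline-corrected
so  <- events[events$type == "so", ]
rip <- events$center_s[events$type == "ripple"]
p <- eventLockedRate(so$max_s, rip, c(-2.5, 2.5), c(-1.5, -1),
                     durationS = recordingDuration(rec),
                     anchorType = "so", targetType = "ripple",
                     anchorPoint = "maximum")
p
#> Peth: so (maximum-locked) -> ripple | 96 anchors | [-2.4995, 2.4995] s, 5000 bins
#>   baseline [-1.5, -1] s, 100-ms Gaussian smoothing
peakLatency(p, c(-2, 0))
#> [1] -0.5275
```

The detected ripple rate peaks about half a second before the SO
up-state maximum (−0.53 s here), reproducing the planted nesting:
spindles sit in the SO up-state and ripples in the spindles' waxing
phase. `firingRatePeth()`,
`eventLockedCcg()`, `plvMap()`, `crossRegionalFrEdge()` and
`clusterPermutationVsZero()` continue the chain through firing rates,
co-firing, connectivity and group statistics; `runPipeline()` drives the
whole analysis over a session directory written by `writeFixture()`.

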