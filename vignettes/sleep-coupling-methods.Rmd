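---
title: "Detecting and coupling NREM sleep rhythms: methods and design notes"
author: "sleepCoupling package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and coupling NREM sleep rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepCoupling)
```

## The analysis problem

During non-REM (NREM) sleep, three field-potential rhythms structure the
activity of medial-temporal-lobe (MTL) circuits: slow oscillations (SOs,
< 1 Hz alternations of depolarized up-states and silenced down-states),
sleep spindles (waxing-waning ~12-16-Hz oscillations) and ripples
(transient ~80-120-Hz bursts riding a sharp wave). Their nesting — ripples
inside spindles inside SO up-states — is thought to set the stage for
spike-timing-dependent plasticity and systems-level memory consolidation.

This package implements the complete analysis chain needed to study that
nesting in intracranial recordings with simultaneous microwire multiunit
activity (MUA): signal conditioning and artifact rejection, per-channel
event detection, event- and spike-rate peri-event time histograms (PETHs),
matched non-event surrogates, event-locked spike cross-correlograms (CCGs)
with shift-predictor and surrogate corrections, cross-regional
co-occurrence, phase-locking and firing-rate connectivity, and
cluster-based permutation statistics across sessions. A synthetic session
generator with known ground truth makes every stage testable without
patient data.

## Signal conditioning

`preprocessSignal()` downsamples to 1 kHz (anti-alias low-pass at 0.8 x
the target Nyquist), removes line noise with +/-1-Hz band-stop filters at
50 Hz and harmonics up to 200 Hz, high-passes at 0.1 Hz, and inverts
polarity so that positive peaks reflect up-states. All filters are
zero-phase (two-pass) order-3 Butterworth: only corner frequencies are
prescribed by the method, and zero-phase filtering preserves the event
latencies every downstream coupling analysis depends on. Because
`signal::filtfilt()` applies no padding, each filter call internally
demeans the trace and extends it by odd reflection before filtering;
without this, a DC offset produces edge transients orders of magnitude
above the signal.

`detectArtifacts()` builds three versions of each channel — the signal, a
250-Hz high-pass copy, and the first-difference gradient — z-scores each
within each sleep stage, and flags samples with |z| > 6 in any signal, or
|z| > 4 in the raw signal together with |z| > 4 in one of the other two.
Flagged runs closer than 3 s are merged and padded by 1 s per side.
Thresholds are applied two-sided: artifacts are large in either
direction, and nothing in the detection logic distinguishes sign.
The 250-Hz copy is computed on the 1-kHz signal after downsampling.

## Event detection

All thresholds are computed per channel from artifact-free N2/N3 samples
only (`nremSamples()`), and "exceeds" is strict (>) throughout — a
degenerate pool of identical candidate amplitudes therefore yields zero
detections.

* **SOs** (`detectSlowOscillations()`): 0.3-1.25-Hz band-pass; candidates
  are spans between successive positive-to-negative zero crossings
  lasting 0.8-2 s; kept when both trough amplitude and trough-to-peak
  amplitude exceed the mean + 1 s.d. of the channel's candidate pool.
  Onset is the first crossing, center the maximal trough (down-state),
  maximum the maximal peak after the trough (up-state).
* **Spindles** (`detectSpindles()`): 12-16-Hz band-pass, RMS envelope
  over 200-ms windows plus 200-ms moving-average smoothing; events are
  supra-threshold runs (mean + 1 s.d. of the envelope) lasting 0.4-3 s,
  rejected when any sample exceeds mean + 9 s.d. or fewer than 6 cycles
  are present.
* **Ripples** (`detectRipples()`): as spindles with an 80-120-Hz band,
  20-ms windows, detection at mean + 3 s.d., the same mean + 9 s.d.
  cutoff, 38-200-ms durations (38 ms = three cycles at 80 Hz) and at
  least 3 cycles.

Cycles are counted as descending zero crossings of the band-passed event
segment (`countCycles()`); counting in a broadband trace is ill-defined,
and the band-passed segment is the signal the detector already reasons
about. Spindle and ripple centers ("maximal trough") are taken in the
filtered signal for the same reason.

`matchSurrogates()` draws, for each event, a duration-matched artifact-free
NREM epoch with no detected event of the same type within 1.5 s, from a
+/-10-min window around the event. Offsets are drawn from a zero-mean
normal (s.d. 2.5 min, truncated at the window edge), concentrating
surrogates near their events so that slow nonstationarities are matched;
the s.d. is a package choice and is configurable. Accepted epochs are
removed from further consideration, so surrogates never overlap.

## Histograms, smoothing, baselines

PETHs use 1-ms bins, rates in Hz per anchor (and per wire for MUA),
smoothed with a "100-ms Gaussian kernel" interpreted as a Gaussian window
of total width 100 ms with s.d. = width/5 (20 ms), truncated at the window
edge and renormalized — a flat input stays flat and interior mass is
conserved. Baseline windows are -2.5 to -2 s for SO- and spindle-locked
histograms and -1.5 to -1 s for ripple-locked ones. Anchors whose window
crosses the recording edge or a masked interval are dropped rather than
truncated, keeping per-bin denominators uniform.

## Cross-correlograms

`eventLockedCcg()` tallies cross-wire spike coincidences in 150-ms windows
centered on event maxima, at 1-ms lags up to +/-50 ms, pooled over both
orderings of each unordered wire pair (so the raw CCG is symmetric by
construction), and normalized per second of lag-valid window time per
event and pair — near the window edge only the available overlap counts,
avoiding zero-padding inflation. Two corrections are subtracted: a shift
predictor pairing event n with event n + 1 (the last event wraps to the
first, preserving the event count), removing event-locked rate
covariation; and the identically computed, shift-predictor-corrected CCG
of matched non-event surrogates. Layers are smoothed with a 5-ms Gaussian
kernel (same convention as above). `significantSpan()` reports the width
of the largest significant positive lag cluster across sessions under the
cluster permutation test.

## Connectivity

`crossRegionalEventRate()` pools target-region event centers around
seed-region event centers over all same-hemisphere contact pairs in both
directions. `plvMap()` estimates phase with a single Hanning-tapered
window per time (25-ms steps) and frequency (1-150 Hz, 1-Hz steps); the
window spans a whole number of cycles, at least five and at least 100 ms
(`plvWindowCycles()`), and the phase-locking value is the modulus of the
event-average unit phasor of the two channels' phase difference. PLV maps
are baseline-corrected by the frequency-wise mean over the same pre-event
windows used for the rate analyses. `crossRegionalFrEdge()` averages
baseline-corrected target-region firing in a 100-ms window at the
seed-region event maximum over pairs, directions and hemispheres, and
tests the session values against zero — edges are symmetric in region
order by construction.

## Statistics

`clusterPermutationVsZero()` forms one-sample t values across sessions,
clusters contiguous supra-threshold cells (run-adjacency in 1-D, a
4-neighbourhood in 2-D; the conservative choice where the convention is
not fixed), sums t within clusters, and compares each cluster mass to the
permutation distribution of the maximal mass under random sign-flipping
of whole sessions (the standard exchangeable scheme for symmetric nulls),
two-tailed, with minimal attainable p = 1/(n_permutations + 1). Defaults:
1,000 permutations, cluster-forming and final thresholds of 0.05.
`aggregateSessions()` averages per-contact results into session values
weighted by each contact's event count; sessions are the inference unit.

## The synthetic-session generator

`simulateSession()` emulates what the analyses assume about NREM data:

* **Background**: Gaussian noise spectrally shaped to 1/f (exponent 1,
  flat below 0.1 Hz), s.d. 15 uV — a minimal stationary stand-in for
  broadband NREM activity.
* **Events**: single-cycle biphasic SOs (trough then peak, 0.75 Hz by
  default), 1.5-s spindles and 150-ms ripples as tapered-cosine
  (plateau) enveloped sinusoids, the ripple riding a brief negative
  sharp wave. Nesting is generated explicitly: each SO nests a spindle
  with probability `p_spindle_in_so` (center in the up-state), each
  spindle nests a ripple with probability `p_ripple_in_spindle`
  (strictly inside the spindle span, centered in the waxing phase, with
  a 0.25-s latency spread). Event amplitudes are `event_snr` times the
  background s.d. *within the event's detection band* — the scaling a
  detector actually competes against.
* **Spikes**: per microwire, an inhomogeneous Poisson process (thinning)
  whose rate is the baseline times a gain that multiplies inside events:
  1.5 in SO up-states, 0.2 in SO down-states (the OFF period), 2 in
  spindles, 3 in ripples (compounding when nested), with a linear
  pre-ripple ramp. `plantCofiring()` adds synchronous cross-wire spike
  pairs with per-event-type timing jitter, the substrate for the CCG
  narrowing analyses.
* **Artifacts** are high-amplitude (8 s.d.) transients; the hypnogram is
  all-N2/N3 with optional wake blocks to exercise stage filtering.

Default event densities (SO 5/min; spindles 3/min plus nesting; ripples
4/min plus nesting) sit at the upper end of what is reported for
N3-rich human sleep. They are chosen deliberately: with a stationary
Gaussian background, the narrowband RMS envelope fluctuates with a
coefficient of variation near 0.4, so relative thresholds of the
mean + k s.d. form only separate events from background when the events
themselves carry appreciable pool mass. Sparser, quieter regimes push the
detection threshold into the background's own envelope tail — a regime in
which no threshold detector of this family is reliable. Passing tests on
this generator therefore demonstrates correct implementation of the
detection rules and recovery of planted structure under favourable,
internally consistent conditions; it does not certify detector
performance on real data, whose background is nonstationary, artifactual
and not Gaussian.

## Desk-scale recovery experiments

The package's acceptance checks (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) rerun the full chain on synthetic sessions sized
for minutes of compute; the problem sizes are package choices:

* **Detector recovery**: one 30-min, 2-contact session at `event_snr = 5`;
  sensitivity and precision >= 0.9 per event type against ground truth.
* **Sequential coupling**: twenty 8-min sessions in a nesting-rich design
  (SO 5/min, background spindles/ripples 1/min, nesting probabilities
  0.6) — latency recovery measures nested events, so they must dominate
  the onset histograms at this scale. Onset-rate PETHs are anchored on
  the SO maximum: the generator plants isolated single-cycle SOs, so
  nested spindle and ripple onsets precede the up-state peak, whereas in
  quasi-rhythmic real SO trains the preceding up-state places them before
  the next SO onset. The recovered quantity is the ordering — spindle
  onsets peak earlier than ripple onsets — plus a higher SO-locked ripple
  rate when a spindle is present.
* **Firing-rate staircase**: ten 8-min sessions at moderate nesting
  (probabilities 0.35, so the cascade's compound gain does not bleed the
  ripple peak into the SO-locked window); the SO < spindle < ripple
  ordering of maximal event-locked firing must hold in every session and
  SO down-state firing must fall below baseline.
* **CCG properties**: exact agreement of the raw layer with a brute-force
  double-loop counter; a null corrected CCG for rate-comodulated but
  independent wires; and a strictly narrower significant co-firing span
  for 2-ms than for 12-ms planted jitter.
* **PLV limits**: a constant-lag narrowband pair reaches PLV >= 0.99 at
  the carrier frequency; 200 independent-noise events fall at the
  Rayleigh expectation sqrt(pi)/2/sqrt(n).
* **Cluster-test calibration**: family-wise error on 1,000 null datasets
  (20 sessions x 101 cells, 200 permutations each — scaled down from
  1,000) within [0.03, 0.07].

## Numerical choices and degenerate inputs

Times are seconds (float64) from recording start; intervals are half-open
[start, end), making 1-ms binning unambiguous. Ties in `peakLatency()`
break to the earliest bin. `scale01()` refuses constant curves; the
cluster test refuses zero-variance cells (callers exclude undefined
correlation cells first); `pairedT()` surfaces a zero-variance error
rather than an infinite t. Fewer than two SO candidates leave the
amplitude s.d. undefined and return no events with a warning. Identical
seeds reproduce sessions, surrogate draws and permutation p values
bit-for-bit.

## Known limitations

The generator is not a biophysical model: its background is stationary,
events are stereotyped kernels, and spike trains are Poisson. Wake and
REM signal structure, interictal discharges, spike sorting and anatomical
localization are out of scope. Detected event counts depend strongly on
the relative thresholds; as with the underlying method, baseline- and
surrogate-normalized quantities are the interpretable outputs, not raw
event counts. EDF ingestion is not provided; sessions are exchanged as
raw float32 binary plus a YAML sidecar and TSV tables (`writeFixture()`,
`readSession()`).
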