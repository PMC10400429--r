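Package: sleepCoupling
Title: Detection and Coupling Analysis of Slow Oscillations, Spindles and
    Ripples in Intracranial Sleep Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of human intracranial sleep recordings
    with simultaneous multiunit activity: artifact rejection and detection of
    slow oscillations, sleep spindles and ripples from NREM field potentials;
    peri-event time histograms of event and firing rates with matched
    non-event surrogates; event-locked spike cross-correlograms with
    shift-predictor and surrogate corrections; cross-regional co-occurrence,
    phase-locking-value and firing-rate connectivity; and cluster-based
    permutation statistics across sessions. Includes a synthetic NREM session
    generator (1/f background with planted slow-oscillation half-waves,
    waxing-waning spindles, ripple bursts and event-modulated inhomogeneous
    Poisson spike trains) so that every stage of the pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'filters.R'
    'simConfig.R'
    'simulate.R'
    'fixtures.R'
    'preprocess.R'
    'detect.R'
    'surrogates.R'
    'peth.R'
    'coupling.R'
    'firing.R'
    'ccg.R'
    'connectivity.R'
    'stats.R'
    'pipeline.R'
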