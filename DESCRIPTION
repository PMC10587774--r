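Package: hfoprime
Title: Fast-Ripple Priming of Inter-Ictal Epileptiform Spikes in
    Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for inter-ictal intracranial EEG linking
    high-frequency oscillations (HFOs) to epileptiform spike generation.
    Detects ripple (80-200 Hz) and fast-ripple (200-600 Hz) events with a
    two-stage detector (Hilbert band-envelope candidates followed by
    topographical classification of wavelet isopower contours), flags HFOs
    on oscillations that precede spikes by under 300 ms, tests the
    coincidence against uniform-resampling surrogate nulls, quantifies
    peri-event single- and multi-unit firing with Gaussian-smoothed rate
    trials feeding Gaussian mixed-effects models, and computes
    resection-cohort localization metrics (seizure-onset-zone and resection
    ratios, fast-ripple rate-distance graph radii).  A synthetic-cohort
    generator with ground truth makes every stage testable without patient
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    lme4,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
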