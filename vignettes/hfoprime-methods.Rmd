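---
title: "Methods: fast-ripple priming of inter-ictal epileptiform spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast-ripple priming of inter-ictal epileptiform spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfoprime)
```

## The scientific question

In epileptic brain, brief high-frequency oscillations (HFOs) in
intracranial EEG — ripples (80–200 Hz) and fast ripples (FR, 200–600 Hz) —
and inter-ictal epileptiform spikes are both biomarkers of epileptogenic
tissue. `hfoprime` implements an inter-ictal analysis chain built around
one hypothesis: *a fast ripple on the background oscillation (fRonO) that
occurs shortly (under 300 ms) before a spike reflects a transient rise in
local excitability that primes the spike*. The chain quantifies

1. whether fRonO precede spikes more often than chance (surrogate
   bootstrap on event onsets),
2. whether priming fRonO carry more spectral power and more vigorous unit
   firing than solitary fRonO (peri-event firing statistics feeding
   Gaussian mixed models), and
3. whether the sites generating pre-spike fRonO coincide with the
   clinician-defined seizure-onset zone (SOZ) and with the resection, and
   whether residual fast-ripple-generating tissue after resection
   (a rate–distance graph radius) separates seizure-free from
   non-seizure-free patients.

Patient recordings of this kind are not publicly distributable, so the
package ships a synthetic-cohort generator with full ground truth; every
stage is validated against it.

## Event detection and classification

**Stage 1 — candidates.** Each channel is band-filtered with a zero-phase
frequency-domain filter (real, symmetric raised-cosine band mask, which is
a frequency-sampled linear-phase FIR and leaves onset times unbiased) in
the ripple (80–200 Hz), FR (200–600 Hz) and spike-scan (20–80 Hz) bands.
The analytic envelope is converted to a robust z-score against the
median/MAD of the envelope inside the artifact-free epochs. Contiguous
runs above a boundary threshold `z_lo = 4` that reach `z_hi = 8` at their
peak, span at least 2 cycles of the band centre frequency, and merge
across gaps under 10 ms become candidates. These thresholds were set from
the envelope statistics of the generator's 1/f background: the Rayleigh
tail of a MAD-scaled band envelope crosses z = 3 thousands of times per
minute, while genuine events at the calibrated amplitudes reach z ≈ 30–50,
so the operating point sits in a wide margin between the two. On pure
background the false-alarm rate is measured at 0 candidates/min; recall on
injected events exceeds 0.97 at an event SNR of 12 dB.

**Artifact masking.** Samples are excised (with a 50 ms guard) when the
analytic envelope in a supra-physiological band (0.8–0.95 of Nyquist —
above the 600 Hz FR edge *and* above the spectral spread of brief bursts
near it) exceeds 8 robust z-units, or when the sample-to-sample derivative
exceeds 150 z-units. Both bounds deliberately sit above what physiological
events reach: sharp epileptiform spikes are rooted below ~100 Hz and fast
ripples carry large slew by construction, whereas mechanical/electrical
transients splash across the whole spectrum (a 2 mV square pulse reaches
z ≈ 250 in the supra-physiological band and ≈ 400 in slew). Flat channels
are treated as saturated and lose all epochs. Amplitude-only artifacts
with no high-frequency content are out of scope of this mask.

**Stage 2 — topographical classification.** Each candidate is windowed
(±500 ms), Morlet-transformed (7 cycles, 64 log-spaced frequencies,
60–800 Hz) and whitened by dividing each frequency row by its median power
across the window, flattening the 1/f background so that event power is
expressed relative to the channel background at that frequency. The grid
extends to 800 Hz because a 20 ms burst at 600 Hz spreads roughly 100 Hz
spectrally; with a lower ceiling its contours are cut open at the map edge
and the event is lost. Contours of iso-power are extracted at ten evenly
spaced levels from the threshold

\[ \theta = 0.2\,( \max P - \min P ) + \min P \]

to the map maximum, on the candidate's own support (±150 ms): the
threshold is relative to the map maximum, so evaluating it over the full
window would let a high-power neighbour (for instance a boosted priming
fRonO) erase a weaker adjacent event. Each contour is *closed* when its
first and last vertices coincide and *open* otherwise; closed contours
group by the local power maximum they enclose (a closed-loop-contour, CLC,
group). Classification follows the contour topology:

* CLC group, no qualifying earlier open contour → RonO / fRonO;
* CLC group whose outermost contour starts *after* the onset of a
  qualifying open-loop contour (OLC, the broadband spike signature) →
  RonS / fRonS;
* qualifying OLCs with no CLC group → sharp spike.

An OLC qualifies as a spike signature only when it extends below 80 Hz
(spikes are broadband and low-frequency-rooted; this keeps edge-truncated
HFOs from being read as spikes), is at least 15 ms wide, reaches 10% of
the suprathreshold power range, and overlaps the CLC group in time.
Closed groups whose mean frequency falls below 80 Hz are treated as part
of the spike's broadband signature, not as HFOs (the HFO classes are
defined on 80–600 Hz). Ripples and fast ripples split at 200 Hz by the
group's mean frequency, computed as the power-weighted geometric mean over
the enclosed cells — an estimator centred on the blob's centre frequency
with ~1% dispersion, so band confusions occur only within one grid step of
the boundary. Peak frequency and power come from the largest isopower
contour in the group; duration from the outermost contour's extent. One
event is emitted per CLC group overlapping the candidate, so a priming
fRonO and the HFO-on-spike it precedes both survive when caught in one
window; near-coincident classifications from different bands are
deduplicated (onsets within 25 ms), preferring CLC-backed classes with the
largest power.

On synthetic cohorts at 15 dB SNR the end-to-end label accuracy against
ground truth is 0.93–0.96 with recall 0.97–0.99; the residual errors are
dominated by ripples-on-spike whose blob merges with the spike signature
below ~110 Hz and by priming fRonO under ~30 ms before the spike, which
are genuinely ambiguous with the fRonS that follows.

## Coincidence and the surrogate null

For each HFO-on-oscillation the latency to the next spike is the minimum
*strictly positive* difference between spike onsets and the HFO onset,
within the channel. A fRonO/RonO is *pre-spike* when that latency is under
300 ms (strict); fRonS/RonS are *followed-by* when a fRonO/RonO onset lies
in the 300 ms before theirs; everything else is solitary. The null keeps
spike onsets fixed and redraws each channel's HFO onsets uniformly within
that channel's artifact-free epochs (HFOs are not constrained to
oscillations), 500 times; the pooled statistic sums per-channel
coincidence counts with surrogates resampled independently per channel.
We report the z-score of the observed count against the surrogate
distribution together with a two-sided empirical p with the +1 correction,
\((1 + \#\{|s - \bar s| \ge |o - \bar s|\})/(n+1)\), leaving the
one-sided/two-sided choice visible to the user. Calibration: with an
independent generator the fraction of datasets with |z| > 1.96 is 0.04–0.05
(200 datasets, 16 contacts × 10 min each); with half of all spikes primed
the pooled z exceeds 70.

## Peri-event unit firing

Every event on a macroelectrode contact is paired with every unit isolated
from that contact's microwire bundle (never across electrodes). A trial is
a 2 s raster of 1 ms bins centred on event onset, convolved with a
unit-area Gaussian kernel and sampled every 25 ms (40 Hz). The kernel's
"100 ms" width is read as the Gaussian SD (truncated at ±4 SD); the
alternative FWHM reading would halve the effective width and the package
exposes `sigma_ms` should a user prefer it. Downsampling takes every 25th
1 ms value rather than averaging — the simplest reading — with the sample
grid anchored so that t = 0 is a sample; a 30 ms event therefore owns
exactly two in-event samples. The baseline rate `bl_fr` is the mean over
[−750, 0) ms; the event rate `hfo_fr` is the maximum over [0, duration];
`hfodiff_fr = hfo_fr − bl_fr`. Trials crossing a recording edge are
dropped rather than zero-padded, which would bias rates downward. The
full-resolution convolution conserves spike count exactly, and the package
verifies its mean `hfodiff_fr` against an independent smoothed-Poisson
simulation (500 pipeline trials against 4000 oracle draws agree within a
few percent; note that because the kernel is much wider than most events,
the expected `hfodiff_fr` for a 3× in-event rate gain on a 5 Hz baseline
is ~2.5 Hz, not the unsmoothed 10 Hz, and for homogeneous null trains the
max-over-window statistic is biased above zero — group contrasts, not raw
`hfodiff_fr`, carry the inference).

Units that do not modulate their firing during events are excluded before
modelling: per unit and event class, a paired t-test of `bl_fr` against
`hfo_fr` across trials, Holm step-down across units within the class, and
exclusion when the adjusted p exceeds 0.001. The step-down decision is
tested for exact agreement with a brute-force implementation.

## Mixed-effects models

Firing responses (`hfodiff_fr` or `bl_fr`) are fitted with Gaussian
identity-link mixed models: a fixed intercept, up to three fixed effects
(log10 event power always among them, plus pre-spike / followed-by flags
or unit type) with up to four interaction terms, and crossed random
intercepts for unit, contact and patient (identifiers are globally unique,
so crossed and nested coincide). Estimation is maximum likelihood via
`lme4`; the "maximum quasi-likelihood" label used by some tools for this
family is equivalent here. Wald normal p-values are reported next to each
coefficient. Random slopes are not included — the design lists only the
three identifiers. Validation is by parameter recovery: with 5000
simulated trials and 50 units, the 95% Wald intervals cover the true power
slope and power × pre-spike interaction in ~95% of replicates, and with
the random-effect variances forced to zero (the profiled deviance
evaluated at θ = 0) the coefficients reproduce ordinary least squares to
machine precision.

## Localization metrics

Per patient, the SOZ (resection) ratio of an event class is the number of
events on flagged contacts over the total. The residual-FR measure uses
fRonS plus fRonO with peak frequency above 350 Hz: per-contact rates
(events/min of artifact-free recording) define a graph on the *generator
sites* — contacts with nonzero rate — whose edge weights are the mean of
the two rates times the Euclidean distance in mm. Treating the weight
matrix directly as a distance matrix (the behaviour of the Brain
Connectivity Toolbox's characteristic-path routine on such graphs), a
node's eccentricity is its largest finite entry and the radius is the
minimum eccentricity; the radius difference is
\(\sqrt{r_{\text{all}} - r_{\text{resected}}}\). Zero-rate contacts are
excluded from the node set: including them gives degenerate faint-node
eccentricities that make the full-graph radius systematically smaller than
the resected-graph radius and the root undefined. When
\(r_{\text{all}} < r_{\text{resected}}\) regardless, the package returns
`NA` with a `negative_argument` flag rather than a signed root. Outcome
contrasts (Engel 1 versus worse) use Wilcoxon rank-sum tests;
within-patient pre-spike versus solitary resection ratios use the
signed-rank test.

## The synthetic cohort generator

`synth_config()` fixes the study conditions; the defaults describe an
inter-ictal non-REM depth-electrode recording: 16 contacts, 10 min, 2 kHz;
background fRonO at 2/min, RonO at 3/min and spikes at 3/min per contact,
spikes split 19.8% fRonS / 71.5% RonS / 8.7% sharp following the typical
composition of inter-ictal spikes; SOZ contacts (25% of the implant, a
spatially contiguous cluster at the implant's centre, since implants are
planned to surround the suspected SOZ) carry twice the rates. Events are
homogeneous Poisson streams with a minimum gap of 0.5 s enforced *within*
each stream only — thinning across streams would couple the fRonO and
spike processes and bias the coincidence null away from independence.
With probability `p_prime` a spike gains a dedicated preceding fRonO at a
latency uniform on (0, 300] ms (or under 10 ms in the spike-locked mode),
with spectral power multiplied by `power_gain_prespike` (default 2). The
enrichment parameter multiplies the priming probability on SOZ contacts
and divides it elsewhere; the below-chance coincidence observed outside a
SOZ is emulated by removing (with probability `p_suppress_nonsoz`)
background fRonO that happen to land within 300 ms before a spike there.

Waveforms: pink (1/f) noise plus a 0.5–2 Hz slow wave; HFOs are
Gaussian-windowed sinusoids (duration 20–100 ms, at least ~4 cycles);
spikes are biphasic transients (50–100 ms) whose leading deflection has a
4 ms Gaussian SD, placing their spectral signature below ~100 Hz;
fRonS/RonS add a burst 5–15 ms after the spike onset. `snr_db` is the
ratio of an event's peak amplitude to the channel's *realized broadband
background SD* — the visual event-versus-background contrast a reviewer
would judge — with per-event lognormal amplitude spread (SD 0.15 in
log10) and epileptiform spikes a further 15 dB above that, reflecting that
spikes are the largest inter-ictal events (≈1 mV against a ≈30 µV-SD
background at the defaults). An alternative calibration tied to the
per-frequency wavelet background was rejected: at that scale a 12 dB event
peaks barely above the background's own extremes over minutes of
recording, and no detector could satisfy the package's recall
requirements; the broadband reference keeps `snr_db` meaningful for both
detection and classification. Amplitude calibration is empirical per seed.

Unit activity is an inhomogeneous Poisson train per unit (two per contact
by default, alternating single/multi labels): baseline `unit_base_rate`
(2 Hz default), multiplied inside any event window on the contact by
\(1 + g \cdot \log_{10}(\text{power})\) with the event's ground-truth
power, floored at zero. Spikes drive firing through the same mechanism, so
pre-spike trials show the after-going secondary firing peak.

For outcome simulation, a configurable fraction of patients is seizure
free (Engel 1); their non-resected contacts generate fast ripples
(fRonO, fRonS, and priming) at a residual factor of 0 — the configured
effect size for the cohort contrast, representing complete removal of
FR-generating tissue — while non-seizure-free patients keep full residual
rates. Electrodes sit on 8-contact, 5 mm-pitch shafts through a ~90 mm
volume; the resection covers the contacts nearest the SOZ centroid.

What the generator does *not* emulate: sleep architecture and state
transitions, measured patient PSDs, spike waveform diversity (blunt
spikes and sharp waves are out of scope, as is the detection of such
events), HFO propagation across contacts, and spike-sorting artifacts —
unit trains are given, not sorted. Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under the stated
statistical structure, not performance on clinical recordings.

## Numerical choices and degenerate inputs

* Half-open time convention throughout: sample i covers [i/fs, (i+1)/fs);
  epochs are [start, end).
* Constant wavelet maps have threshold equal to the constant and no
  contours; candidates with no contours or no qualifying topology are
  dropped.
* A spike exactly at an HFO onset does not count as "after" (strictly
  positive latency); a latency exactly at the window bound is not flagged
  (strict <).
* Surrogate SD of zero flags the z as undefined rather than dividing.
* Peak-time ties resolve to the earliest sample.
* Event durations outlasting the trial window clamp to the window end
  with a warning.
* Degenerate paired t-tests (zero-variance differences) give p = 1 and
  exclusion.
* Isolated graph nodes are excluded from the radius with a warning; a
  graph with no finite edge is an error.

## Validation scale

The shipped tests and the acceptance script run the calibration studies at
the scale the science needs and no larger: 200 independent datasets for
the type-I calibration (16 contacts × 10 min each, events-only), 50 seeds
for priming power, two rendered 4-contact × 4-min cohorts for classifier
fidelity, 500 + 4000 trials for the firing oracle, 20 × 5000 trials for
mixed-model coverage, 1000 random instances for each exact oracle, and a
20-patient cohort for the outcome contrast. All randomness is seeded;
identical seeds give bit-identical cohorts.
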