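---
title: "Methods: simulating and analysing mismatch negativity with a fixed three-source model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing mismatch negativity with a fixed three-source model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`mmnsource` implements, end to end, the analysis chain used in clinical
mismatch-negativity (MMN) studies of psychosis risk: a passive auditory
oddball paradigm, ERP preprocessing, sensor-level MMN peak measures, source
activity estimation with a fixed three-regional-source model, and the group
and transition statistics computed on those measures. Because raw clinical
EEG of this kind is generally not shareable, the package pairs the analysis
chain with a synthetic cohort generator whose defaults instantiate the
cohort structure and group-level source-amplitude moments of a
four-group risk design (healthy controls; basic-symptoms-only; combined
UHR and basic symptoms; UHR-only), so the whole chain can be exercised,
tested and benchmarked without any real data.

## The paradigm

2,400 binaural tones at a fixed 500 ms stimulus onset asynchrony: 1,896
standards (1000 Hz, 100 ms, 80 dB) and 168 each of duration- (50 ms),
frequency- (1200 Hz) and intensity- (70 dB) deviants, pseudo-randomized
with at least two standards between any two deviants. `generate_sequence()`
samples deviant positions uniformly over all gap compositions satisfying
the constraint (a stars-and-bars construction), so there is no recurring
template; the first two events are forced to be standards so the gap rule
also holds at the sequence start. "No recurring order" is ambiguous in the
field's usual phrasing; the only rule stated unambiguously is the
two-standard gap, so that is the default, and a stricter variant that also
forbids two same-kind deviants in direct succession is available via
`no_same_kind_adjacent = TRUE`.

## Head model and sources

The forward model is a three-shell concentric-sphere conductor (radii
71/79/85 mm; conductivities 0.33/0.0042/0.33 S/m; 60 Legendre terms by
default). The per-degree radial transfer is solved from the interface
continuity conditions with per-shell rescaled coefficients so the linear
systems stay well conditioned at high degree; in the homogeneous limit the
solution reduces to the classical single-sphere closed form, which the test
suite uses as an independent oracle (relative error below 1e-6 up to
eccentricity 0.8).

Three regional sources — each a triplet of orthogonal unit dipoles — are
fixed anatomically: left and right transverse temporal gyrus (auditory
cortex, Talairach ±41, −26, 11 mm) and anterior cingulate (0, 25, 25 mm).
Distributed-imaging localization (the iterative LORETA-style pass used by
commercial tools to derive such models from grand averages) is out of
scope by design: the three locations are canonical for MMN generation and
user-overridable via the run configuration. With locations fixed, "deriving
the model from the grand average" reduces to lead-field construction, which
is why `build_source_model()` needs only the montage and head model.

Units are physical throughout: source moments in nAm and scalp potentials
in µV, with the lead field carrying the scaling. With the default geometry
the frontal source produces ≈0.09 µV at Fz per nAm, so group-typical
amplitudes of 8–14 nAm give the 1–2 µV fronto-central MMN deflections seen
in practice.

The montage is a 32-channel arrangement: 31 scalp electrodes on idealized
spherical 10–20 positions (left-right symmetric) plus one infra-orbital EOG
electrode, recorded against FCz. Idealized positions rather than digitized
cap coordinates keep the geometry exactly reproducible.

## The synthetic cohort generator

Each subject is described by a profile: per-source MMN amplitudes for the
duration condition (and separate draws for frequency/intensity), an MMN
peak latency in 150–250 ms, noise and blink parameters, and clinical
covariates. Amplitudes are truncated-normal draws (floor 0.5 nAm) whose
location is corrected so the post-truncation mean equals the design moment
— the design moments are the group means the cohort is meant to reproduce.
UHR-criteria subjects draw from transition-stratified moments; the three
basic-symptoms-only converters draw their frontal amplitude from the
transition moments and their temporal amplitudes from group moments.
Frequency- and intensity-condition amplitudes are drawn at control-group
moments for every group, because those conditions carried no group
structure in the motivating design.

The event-locked source activity is built from two components:

* an obligatory auditory response to every tone at the two temporal
  sources (a biphasic transient centred at 100 ms), and
* an MMN component added for deviants at all three sources: a zero-mean
  transient — a 300 ms raised-cosine envelope on a 7 Hz cosine carrier —
  whose negative central lobe peaks exactly at the profile latency with
  magnitude equal to the profile amplitude.

The wavelet shape is a deliberate design choice. A unipolar "bump" carries
substantial DC and sub-1 Hz content that any 1 Hz high-pass removes,
attenuating its peak by ~9–15% and making a noiseless
generate-then-measure round trip irreducibly lossy. The zero-mean wavelet
concentrates its energy near 4–10 Hz, inside the analysis band, so the full
noiseless pipeline returns the configured amplitude to within 2%
(measured: 1.5–1.7% across the latency range). It also resembles real
difference waves, where the MMN negativity is flanked by positive
deflections. The unipolar shape remains available (`shape = "bump"`) for
sensitivity analyses.

The effective dipole orientation of each source is chosen so its
average-referenced projection is maximally negative at Fz, producing the
fronto-central negativity by which MMN is defined; with the orientation
fixed, the regional magnitude (the Euclidean norm over the three
orientation time courses) equals the configured amplitude at the peak.

Background noise is spatially correlated (a rank-16 smooth random mixing
across channels), band-limited to 1–45 Hz with a 1/f power tilt, and
calibrated in the spectral domain so its RMS *after* the 1–20 Hz analysis
filter equals the profile's `noise_rms_uv`. The default is 2 µV. This is
the one place where the generator is calibrated to the averaged domain
rather than to single-trial realism: the three-source pseudo-inverse has a
noise gain of roughly 11–17 nAm per µV of averaged scalp noise, and
between-subject amplitude SDs of 4–8 nAm in the motivating design imply
within-subject measurement noise well below that, i.e. residual averaged
noise of a few tenths of a µV. With ~160 accepted deviant trials, a 2 µV
single-trial RMS reproduces exactly that regime (source-level measurement
noise ≲1 nAm), whereas physiological 8–15 µV single-trial noise would make
the unregularized source estimates noise-dominated and the recovery of the
design moments impossible. Passing tests therefore demonstrate correct
measurement at realistic averaged-domain SNR, not robustness to raw
single-trial EEG noise levels.

Blink artifacts are stereotyped 400 ms transients (80 µV, frontal-dominant
spatial decay, mirrored negatively on the EOG channel) arriving as a
Poisson process at 0.1 Hz. They exist to exercise the ocular rejection
rule: at the default rate they contaminate ~10% of epochs, comfortably
above the detection threshold and comfortably below the 60% exclusion
gate. The generator does not attempt ongoing rhythms (alpha), saccades, or
line noise.

## Preprocessing

The order is fixed: average reference (EOG excluded from the reference
computation and left unreferenced) → 1–20 Hz filter → 500 ms epochs
(−100…+400 ms) with 100 ms baseline correction → artifact rejection →
60% subject gate → per-condition averaging.

The filter deserves a note. The stated analysis filter is "1 Hz and 20 Hz,
12 dB/octave each", applied without phase distortion. A forward–backward
(filtfilt) cascade of 2nd-order Butterworth sections is zero-phase but
*squares* the magnitude response, yielding 24 dB/octave and a passband
droop that costs ~5% of a band-limited MMN peak. `bandpass()` therefore
applies the exact 2nd-order Butterworth *magnitude* response with zero
phase in the frequency domain (FFT with ≥4 s padding), so the net slope is
the stated 12 dB/octave and a 10 Hz component passes with gain 0.97. A
consequence of the gentler net slope is that ~3–4% of broadband power
above 40 Hz survives the low-pass; the 100 Hz attenuation is 28 dB.

Rejection implements two rules: any EEG channel exceeding 120 µV absolute
post-baseline amplitude (the amplitude criterion is absolute, not
peak-to-peak; configurable), or EOG peak-to-peak above 60 µV within the
epoch (the ocular criterion is operationalized as a threshold because the
motivating description names no number; 60 µV is conventional). Blink
handling is rejection, not topographic correction. Subjects with fewer
than 60% accepted trials are excluded; exactly 60% is included. Epochs too
close to a recording edge are flagged (`"edge"`), never silently dropped.

## Sensor and source measures

The MMN waveform is the pointwise deviant-minus-standard difference of the
per-condition averages. At the six analysis electrodes (Fz, F3, F4, Cz,
C3, C4) the peak is the most negative single sample in the closed
150–250 ms window, ties broken to the earliest latency; a mean-around-peak
alternative exists but point-peak is the default because "peak amplitude"
is what the motivating analysis reports. Peak latency is free per subject
within the window.

Source waveforms are the per-sample least-squares solution of the fixed
three-source model on the average-reference EEG subspace (Moore–Penrose
pseudo-inverse; the default 32-channel/9-unknown geometry has condition
number ≈9.5, so no regularization is applied by default; a Tikhonov ridge
is available for degraded montages). The scalar "source activity" is the
maximum of the orientation-norm magnitude within 150–250 ms — chosen for
consistency with the sensor peak measure, since the scalar reduction is
not defined unambiguously in the field; mean-in-window is available as a
config alternative. The magnitude is invariant to rotations of a source's
orientation basis. Residual scalp variance is reported with every
estimate.

Because the magnitude is a norm and the window reduction a maximum,
activity estimates under additive noise are upward-biased but monotone in
the true amplitude; at the default averaged-domain SNR the bias is below
1 nAm (≈ +3–5% at control-group amplitudes).

## Statistics

The statistics layer mirrors the standard reporting of such studies:
one-way ANOVAs per measure (controls vs at-risk, and across the four
subgroups), Bonferroni post-hoc pairwise comparisons implemented as
pooled-variance two-sample t tests with p multiplied by the number of
pairs (Welch available), the correlation matrix of sex (0/1 coded), age,
duration-condition source activities and GAF over the at-risk subjects,
and logistic transition models on the UHR-criteria subset: source
predictors inverse-coded (so odds ratios read as risk per SD of deficit)
and all continuous predictors z-standardized to the analysis subset's own
moments — the subset, not the full cohort, because the models are fit
there. Unadjusted models are one single-predictor fit per variable; the
adjusted model is one joint fit of all eight predictors (mutual
adjustment). Complete or quasi-complete separation is detected and
reported as non-convergence, never as spurious estimates; no Firth-type
repair is attempted. No multiplicity correction is applied across the six
electrodes and three sources beyond the per-measure ANOVAs, mirroring the
reporting conventions of the motivating analyses.

## Numerical choices and problem sizes

* Epochs are 250 samples at 500 Hz; windows are closed intervals; all
  tie-breaks go to the earliest latency.
* Profile latencies are snapped to the 2 ms sample grid so the generative
  calibration identity (peak equals configured amplitude at the configured
  latency) holds exactly at machine precision.
* The FFT filter pads with ≥4 s of zeros (filter tails decay with the 1 Hz
  time constant, ≈0.2 s, so wrap-around leakage is negligible).
* Degenerate inputs are errors, not silent repairs: rank-deficient lead
  fields, zero-variance predictors, single-class outcomes, conditions with
  zero accepted trials, dipoles outside the brain shell.
* The test suite validates the forward model against the closed-form
  single-sphere solution, the inverse against noiseless round trips
  (1e-8 nAm), and the statistics against brute-force formula oracles.
  Cohort-scale checks simulate the full default design (211 subjects,
  2,400 events each at 500 Hz); at roughly 4 s per subject this is the
  dominant cost of a full test run and the problem size we consider
  adequate for stable group-level checks (control-arm recovery of the
  frontal moment, and the four-group ANOVA separation).

## Known limitations

* The spherical head model and idealized electrode positions are
  reproducible but anatomically generic; absolute nAm scales depend on the
  conductivity ratio, which is fixed at the classical 1:80 skull value.
* The generator's noise is calibrated to averaged-domain SNR (see above);
  it does not emulate raw-EEG noise amplitudes, ocular correction, or
  non-stationarities.
* Transition outcomes are simulated only through amplitude moments; no
  dose-response or time-to-event structure is modelled, and covariates are
  drawn independently of source amplitudes (the motivating correlation
  table is near-null for functioning measures).
* With 12 events among 87 UHR-criteria subjects, the unadjusted
  transition odds ratio at the design moments is only marginally
  significant by construction; replicate checks of that contrast sit near
  their pass boundary, which is a property of the design's own effect
  size, not of the estimator.
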