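---
title: "Identifying people from piezo-sensor cardiac vibration spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from piezo-sensor cardiac vibration spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezoid)
```

## The problem

A sheet-type piezoelectric (PVDF) sensor laid on a chair or bed converts body
vibration into voltage. Every heartbeat shakes the body — a
ballistocardiogram — so the sensor picks up a cardiac vibration signal
without anything being worn. In a home with more than one resident, a
monitoring system that detects a collapse also needs to know *who* is on the
sensor. This package implements a spectral-shape method for that: the
0.6–15 Hz frequency spectrum of the cardiac vibration forms a harmonic comb
whose pattern differs between people and is reproducible for the same person
across days, so enrolled subjects can be re-identified from a short
recording.

Two phenomena make a simple "filter around 1 Hz" approach fail and motivate
the spectral view. First, some subjects' vibration carries almost no energy
at the ~1 Hz fundamental: the heartbeat appears only as higher-frequency
carriers amplitude-modulated at the heart rate. Second, beat-to-beat
intervals fluctuate (respiratory sinus arrhythmia) within a hard envelope of
about ±100 ms around the nominal period, so the comb lines are not
perfectly sharp.

## Pipeline

`signal_features()` chains five stages, each exported on its own:

1. **Stable segment selection** (`select_stable_segment`). Recordings contain
   body-movement transients. A 10-s window slides in 1-s steps; each window
   is scored by max/median RMS over its ten 1-s subwindows, and the
   lowest-scoring window wins (earliest on ties; a configurable threshold,
   default 3, flags windows that are still unstable). The score is a ratio,
   so selection is invariant to sensor gain. The 10-s duration is the
   shortest window that resolves the comb at 0.1 Hz while fitting between
   movement artifacts. *The numeric stability criterion is this package's
   stand-in for a manual choice of a clean stretch; nothing in the method
   depends on its exact form.*
2. **Band-limiting** (`bandpass`). A zero-phase frequency-domain mask with
   raised-cosine transitions 0.1 Hz wide cuts everything below 0.6 Hz
   (respiration, drift) and above 15 Hz (noise). A mask rather than an IIR
   filter: deterministic, no phase distortion, no order to choose, and
   exactly zero gain more than 0.05 Hz outside the band. The segment is
   demeaned first (sensor electronics introduce a DC offset).
3. **Spectrum** (`power_spectrum`). One periodic-Hann periodogram of the full
   segment, one-sided, restricted to bin centers in [0.6, 15] Hz, with
   frequency resolution `df = 1/duration` (0.1 Hz at the default 10 s).
   Welch averaging is deliberately not used: splitting 10 s would destroy
   the resolution the harmonic peaks need.
4. **Smoothing and normalization** (`smooth_spectrum`, `normalize_spectrum`).
   A conservative 3-bin moving average (each bin's power redistributed over
   its centred, edge-shrunk window — identical to the ordinary moving
   average away from edges but exactly mass-preserving) suppresses
   single-bin noise maxima before peak counting; width 1 disables it. The
   spectrum is then divided by its rectangle-rule integral over the retained
   band so it integrates to exactly 1: all downstream features depend on
   spectral *shape* only, never on gain, posture or coupling amplitude.
5. **Features** (`find_peaks`, `extract_features`), described next.

## The two discriminants

Let the global maximum of the normalized spectrum define two power
standards, θ = max/2 and θ = max/4. At each standard:

* a **peak** is a bin strictly above θ that is a local maximum (strictly
  above its left neighbour, at least its right neighbour — a flat plateau is
  credited once, to its leftmost bin; band-edge bins use the one-sided test,
  so the global maximum always counts);
* its **region** is the maximal interval around it where the linearly
  interpolated spectrum stays at or above θ, delimited by sub-bin
  interpolated crossings (or the band edge);
* its **excess area** is the trapezoid integral of (power − θ) over the
  region — the convex-upward cap cut off at the standard.

Peaks sharing one above-θ excursion share a region: the area is counted
once, but each qualifying local maximum counts toward the peak number. The
two features are

* **number of peak shapes**: `n = (count@1/2 + count@1/4) / 2`, and
* **sharpness**: `s = n / (area@1/2 + area@1/4)` — the summed caps divided
  by the peak number, reciprocated. The sharper (narrower) the peaks, the
  smaller the caps and the larger the value.

Reading "power more than 1/2" as strict, counting merged excursions once in
area but per-maximum in count, and interpolating crossings linearly are the
conventions fixed here; they keep count@1/4 ≥ count@1/2 for every spectrum
and stabilize areas against bin phase at the coarse 0.1 Hz resolution. The
excess-area (rather than total-area-under-curve) reading makes sharpness a
property of the peaks themselves instead of baseline power far from them.
Whether the areas are computed on the normalized or raw spectrum is
immaterial for counts but not for areas; this package uses the normalized
spectrum so that features are scale-free end to end.

```{r toy}
spec <- spectrum_bcg(0:2, c(0, 4, 0), df = 1)
extract_features(spec)
```

The triangle has one peak at both standards; its caps have areas 1.0 (θ=2)
and 2.25 (θ=1), so n = 1 and s = 1/3.25 ≈ 0.3077.

## Enrollment and identification

Because sharpness divides areas by the peak count, the raw pair
(n, s) is strongly correlated by construction; the discriminative content
is the *deviation* of sharpness from the regression line fitted over all
enrolled sessions. `profile_db()` / `enroll()` maintain that shared
ordinary-least-squares line and a per-dimension scaler; queries are mapped
to (n, residual), z-scored by the enrollment population, and ranked by
Euclidean distance to each subject's centroid (`predict()`), ties broken
lexically for determinism. A dimension with undefined or zero spread — a
single enrolled session, all-equal counts — is dropped from the distance
rather than dividing by zero, so a one-subject database still answers.
`cross_validate()` removes each session in turn, refits regression and
scaler from scratch without it, and reports top-1 accuracy, the confusion
table, and median intra- versus inter-subject distance.

The classifier is deliberately minimal — a nearest-centroid rule with no
trained weights — matching the method's scatter-plot argument: same-person
points cluster, different people spread.

## The synthetic cohort generator

No recordings are distributed with the method, so `make_subject()`,
`synth_signal()` and `synth_cohort()` generate labeled cohorts that realize
its physiological premises; every test runs against them.

A synthetic subject is a phase-locked harmonic comb: nominal heart rate
`f0` uniform on [0.9, 1.3] Hz, orders `h` retained while `h·f0 ≤ 15` Hz.
Beat intervals are `1/f0 + u_i` with `u_i` dominated by a sinusoid at the
subject's respiration frequency (0.18–0.26 Hz) — respiratory sinus
arrhythmia is respiration-locked and slow — plus a small independent
beat-to-beat residual; their sum never exceeds the hard ±100 ms envelope.
Per-subject magnitudes (RSA 2–20 ms, residual 1–4 ms) sit in the low-normal
range of an elderly target population. White per-beat jitter of the full
envelope magnitude was rejected: it would decohere harmonics above about
the third order and make the 10-s spectrum irreproducible, contradicting
the observed day-to-day stability that identification rests on. Harmonics
of order ≥ 2 are amplitude-modulated at the beat frequency; the
"am-suppressed" phenotype (about one subject in four) has a fundamental at
most 5% of its strongest harmonic and modulation index 0.5–0.6, while
"fundamental-rich" subjects start their dominant group at the fundamental.
A sub-0.6 Hz respiration sine, a white sensor-noise floor, and
Poisson-placed 2-s movement bursts at 5× signal RMS complete the trace.

The decisive design choice is that a subject's *signature* is the pattern
their harmonics form relative to the two power standards: a dominant group
(one or two contiguous clusters, the second modelling a reflected-wave
resonance) with spectral density clearly above the 1/2 standard, an
optional set of mid-strength harmonics stably between 1/4 and 1/2, and a
weak tail whose richness varies between subjects. Target density ratios
are drawn with safety margins around the standards and verified at draw
time against an analytic model of the realized spectrum — including the
amplitude-modulation sidebands each harmonic throws onto its neighbours and
the effective per-harmonic width under smoothing and frequency sweep — and
redrawn when a slot lands too near a standard. Two numerical facts shape
the margins, both measured on this pipeline: a single 10-s periodogram
realizes a harmonic's smoothed density within about ±2% when the beat
sequence is respiration-locked, and a stochastic noise floor perturbs a
peak of density P by roughly ±2·sqrt(P·floor) through the periodogram
cross term, which is why the floor is kept ~25 dB below the peaks and
between-subject "diffuse power" diversity is carried by the deterministic
tail instead. Day-to-day change decomposes into a common gain (posture and
coupling; removed by normalization — the reason normalized spectra are
reproducible while raw traces look different) and a smaller per-harmonic
shape component; the default `session_variability` of 0.05 reproduces the
qualitative observation of clearly similar spectra months apart, and
raising it degrades identification monotonically, which the test suite
asserts.

What the generator does **not** emulate: real ballistocardiographic
waveform templates, day-to-day heart-rate drift, posture-dependent sensor
coupling, arrhythmia, or any claim about the spectral distance between real
humans — the separation parameters are calibration knobs chosen so the
simulated cohort realizes the documented premises, not population
estimates. A passing identification test therefore demonstrates that the
pipeline recovers the structure the generator encodes, not field accuracy
on real recordings.

## Numerical conventions

* Rectangle rule for the unit-integral normalization; trapezoid would
  differ by O(df) but one convention must be fixed for bit-stable tests.
* Linear interpolation for sub-bin threshold crossings; trapezoid
  integration for caps.
* Strict `>` against θ for peak candidacy; plateaus credited to the
  leftmost bin; one-sided local-max test at band edges.
* Stable-window ties broken toward the earliest start, within a 1e-9
  relative score tolerance (bit-identical scores arise for periodic
  signals).
* All simulator randomness flows through a single seed per object;
  identical seeds give bit-identical subjects, recordings and cohorts.
* Degenerate inputs error early with messages naming the violated
  precondition (all-zero spectrum, recording shorter than the window,
  band edges beyond Nyquist, duplicate enrollment).

## Problem sizes used by the test suite

The packaged checks run cohorts of 8 subjects × 3 sessions (seed 7) for
identification, 6 × 3 cohorts over five seeds and four variability levels
for the degradation check, 200 random spectra against a brute-force
fine-grid oracle for the feature extractor, and 3-minute recordings at
100 Hz for single-subject properties. These sizes mirror the scale of the
original study (24 subjects one-shot; four subjects across three days)
while keeping the whole suite within a half-minute on one CPU.

## Known limitations

* The two features compress a 145-bin spectrum into 2 numbers; collisions
  between subjects with similar peak counts and cap geometry are expected
  as cohorts grow — the method's own assessment is that it provides a
  coarse level of identification, and nothing here claims otherwise.
* Identification is closed-set: a query is always assigned to the nearest
  enrolled subject; there is no "unknown person" rejection.
* The stability criterion for segment selection is amplitude-based and will
  not flag stationary interference (e.g., mains hum within the band).
* Sampling rates below 30 Hz are rejected rather than resampled.
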