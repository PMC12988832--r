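---
title: "Quantifying photoacoustic ureter visibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoacoustic ureter visibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paviq)
```

## The problem

During pelvic surgery the ureter is easily confused with surrounding
structures, and accidental ureteral injury is a persistent surgical risk.
Photoacoustic imaging offers a route to intraoperative ureter
identification: methylene blue accumulating in the urinary tract absorbs
pulsed near-infrared laser light, and the resulting acoustic emissions are
received by a linear ultrasound array coregistered with B-mode imaging.
`paviq` implements the computational chain needed to quantify how visible
the ureter is in such acquisitions over time after dye injection: image
formation from raw channel data, objective frame selection, reproducible
region-of-interest (ROI) placement, image-quality metrics, nonparametric
group comparison across post-injection time points, and the laser/dye
dosimetry arithmetic that accompanies such a study.

Because in vivo channel data of this kind are typically proprietary, the
package ships a synthetic acquisition generator that emulates the relevant
geometry — a tube-like lumen filled with absorbing dye, lined by an
adventitia of absorbers — so that every downstream stage is exercised by
reproducible, fully characterized inputs.

## Forward model of the synthetic generator

Each absorber \(k\) at position \((x_k, z_k)\) with amplitude \(a_k\) is an
omnidirectional point source that emits, at \(t = 0\), a Gaussian-windowed
sinusoid at the transducer center frequency \(f_0\):

\[ p(t) = \exp\!\left(-\frac{t^2}{2\sigma_t^2}\right) \sin(2\pi f_0 t), \]

with \(\sigma_t\) chosen so the pulse's \(-6\) dB spectral extent matches
the transducer band (15–29 MHz at \(f_0 = 21.33\) MHz gives
\(\sigma_t \approx 26.7\) ns). Element \(e\) at lateral position \(x_e\)
records

\[ s_e(t) = \sum_k \frac{a_k}{\max(r_{ek}, r_\min)}
   \, p\!\left(t - \frac{r_{ek}}{c}\right) + n(t), \qquad
   r_{ek} = \sqrt{(x_k - x_e)^2 + z_k^2}, \]

one-way (receive-only) propagation with \(1/r\) geometric spreading,
\(r_\min = 1\) mm guarding the near-field amplitude singularity, and
additive white Gaussian channel noise \(n(t)\) of standard deviation
`noise_sigma`. The model is deliberately the simplest one for which
delay-and-sum beamforming is a consistent inverse: single scattering, no
attenuation, no element directivity, no transmit delay (photoacoustic
sources fire at \(t = 0\)). It emulates the statistical structure the
analysis chain must handle — amplitude contrast, speckle-like interference,
noise floors, frame-to-frame motion — not acoustic realism; passing tests
on it says nothing about aberration, nonlinear propagation, or fluence
heterogeneity in tissue.

Default acquisition constants are those of a 256-element, 0.09-mm-pitch,
23-mm-aperture array at 21.33 MHz center frequency, sampled at 96 MHz with
an assumed soft-tissue sound speed of 1538.5 m/s. The default channel-line
length covers a 20 mm one-way imaging depth.

## Image formation

`das_beamform()` back-projects each pixel \((x, z)\) along one-way delays
\(\tau_e = \sqrt{z^2 + (x - x_e)^2} / c\), linearly interpolating channel
samples, zeroing contributions outside the recorded window, and summing
with uniform (rectangular) apodization over the full aperture. The pixel
grid is the acquisition-native one — one column per element center, axial
spacing \(c / f_s\) — so no resampling is hidden in the comparison between
channel data and image. Apodization and an optional 15–29 MHz channel
bandpass are exposed as configuration; both default to off/uniform.

Envelope detection is the magnitude of the analytic signal along depth,
computed via the standard frequency-domain construction (negative
frequencies zeroed, positive doubled). Images are normalized to their
brightest pixel and log-compressed as amplitude decibels
(\(20\log_{10}\)), clipped at the display dynamic range (30 dB default).

One numerical convention worth knowing: with an even element count the
lateral grid has no column at exactly 0 mm. A point target placed midway
between two columns excites the full f/0.43 aperture with a carrier-phase
spread of roughly \(\pm\pi\) at the nearest pixels, which splits the axial
main lobe into twin lobes about one wavelength apart. This is diffraction
physics, not an implementation defect; localization checks in the test
suite therefore place point targets on grid columns, where the envelope
argmax is exact.

## Frame selection

A frame is retained when its segmented photoacoustic signal mask and the
segmented ureter-lumen mask share at least one pixel (a minimum-overlap
option exists, default 1). "Stationary duplicate" frames — consecutive
acquisitions that add no information — are flagged when the signal mask's
intersection-over-union with the previous kept frame exceeds 0.95 *and*
envelope correlation inside the mask union exceeds 0.99; a manual
exclusion list is honored for cases (e.g. reverberation copies) the
automatic rule cannot see. Both thresholds are configuration. The rule is
deliberately conservative: flagged frames are excluded, never modified,
and re-running the filter on a filtered sequence flags nothing new.

## ROI placement

The target ROI is a fixed physical rectangle, 3 mm laterally by 0.6 mm
axially by default (33 by 37 pixels on the native grid, rounded), centered
on the brightest photoacoustic pixel inside the intersection of the ureter
and signal masks (ties broken toward the smallest row, then column; even
pixel extents put the extra pixel toward the larger index). If the
centered ROI extends beyond the ureter mask, the position walks one pixel
at a time through eight candidate offsets in a fixed order — left, right;
proximal (shallower), distal (deeper); then the four diagonals — accepting
the first in-bounds candidate that keeps the brightest pixel inside the
ROI, still intersects the mask, and strictly increases the count of ROI
pixels inside the mask. The walk stops at the first fully contained
position, which by first-found ordering favors minimal displacement. The
strict-improvement requirement guarantees termination; before walking, an
exhaustive feasibility scan (integral-image rectangle sums over every
position containing the brightest pixel) decides whether a valid position
exists at all, so infeasible frames fail fast with a "no valid ROI" error
and are dropped from analysis rather than silently mis-measured. On
non-convex masks the greedy walk can stall even when a feasible position
exists elsewhere; that also surfaces as the same error, never as an
invalid placement.

The matched background ROI has identical size at the same image depth,
with its right edge 0.54 mm (6 pixels) from the right edge of the image.
A warning is emitted if it overlaps the target — in practice the synthetic
scenes keep the lumen in the left two-thirds of the aperture.

## Image-quality metrics

All metrics operate on pre-log normalized envelope amplitudes:

* contrast \(= 20\log_{10}(\mu_t / \mu_b)\) in dB;
* SNR \(= \mu_t / \sigma_b\), with the sample (\(n-1\)) standard
  deviation — the population/sample choice is not derivable from the
  study context, so the convention is documented rather than assumed
  canonical;
* gCNR \(= 1 - \sum_k \min\{h_t(x_k), h_b(x_k)\}\) over \(N = 256\)
  shared equal-width probability-mass bins spanning \([0, 1]\) (the
  natural support after normalization; amplitude 1.0 falls in the last
  bin).

gCNR is bounded in \([0, 1]\), zero for identical distributions, one for
disjoint support, and invariant under monotone amplitude transforms that
are applied jointly with the bin edges. Binning can only merge probability
mass, so the binned gCNR never exceeds the exact overlap complement of the
empirical distributions; the suite regression-tests this against a
rank-based oracle. Two Gaussian sample sets with \(|\mu_t - \mu_b| =
2\sigma\) must reproduce the closed-form \(1 - 2\Phi(-1) \approx 0.6827\).

## Group statistics

Per-frame metrics grouped by post-injection time point are compared with
the standard nonparametric chain: Shapiro–Wilk normality per group,
a tie-corrected Kruskal–Wallis omnibus test (chi-square reference,
\(k - 1\) degrees of freedom), and Dunn's post hoc pairwise \(z\) tests

\[ z_{ij} = \frac{\bar R_i - \bar R_j}
   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum(t^3 - t)}{12(N-1)}\right)
   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}, \]

two-sided against the standard normal. Dunn p-values are unadjusted by
default — no multiple-comparison correction is part of the baseline
procedure — with a Bonferroni switch for users who want family-wise
control; both modes are reported explicitly rather than silently chosen.
Significance labels use strict thresholds: `*`, `**`, `***`, `****` for
p below 0.05, 0.01, 0.001, 0.0001, and `ns` at or above 0.05. Boxplot
summaries use linear-interpolation quartiles (quantile type 7) with
whiskers at the most extreme observations within 1.5 interquartile ranges
of the box; the quartile convention is stated because plotting defaults
differ across software. Frames within a time point are treated as
independent samples, mirroring freehand repositioning between
acquisitions; within-subject correlation modeling is out of scope.

## Dosimetry

Fluence assumes a uniform top-hat beam over the fiber face:
\(E / (\pi (d/2)^2)\) in mJ/cm². A 6.78 mJ pulse through a 5-mm fiber
gives 34.53 mJ/cm²; 15.89 mJ gives 80.93 mJ/cm²; against the 25.2 mJ/cm²
ANSI skin limit at 750 nm these are factors of 1.4 and 3.2. Intraluminal
dye concentration distributes the injected mass (volume times vial
strength, default 5 mg/mL from 10-mL/50-mg vials) into an assumed 22.2 mL
lumen volume, divided by the 319.85 g/mol molar mass: 0.5 mL gives
≈352 µM and 2.5 mL ≈1760 µM. Biomarker reference intervals are
inclusive; the
BUN/SC ratio bounds default to the exact fractions 2/0.6 and 13/1.8
(printed 3.33–7.22) so that boundary biomarker values are consistently in
range. Systemic concentration estimates require a user-supplied
distribution volume — no hidden physiological assumptions.

## The synthetic monitoring run

`pipeline_config()` describes a six-time-point (10/20/30/60/70/80 min)
monitoring run with per-time-point signal scaling peaking 20–30 min after
injection (multipliers 1.0, 2.6, 2.3, 1.5, 1.0, 1.8), a lumen ellipse of
2 × 1 mm half-widths centered 8 mm deep and 3 mm left of the aperture
center, 25 lumen and 35 adventitia absorbers, channel noise
`noise_sigma = 0.004` (chosen to put gCNR in the 0.3–0.6 mid-visibility
regime typical of in vivo dye-enhanced imaging), and 0.3 mm frame-to-frame
lumen jitter emulating freehand probe and fiber drift. Every stage derives
its randomness from the master seed, so identical configurations produce
byte-identical output tables. `sample_metric_groups()` with
`default_group_spec()` provides the complementary shortcut of drawing
grouped metric samples directly (28/43/39/64/48/65 samples per time
point, medians spanning 3.46–11.43 dB contrast) for exercising the
statistics stage without imaging.

What the generator does *not* emulate: acoustic attenuation and
aberration, element directivity, clutter with non-Gaussian statistics,
peristalsis-induced deformation (only rigid jitter), and fluence decay
with depth. Conclusions from synthetic runs are about the correctness of
the analysis chain, not about in vivo image quality.

## Problem sizes and numerical choices

The test suite runs its end-to-end checks on a reduced 64-element,
576-sample configuration (≈7 s of pipeline work) and its beamformer
oracle checks on 8-element, 64-sample toys against a brute-force per-pixel
loop; full 256-element frames are beamformed where localization physics is
asserted. Delay interpolation is linear; out-of-window delays contribute
zero; the amplitude clamp \(r_\min = 1\) mm and the 5\(\sigma_t\) pulse
support truncation are the only other numerical cutoffs. Degenerate
inputs error loudly: all-zero envelopes (empty frames), empty search
masks, zero-variance backgrounds, constant samples in normality tests,
and rank tests without rank variation all raise informative conditions
rather than returning NaN.

## Limitations

* The stationary-duplicate rule is a temporal-similarity heuristic;
  depth-reverberation copies within a single frame must be handled via
  the manual exclusion list.
* The greedy ROI walk matches the described first-found behavior and can
  report infeasibility on non-convex masks where a global search would
  succeed; such frames are dropped, trading a little data for
  reproducibility of placement.
* Metrics are computed on normalized envelopes, so absolute amplitudes
  are not comparable across frames — only ratios and distribution
  overlaps are.
* The statistics stage assumes independent frames; longitudinal
  within-animal correlation would require mixed-effects extensions that
  are deliberately out of scope.
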