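---
title: "Stimulus vignetting: model, synthetic experiments, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus vignetting: model, synthetic experiments, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Any aperture or contrast modulation that bounds a grating — a
"vignette" — spreads the grating's Fourier energy. Neurons whose
receptive fields overlap the contrast change respond to the spread
components, so a population readout that is completely agnostic to
orientation (it sums over all orientation channels) can still depend
systematically on grating orientation near the vignette. At the coarse
scale of an fMRI voxel this masquerades as orientation tuning: with a
circular annulus it produces a radial preference map, and swapping a
radial modulator (rings) for an angular one (wedges) rotates every
voxel's apparent preference by 90 degrees.

`vignetta` implements the full chain needed to study this effect at a
desk: an image-computable V1 energy model, the vignetted stimuli, pRF
sampling, a synthetic phase-encoded fMRI session generator, the
voxelwise cosine analysis, and the decoding/RSA suite.

## The model

The model is a steerable-pyramid energy model built entirely in the 2D
Fourier domain with periodic boundary handling.

* **Radial profiles** are raised cosines in log2 spatial frequency:
  scale $s$ has amplitude $\cos\!\big(\tfrac{\pi}{2}\,(x - c_s)/b\big)$
  for $|x - c_s| < b$, with $x = \log_2 r$, spacing and bandwidth both
  $b$ octaves. "Bandwidth" is the FWHM of the *squared* radial
  transfer. Centers run downward from the Nyquist frequency; the
  channel count is $\lfloor(\lfloor\log_2 m\rfloor - 2)/b + 1\rfloor$
  for minimum image dimension $m$ (15 channels for $768 \times 1024$
  at $b = 0.5$; the lowest band then peaks at 3 cycles per minimum
  dimension).
* **Angular profiles** are the standard $\cos^{K-1}$ windows for $K$
  orientation bands (default 6, spanning 180 degrees evenly),
  normalized with the constant-sum identity for even cosine powers so
  that the squared amplitudes of all channels (both quadrature phases)
  plus the high/low residuals sum to exactly 1 at every frequency
  sample. `tiling_error()` verifies this; it is $\sim 10^{-15}$ by
  construction, and energy therefore satisfies Parseval's identity
  against the raw image power.
* **Quadrature pairs.** Each channel has even- and odd-phase members,
  realized as real and imaginary parts of an analytic (half-plane)
  band. Bins on a Nyquist row/column are their own conjugate mirror;
  they get weight $\sqrt{2}$ instead of the half-plane factor 2, which
  keeps energy conservation exact. The **energy** of a channel is
  $\text{even}^2 + \text{odd}^2$: local spectral power, invariant to
  carrier phase.
* **Orientation convention.** 0 degrees means horizontal stripes
  (luminance varying vertically); angles grow counterclockwise, modulo
  180. Carrier phase 0 places a luminance maximum at fixation.

A simulated "voxel map" sums energy across **all** orientation
channels at the scale with maximal total response, then averages
across carrier phases. Any orientation dependence that survives the
orientation sum is a vignetting effect, not tuning.

### Exact phase averaging

The experiments randomize carrier phase over 16 values uniform in
$[0, 2\pi)$. Because energy is a quadratic functional of the image and
the carrier enters linearly, the average energy over any uniform phase
set equals $\big(E[\text{phase } 0] + E[\text{phase } \pi/2]\big)/2$
exactly (cross terms cancel). The package therefore uses the
quadrature pair by default; tests confirm equality with the literal
16-phase average at machine precision. The same identity applies to
the modulator's sine/cosine spatial phases.

### Scale selection

"The scale with maximal response" is computed from the total energy
summed over pixels and orientations, averaged over phases — never per
pixel. For a synthetic session the scale is selected *once* across the
whole stimulus family (both modulator axes and phases): the experiment
holds one carrier frequency, and letting different modulators pick
adjacent scales would compare population patterns across bands. When a
single stimulus family is simulated in isolation,
`simulate_orientation_maps()` selects its own scale.

## Stimuli

Stimuli are `mean + 0.5 * carrier * modulator * annulus`:

* carrier: oriented sinusoid, 0.5 cpd (3T preset) or 1.4 cpd (7T
  preset);
* annulus: raised-cosine vignette with the transition **centered on
  the nominal edge** (mask = 0.5 exactly at the edge radius); presets
  0.5–9.5 deg (3T) and 0.75–9 deg (7T), 1 deg transitions; the
  bias-map demonstrations use the classic 5–9 deg annulus;
* modulator: radial rings (a function of eccentricity; optionally
  scaled with eccentricity, i.e. periodic in $\log_2 r$) or angular
  wedges (a function of polar angle; integer cycles/revolution for
  wrap continuity), square-wave or smooth sinusoidal, in sine or
  cosine spatial phase.

The modulator frequencies are not printed in the source experiments;
the package defaults to 0.5 cycles/deg (linear rings), 1 cycle/octave
(scaled rings) and 12 cycles/revolution (wedges), all configurable.

## pRF sampling and predictions

A voxel is a 2D Gaussian pRF (center, $\sigma$), truncated at
$4\sigma$ and renormalized to unit mass. Its predicted response to
each of the 16 carrier orientations is the pRF-weighted mean of the
corresponding voxel map, averaged across carrier *and modulator*
phases — the latter matters: a static modulator's local spatial phase
adds voxel-specific offsets to the apparent tuning, and only the
phase-averaged prediction shows the clean 90-degree radial/angular
flip. The preferred orientation is the phase of the fundamental
discrete Fourier component of the 16-point tuning vector, which equals
the least-squares single-cycle cosine fit for complete evenly spaced
samples (tested against `lm()` to 1e-10). A tuning vector with zero
fundamental amplitude has no defined preference and is flagged `NA`.

## The synthetic session

The generator emulates the phase-encoded design exactly: 16
orientations, 1.5 s per step, TR 1.5 s, 10.5 cycles, 168 volumes,
252 s per run; 8 conditions ({cw, ccw} x {radial, angular} x {sine,
cosine modulator phase}) x 2 repeats = 16 runs. Counterclockwise runs
ascend the orientation sequence; clockwise runs are defined as its
exact time reversal (starting at 168.75 deg), so direction
normalization in the analysis is exact rather than approximate.

Per-voxel signal: the ground-truth tuning (from the model, per
modulator axis *and phase*) is read out at the orientation shown each
volume, delayed by the hemodynamic model, scaled so the peak-to-mean
modulation is `amplitude_scale` percent (2% default) of the baseline
using the tuning's own statistics (so cw/ccw remain exact reversals),
then drift and noise are added:

* **hemodynamics**: a pure 3-volume (4.5 s) delay by default, matching
  the analysis' shift-based compensation and keeping recovery tests
  sharp; an optional gamma-IRF convolution (shape 4, peak ≈ lag) for
  realism;
* **drift**: per-voxel random linear (±0.5%) and quadratic (±0.3%)
  terms plus a 1/f Gaussian component (0.3% SD) — present so the
  detrend/high-pass stages do real work;
* **white noise**: 1% SD default; `calibrate_noise()` bisects the
  level to hit a target median single-run coherence (e.g. 0.3 for the
  recovery benchmarks).

Everything is seeded; the same seed reproduces a session bit for bit.

The default pRF grid covers eccentricities 2–6.5 deg. This is a
deliberate choice: both modulators share the annulus' inner and outer
radial edges, and near those edges the aperture's own vignette imposes
a radial bias on *both* modulators (empirically, beyond ~7 deg the
radial/angular preference difference collapses to 0). Real V1 data
pool enough voxels that edge-dominated ones dilute out; a 48-voxel
synthetic session does not, so the grid samples the modulator-dominated
zone.

## Analysis choices

`preprocess_run()` applies, in order: discard the first half cycle
(8 volumes); linear detrend; high-pass (zero Fourier bins strictly
below 0.01 Hz); divide by the mean (percent change); circular shift
back 3 volumes; time-reverse clockwise runs; circularly realign by the
discarded half cycle. Numerical details worth knowing:

* the detrend slope is estimated after projecting out the within-cycle
  mean pattern, so a noiseless periodic series passes through the
  whole chain *exactly* (a plain line fit leaks a small slope from the
  periodic signal itself and breaks machine-precision recovery tests;
  on noisy data the two estimators agree to within the trend aliased
  into the stimulus frequency);
* shifts are circular over the retained 10 cycles — the series is
  periodic by design;
* the final realignment makes volume 1 correspond to the first
  orientation of the ccw sequence, so cosine phase 0 maps to 0 deg;
* coherence = fundamental amplitude / root-sum-square of amplitudes at
  all nonzero frequencies (half spectrum). Noiseless model-driven
  voxels have coherence ≈ 0.87–0.93, *not* 1: the model tuning has
  genuine harmonic content, which the coherence denominator counts.
  Tests assert the sharp statement (noiseless coherence equals the
  tuning's own fundamental-to-total ratio) rather than an idealized
  threshold. Maps and comparisons flag voxels below coherence 0.2.

`circular_correlation()` is the Fisher–Lee statistic on doubled angles
(orientations are axial); it is invariant to rotating either sample.

## Decoding and RSA

The classifier is the shared-diagonal-covariance Gaussian ("diagonal
linear") model: per-class means, one pooled per-voxel variance
(floored at 1e-12), equal priors, ties to the lowest class index. On
toy instances its predictions match a brute-force posterior oracle
exactly. Within-modulator decoding is leave-one-run-out; across-
modulator decoding trains on all runs of one modulator and tests on
the other (both directions averaged), optionally rotating the test
labels by 90 deg. The permutation test phase-randomizes each voxel's
raw series independently (amplitude spectra preserved exactly), reruns
the full preprocessing plus statistic, and reports the fraction of
permutations at or above the observed value; with n_perm = 99 and
discrete accuracies the test is slightly conservative (false-positive
rate ≈ 0.04 at nominal 0.05 over 200 null datasets).

RSA uses 1 − Pearson correlation over the 32 condition-mean population
responses; MDS is seeded stress-majorization (SMACOF) with 10 restarts
(first start = classical scaling). On model-faithful synthetic
sessions the characteristic pattern reproduces: within-modulator
accuracy near 1, across-modulator accuracy below chance (≈ 0),
across-modulator accuracy after the 90-degree label shift back near
the within level, and MDS identical-label distances shrinking after
rotating the angular labels by 90 degrees.

## What a green test does and does not establish

The generator emulates the design's timing, condition structure,
hemodynamic lag, low-frequency drift and white noise. It does not
emulate spatially correlated noise, motion, distortion,
eccentricity-dependent spatial-frequency tuning, pRF estimation error,
or across-session coregistration error. Green recovery tests establish
that the pipeline is a faithful inverse of the stated generative
model; they do not reproduce the source study's real-data effect sizes
(e.g. its circular correlations of 0.26/0.20 between predicted and
measured preferences), which require the deposited fMRI data.

## Limitations

* No divisive normalization, surround suppression, gain maps, or
  second-order filters — orientation biases in the model arise from
  vignetting alone, by design.
* The scale-count stopping rule is reverse-engineered from the printed
  channel count; alternates (e.g. a fixed low-frequency floor) give
  counts that differ by one at some sizes.
* Session serialization uses CSV + JSON rather than HDF5/NIfTI (no
  suitable readers in the supported dependency set); `import_real_session()`
  accepts any per-run voxels-by-volumes CSV matrices with a design
  sidecar.
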