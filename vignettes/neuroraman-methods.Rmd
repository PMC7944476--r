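---
title: "Methods: spectral preprocessing, SOM classification and NNLS unmixing for brain-tissue Raman spectra"
author: "neuroraman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral preprocessing, SOM classification and NNLS unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroraman)
```

## Scope and scientific setting

Probe-based Raman spectroscopy of brain tissue produces, per measurement, a
stack of short accumulations (15 by default here) of counts on a wavenumber
axis. The biochemical signal of interest after traumatic brain injury (TBI)
is a shift in relative lipid composition: cardiolipin, a mitochondrial
phospholipid released during the post-injury metabolic cascade, dominates
the bands near 1266 and 1660 cm⁻¹, so its depletion lowers those bands and
raises the 1447/1660 cm⁻¹ peak-height ratio, while ganglioside and
hemoglobin contributions tend to rise. This package implements the analysis
chain needed to read that signal out of raw probe spectra: synthetic-cohort
generation (so everything is testable against known truth), preprocessing,
a hexagonal self-organizing-map (SOM) classifier with a per-class
discriminant index (SOMDI), and non-negative least-squares (NNLS) unmixing
with group statistics.

## The generative model

A clean spectrum is a non-negative mixture plus a smooth background:

$$y(\nu) = \sum_i c_i\, s_i(\nu) + b(\nu), \qquad c_i \ge 0 .$$

**Band shape.** Component spectra $s_i$ are sums of pseudo-Voigt profiles
(`pseudoVoigt()`), the standard line shape for condensed-phase Raman bands:
a Lorentzian/Gaussian mixture with per-band centre (cm⁻¹), FWHM (cm⁻¹),
amplitude and Lorentzian fraction.

**Default library.** Five components — cardiolipin, ganglioside,
hemoglobin, cholesterol and a generic protein — with band tables chosen so
that cardiolipin dominates 1266 and 1660 cm⁻¹, CH₂/CH₃ bending of mixed
proteins and lipids dominates 1447 cm⁻¹, and phenylalanine ring breathing
marks protein at 1003 cm⁻¹. Each component is scaled to unit maximum so
unmixing coefficients are comparable across components. This is a
*synthetic stand-in* basis with literature-informed band positions, not a
measured lipid reference set; the exact composition of a measured basis is
not reproduced here.

**Axis.** The default axis is 600–1800 cm⁻¹ at 1 cm⁻¹ spacing — the
fingerprint region containing every band the analysis interprets. The full
probe domain (−200 to 3723 cm⁻¹, `probeAxis()`) is supported but not the
default.

**Class structure.** Per-class mean mixing coefficients
(`defaultMeanCoefficients()`) encode the injury biology: cardiolipin at
100%/70%/50% of the control level for control/mTBI/sTBI, a modest
ganglioside and hemoglobin increase, a slight cholesterol decrease, and an
unchanged protein level. Per-sample coefficients are drawn from a
truncated-at-zero normal around the class mean with a between-sample
coefficient of variation of 0.15 — group distributions are only described
qualitatively in the literature, so the CV is a choice meant to give
realistic within-group overlap.

**Acquisition artifacts.** Each sample yields 15 accumulations; each adds
(i) i.i.d. Gaussian channel noise with standard deviation `noiseSD`
(default 0.01, i.e. 1% of a unit-maximum component peak; a Poisson
shot-noise option exists but is off by default), and (ii) Poisson-count
cosmic-ray spikes (`spikeRate` default 0.2 per accumulation): 1–3 channels
wide, amplitude 10–30× the spectrum's robust (MAD-based) intensity scale,
purely additive. The fluorescence baseline is an exponentially decaying
curve plus a gentle low-order term (`fluorescenceBaseline()`), amplitude
0.5 with a 700 cm⁻¹ decay constant by default.

**What the generator does not emulate.** No optics (collection efficiency,
quartz-window response, working distance), no wavelength/intensity
calibration error, no detector nonlinearity, no spatial tissue
heterogeneity, and no instrument file formats. Passing tests therefore
demonstrate correctness of the *computational* chain under the stated
statistical assumptions, not robustness to every artifact of real
acquisitions.

## Preprocessing

**Cosmic-ray removal** (`removeCosmicRays()`) exploits the fact that a
spike hits a single readout: for each channel, values deviating from the
cross-accumulation median by more than 8 robust scales (per-channel MAD,
floored by the median positive channel MAD so that the handful of
accumulations cannot produce degenerate scales) are replaced by the median
of the remaining accumulations, and the cleaned stack is averaged. With a
single accumulation the function falls back to within-spectrum detection
against a running median, with a warning. The procedure is idempotent on
the cleaned stack.

**Baseline subtraction** (`subtractBaseline()`) uses an 11-node spline —
the node count is the one parameter the source processing chain states —
in two stages:

1. *Asymmetric envelope fit.* An 11-interior-knot cubic B-spline is fitted
   by iteratively re-weighted least squares; channels above the running
   fit are logistically down-weighted on the scale of the below-fit
   residuals, so the spline settles toward the lower envelope. The noise
   scale is floored by a fit-independent estimate, `mad(diff(y))/√2`,
   which keeps band detection honest when the envelope hugs the data.
   Iteration stops when the weight vector changes by less than 1% in L1,
   or after 20 iterations (a warning is emitted and the last iterate
   used).
2. *Node-anchored interpolation.* Stage-1 residuals identify band regions
   (cores above 3σ, expanded across the flanks while residuals exceed
   max(0.5σ, 1% of the band height) — the relative floor stops far
   Lorentzian tails from swallowing the axis at low noise). Eleven equally
   spaced node windows contribute one anchor each (median position and
   intensity of their baseline-like channels); windows dominated by band
   channels are dropped, and a leave-one-out consistency check removes any
   interior anchor sitting more than 2σ above the spline through the
   remaining anchors — such anchors are elevated inter-band valleys, not
   baseline. A natural cubic spline through the surviving anchors is the
   baseline; the mask/anchor pass runs twice so the second pass works from
   an unbiased fit.

Negative post-subtraction intensities are retained, not clipped: clipping
would bias the downstream least-squares fits.

On isolated marker bands (1003/1266/1337/1447/1660 cm⁻¹) over a known
baseline, recovered peak heights are within a few percent of truth (the
test suite asserts 5%). The known limitation is congested regions: where
several broad bands overlap (e.g. a 1266/1301/1337 cluster), the
inter-band valleys never reach the true baseline, and *any*
envelope-based method will over-subtract there; with the default brain
library the residual bias at 1337 cm⁻¹ can reach ~6%. The marker-band
recovery checks therefore use a library of isolated bands, which is what
the peak-height criterion is about; unmixing, which models the full band
shapes, is the appropriate quantification tool in congested regions.

**Resampling** (`resampleTruncate()`) is linear by default — cubic is
available by flag but can ring near sharp bands — and never extrapolates;
requesting points outside the source range is an error.

**Normalization** (`normalizeSpectrum()`): `none`, `vector` (unit
Euclidean norm) or `area` (unit trapezoidal integral). Whether the source
chain normalized before multivariate analysis is unstated; this package
defaults to vector normalization for SOM input (so distances compare
spectral shape) and no normalization for NNLS (which fits absolute
mixtures), both exposed in configuration.

## SOM classification (SKiNET-style)

Neurons live on a pointy-top hexagonal grid (axial coordinates; distance =
(|dq|+|dr|+|dq+dr|)/2, verified against a breadth-first-search oracle in
the tests). Training is online Kohonen learning: per step, the
best-matching unit (BMU) of a training spectrum is found by Euclidean
distance (cosine available by flag), and all neurons are moved toward the
spectrum with step size
$\alpha(t)\, \exp(-d_{hex}^2 / 2\sigma(t)^2)$,
with learning rate decaying exponentially 0.5 → 0.01 and radius
max(grid)/2 → 1 over 100 epochs (defaults; all in `somTrainConfig()`).
Per-neuron label vectors receive the same kernel-weighted update toward
the sample's one-hot class vector. Because updates are convex
combinations, label weights stay in [0, 1] with row sums ≤ 1 throughout
training — an invariant the test suite checks. Whether the original
supervised step re-trains weights or only labels neurons is not specified
in the accessible description; this package co-trains the label vectors
with the weights and documents that as its definition.

Grid size (10×10), epoch count and split protocol (stratified 70/30,
seeded) are engineering choices for cohorts of tens of spectra, not
reproductions of unstated originals. Initialization is a seeded random
sample of training spectra (PCA-span initialization available).
Determinism is part of the contract: all randomness (initialization,
presentation order) is drawn in R under the config seed, and the C++
training loop is purely deterministic; ties in BMU search break toward the
lowest linear neuron index, ties in classification toward the
first-listed class — bit-reproducibility over elegance.

Classification returns the BMU's arg-max label with confidence equal to
that label's normalized weight; an untrained model is a state error, and a
neuron never visited during training (all-zero labels) yields the uniform
confidence 1/k.

**SOMDI.** The discriminant vector for class $k$ is the mean over neurons
of the weight vector scaled by the label contrast:
$d_k = \tfrac{1}{M}\sum_u (L_{uk} - \overline{L_{u,-k}})\, w_u$.
The accessible description names the construction but not its scaling;
the mean (rather than unit-norm) scaling is this package's definition,
chosen deliberately so that magnitude is meaningful: a map trained on
label-free structure (identical class distributions) yields near-zero
vectors, which the tests compare against a label-permutation noise floor.
Positive peaks (`somdiPeaks()`, local maxima with a 30 cm⁻¹ separation
guard) localize the class-discriminating bands; on cohorts whose classes
differ in a single generated band the top peak falls within ±10 cm⁻¹ of
that band's centre.

## NNLS unmixing and group statistics

`nnlsFit()` solves $\min_c \|y - S c\|_2, c \ge 0$ with the Lawson–Hanson
active-set algorithm (`pracma::lsqnonneg`); the tests verify the
Karush–Kuhn–Tucker conditions on every fit and agreement with an
exhaustive non-negative grid search (step 10⁻³) on small two- and
three-component problems. Components are max-normalized before fitting by
default so coefficients are comparable across components. A constant
offset term is included by default to absorb residual baseline — whether
the original fits carried one is unstated — and is implemented as a
*free-sign* offset (+1 and −1 columns) because baseline-corrected spectra
may legitimately sit slightly below zero; component coefficients remain
non-negative. Fits are applied to per-sample average spectra, not
individual accumulations.

`fitSomdiComponents()` fits the library to the positive part of a class's
SOMDI vector — a physically realistic decomposition, since tissue spectra
are mixtures of positive component contributions; the dominant coefficient
names the component driving that class's activation.

`groupCompare()` runs an ordinary one-way ANOVA per component across
classes (`stats::oneway.test`, equal variances). No multiple-testing
correction is applied by default, matching the per-component reporting
convention of the source analyses; Bonferroni is available by flag. A
degenerate component (zero variance everywhere) is reported as F = 0,
p = 1 rather than NaN.

## Pipeline and reproducibility

`runPipeline()` chains generate/read → preprocess → split → train →
classify → SOMDI → unmix → ANOVA → report, writing every artifact plus a
manifest of MD5 checksums; identical config and seed give identical
checksums, which both the tests and the acceptance script verify by
running twice. Configuration is YAML (`readPipelineConfig()`), with
exactly one input source (synthetic block or a cohort directory) enforced
before any stage runs. Spectra are exchanged as plain CSV or minimal
JCAMP-DX (`(XY..XY)` and AFFN `(X++(Y..Y))` tables); no R package in the
supported stack reads JCAMP-DX, so the reader/writer here is a small
purpose-built one, covering only those plain forms.

## Problem sizes and numerical tolerances

The test suite and `scripts/acceptance.R` run cohorts of 20 samples per
class with 15 accumulations (the acquisition's accumulation count) for the
recovery and classification checks, 5 random seeds for accuracy averages,
and 3 cardiolipin depletion levels (0.9/0.7/0.5) for the effect-size
monotonicity check; smaller cohorts are used where a check does not need
statistical power. These sizes are the package's choice of a demonstration
scale for desk-top reproduction. Key tolerances: exact NNLS recovery at
zero noise to 10⁻⁶ (observed ~10⁻¹⁶); grid-oracle agreement within the
10⁻³ grid resolution; cleaned spectra within 5 noise SDs of truth
channel-wise; marker-band peak recovery within 5%; held-out accuracy ≥ 0.9
averaged over seeds with permutation accuracy at chance ± 0.1.

## Known limitations

- Baseline estimation in congested band regions carries a systematic
  over-subtraction of a few percent (see above); quantification there
  should rely on unmixing, not peak heights.
- Unmixing coefficients are concentration *proxies* (proportionality, not
  absolute calibration), and depend on the reference basis; the default
  basis is synthetic.
- The SOM confidence is a normalized label weight, not a calibrated
  probability.
- The generator's class structure is a two-/three-class composition shift;
  real cohorts add covariates (age, tissue site, post-injury time) that
  the pipeline does not model.
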