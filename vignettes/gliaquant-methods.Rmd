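---
title: "Quantifying astrocyte structure, metabolism and function with gliaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte structure, metabolism and function with gliaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

gliaquant implements the quantitative pipeline of single-cell studies that
compare cortical astrocytes (and neurons) between two groups — typically a
younger and an older cohort. Five measurement modalities are covered: Raman
microspectroscopy of mitochondrial redox state, 3D morphometry of dye-filled
astrocytes, leaflet volume-fraction estimation, patch-clamp feature
extraction, and immunostain quantification. A synthetic-data module generates
every input modality with known ground truth, so each analysis operation can
be validated by loop closure (analyze a generated input, recover the
generating parameter) and by independent numerical oracles.

## Raman redox metrics

Single-cell Raman spectra under 532 nm excitation carry bands at 750 and
1126 cm^-1 (heme vibrations of reduced c- and b-type cytochromes), 1440
cm^-1 (lipid C–C) and 1660 cm^-1 (protein amide I). Under 633 nm excitation
a broad 1550–1580 cm^-1 band reports reduced a-type cytochromes. The
fluorescence background is removed by subtracting a cubic spline through a
fixed set of knots placed outside the informative bands; knot heights are
re-estimated per spectrum as 5-point neighborhood averages of the intensity
around each knot position. The reported metrics are intensity ratios —
I1660/I1440 (protein per lipid), I750/I1660 (reduced c,b cytochromes per
protein), I750/I1126 (c- versus b-type), and the 633 nm band-sum ratio
I[1550–1580]/I[1655–1665] — which makes them invariant to overall intensity
scaling (laser power, collection efficiency).

Numerical choices:

* **Spline end conditions.** The default is a natural cubic spline (zero
  second derivative at the outer knots), the common choice for spectral
  baselines. Natural end conditions reproduce straight-line backgrounds
  exactly but not general cubics near the spectrum ends; `method = "fmm"`
  is available when polynomial exactness up to degree 3 matters. The test
  suite pins the default against an independently coded tridiagonal
  natural-spline solver to 1e-9 relative accuracy.
* **Peak reading.** A peak intensity is the maximum corrected intensity
  within ±5 cm^-1 of its nominal position; the window absorbs small
  calibration shifts. Because the maximum of many noisy samples is biased
  upward, `metrics_532()` applies a 3-point running mean before the window
  maximum (attenuating bands of width ≥ 8 cm^-1 by well under 1%); set
  `smooth_halfwidth = 0` for raw reads.
* **Band sums** use the closed interval on the native wavenumber grid with
  no re-interpolation.
* Negative corrected intensities are kept (a warning is logged when a named
  peak is negative); ratios with a non-positive denominator raise an error
  naming the offending band.

## Astrocyte morphometry

Two-photon z-stacks of dye-filled astrocytes are first resampled along z by
natural cubic spline interpolation so voxels become isotropic at the lateral
pixel size, then filtered with coherence-enhancing diffusion (CED) — a
structure-tensor-steered anisotropic diffusion that spreads intensity along
locally coherent orientations, enhancing thin processes. CED runs per
z-plane with defaults of 20 iterations, structure-tensor smoothing of 1 px,
time step 0.15 and a contrast parameter of (5% of the intensity range)^2;
the output range is clamped to the input range.

Segmentation follows a per-plane hysteresis threshold: the high level is the
plane mean + 3 SD of brightness, the low level mean + 1 SD;
low-threshold components (8-connectivity) survive only if they contain a
high-threshold pixel. In-plane components under 9 pixels are removed, planes
are combined, and 3D components (26-connectivity) under 100 voxels are
removed. The mean anchors both thresholds; plane statistics are recomputed
per plane because brightness varies with depth. The **domain area** is the
pixel area of the mask's z-projection.

Tracings (SWC) are analyzed with 3D Sholl analysis: concentric spheres of
radius 10–100 µm (step 1 µm) around the soma center, counting segment
crossings. Crossings are computed exactly from the quadratic distance
function along each straight parent→child segment, so a segment dipping
through a sphere and back counts twice; a point exactly at radius r counts
as outside. This matches a dense-sampling oracle exactly on random trees.
Derived metrics: number of primary branches (children of the SWC root),
maximal intersection count, ramification index (their ratio), and mean
branch length over root-to-fork, fork-to-fork and fork-to-tip paths. The
endpoint-circumscribed **domain area** is the convex hull of the tip
projections — the unique polygon independent of vertex order.

### Leaflet volume fraction

Leaflets are below optical resolution, so their tissue volume fraction (VF)
is estimated photometrically: with soma fluorescence defined as 100%
space-filling, the normalized fluorescence of the diffuse "fog" between
resolvable branches reads directly as a VF percentage. In the soma plane,
five cross-sections through the soma center (72° apart, i.e. ten half-rays
36° apart) are sampled with bilinear interpolation. Resolvable-branch
crossings are excised: excursions more than 10 percentage points above a
moving-median baseline for runs longer than 0.5 µm are bridged by linear
interpolation. The characteristic VF is the mean over the band 30–40 µm
beyond the soma boundary, averaged over usable half-rays.

Two robustness choices matter here. The soma normalization uses a soma core
eroded by 1 µm, because boundary pixels mix soma and background by partial
volume and would dilute the reference intensity. The excision baseline uses
a 7 µm moving-median window: a window comparable to the crossing width sits
entirely inside the crossing (the median *is* the branch) and fails to
detect it — 7 µm keeps clustered ~1 µm crossings below half the window.
Excised runs are dilated by one sample to catch sub-threshold shoulder
samples. With these defaults, fog levels of 5–10% are recovered within
±0.3 VF points in the presence of 40%-amplitude crossings.

## Electrophysiology

Voltage-clamp step families give the input resistance
R_i = ΔV / ΔI_ss (mV/pA → GΩ, reported in MΩ), where ΔI_ss is the mean
current over the last 20% of the step minus the pre-step baseline, and IV
curves whose least-squares slope is the conductance in nS. Current-clamp
step families (0–440 pA, Δ40 pA, 500 ms) yield action-potential features:

* spikes are detected where dV/dt crosses 10 mV/ms upward (1 ms refractory);
  the onset index is the last sample before the crossing so the threshold
  voltage is read on the pre-rise plateau;
* *rheobase* is the amplitude of the step immediately preceding the first
  spiking step (the conventional first-spiking amplitude is also reported);
* *maximal frequency* is the spike count in the largest step over its
  duration;
* *adaptation* is the instantaneous frequency of the first AP pair over
  that of the last pair in the largest step;
* *overshoot* and *half-width* (duration at the voltage halfway between
  threshold and peak, linearly interpolated between samples) are averaged
  over the spikes of the first spiking sweep;
* *AHP* is the pre-step baseline minus the post-step trough.

Spontaneous IPSCs are detected as deflections exceeding a threshold
(default 10 pA) above a 200 ms running-median baseline, with hysteresis run
closure at half the threshold (so tail noise does not split one event), a
minimum of 1 ms spent above threshold (rejecting narrow noise spikes), and
a rise-faster-than-decay kinetics test. Decay constants come from a
single-exponential least-squares fit after the peak, truncated where the
trace rebounds above its running minimum (an overlapping next event). At a
signal-to-noise ratio of 25 the detector recovers rate and amplitude within
10% and tau within 15%.

## Immunostains

GFAP coverage is the percentage of frame pixels strictly above 10% of the
mean soma intensity; the ezrin metric is the mean intensity over the
territorial domain divided by the mean over the soma. Brightfield DAB images
must be inverted (signal = 255 − value) before analysis. Both metrics are
invariant to intensity scaling; masks are treated as inputs (their
delineation is not part of the pipeline).

## Synthetic data and what it does (and does not) show

Every generator is seed-deterministic and stores complete ground truth; a
study seed expands into per-cell sub-seeds by a fixed counter scheme.

* **Spectra**: polynomial background (in a scaled coordinate spanning
  −1..1 over 600–1800 cm^-1) plus Gaussian bands plus white noise.
* **Astrocytes**: stochastic 3D trees (exponential segment lengths,
  outward-biased random-walk directions, configurable branching
  probability, z-flattened as protoplasmic astrocytes are), optionally
  rasterized into stacks with the soma sphere and 0.5 µm-radius branch
  tubes at intensity 100 over a uniform leaflet fog, plus noise.
* **VF images**: soma disc, uniform fog, and annular "branch crossings"
  (≥ 4 µm apart, as crossings of separate resolvable branches).
* **Ephys**: single-compartment RC step responses (τ = RC); stereotyped
  triangular AP templates at ISIs interpolating between a first and last
  interval (ground-truth adaptation is their ratio); homogeneous-Poisson
  IPSC trains with instantaneous rise and exponential decay.
* **Cohorts**: per-cell parameters drawn lognormally (CV 0.15) around group
  means; the "older" group's means are scaled by configurable effect
  factors (defaults: branch length ×0.75, fog VF ×0.6, cytochrome peak
  ×0.7, membrane resistance ×1.5 — the qualitative aging pattern the
  pipeline is designed to detect; all factors ×1 gives an exact null).

The generators emulate the *geometry and statistics* the pipeline is
sensitive to, not the physics of acquisition: there is no optical PSF or
depth-dependent attenuation, branch tubes have uniform intensity, fog is
spatially uniform, membrane models are passive single compartments, and AP
shapes are stereotyped. Passing tests therefore demonstrate that the
implementation computes the intended quantities and recovers known
parameters under realistic noise — not that the estimators are unbiased on
real tissue data.

Problem sizes were chosen for routine desk-scale validation: rasterized
stacks use 0.4–0.5 µm voxels over fields of ~50–100 µm, cohorts use 15
cells per group, and the calibration runs use 100 null replicates. These
are the package's reference conditions; all sizes are arguments.

## Statistics

Group comparisons use the Mann–Whitney U test (midranks for ties). For
pooled samples of at most 12 without ties the p-value is exact by complete
enumeration of labelings; otherwise a normal approximation with tie and
continuity corrections is used — the switchover follows the smallest sample
sizes at which enumeration is cheap, and the implementation is pinned
against independent exhaustive enumeration and against `wilcox.test`.
One-tailed tests are supported per metric. Box summaries use
linear-interpolation quartiles with whiskers at the most extreme data
within 1.5·IQR fences. Significance bands default to * P < 0.05,
** P < 0.01, *** P < 0.001 and are configurable. No multiple-testing
correction is applied by default, matching per-metric reporting practice;
the unit of analysis is the cell, with patient counts carried alongside for
reporting.

Empirical calibration: across 2000 null simulations (n = 7 vs 7) the
rejection rate at α = 0.05 stays within [0.03, 0.07] (the continuity
correction makes the approximation slightly conservative); with the default
effect factors at n = 15 per group, the four headline metrics are detected
with the correct direction in well over 80% of cohorts.

## Known limitations

* The CED filter uses an explicit scheme with per-plane 2D tensors; it is
  not a 3D diffusion and large time steps can ring (the range clamp guards
  the output).
* Sholl analysis assumes straight segments between SWC nodes; finely
  sampled curved tracings are handled naturally, but sparse tracings of
  curved processes undercount crossings.
* The VF estimator assumes an unsaturated soma and a fog that is homogeneous
  over the 30–40 µm band; saturation or strong gradients bias it.
* The sIPSC detector merges events closer than the hysteresis closure
  allows; at rates well above ~5 Hz (with τ = 10 ms) undercounting becomes
  noticeable.
* `gen_cohort()` generates tracings, soma-plane VF images, spectra and
  passive sweeps per cell; it does not rasterize full 3D stacks per cell
  (use `gen_astrocyte()` directly for stack-level end-to-end runs).

## A minimal end-to-end run

```{r example, eval = FALSE}
co <- gen_cohort(cohort_spec(n_per_group = 15, seed = 3))
rep <- run_study(co$table)
print(rep)
write_report(rep, "report")
```
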