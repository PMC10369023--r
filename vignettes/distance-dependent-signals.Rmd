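---
title: "Distance-dependent detectability and boldness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-dependent detectability and boldness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aposematic animals advertise chemical defences with conspicuous colour
patterns, but conspicuousness is not one thing. An animal can be easy to
*detect* (its edge statistics differ from its background's) and, separately,
*bold* (its own pattern is internally contrasty). Both properties depend on
the viewer: a fish with a spatial acuity of ~3 cycles/degree loses all fine
pattern detail beyond a few tens of centimetres, so a pattern that is bold
in hand may be camouflaged at the distance where predators actually make
detection decisions. `distsig` quantifies both properties as a function of
viewing distance, for an arbitrary receptor-noise-limited (RNL) observer,
from calibrated cone-catch image stacks — and ships a synthetic-scene
generator so the whole chain is testable without field photographs.

## The perceptual model

**Receptor-noise-limited contrast.** Discriminability between two stimuli
with cone catches $q_a, q_b$ is measured in just-noticeable differences.
With per-channel log contrasts $\Delta f_i = \ln(q_{a,i}/q_{b,i})$ and Weber
fractions $e_i$,

$$\Delta S^2 =
  \frac{\sum_{i<j}(\Delta f_i-\Delta f_j)^2\prod_{k\neq i,j}e_k^2}
       {\sum_i \prod_{k\neq i}e_k^2},$$

implemented as the equivalent quadratic form
$\Delta S^2 = \Delta f^\top A\, \Delta f$ with
$A = W - ww^\top/\mathbf{1}^\top w$, $W = \mathrm{diag}(1/e_i^2)$,
$w = W\mathbf{1}$ — identical algebraically, $O(n^2)$, and vectorizable over
pixels. Achromatic contrast is $|\ln(l_a/l_b)|/\omega$ with luminance Weber
fraction $\omega$. `rnl_coords()` factorizes $A$ so that Euclidean distance
in the resulting $(n-1)$-dimensional chromaticity space equals
$\Delta S$; the basis orientation is arbitrary and only distances are
consumed downstream.

The default observer (trichromat, $e_i = 0.05$ per chromatic channel,
$\omega = 0.05$, 3 cpd) is a triggerfish-like parameterization taken from
the visual-ecology literature; none of these values is estimated by this
package and all are overridable in code or config.

**Spatial acuity.** At viewing distance $d$ the finest resolvable cycle
subtends $\theta = (1/a)(\pi/180)$ radians (small-angle approximation;
error < 0.002 % at 3 cpd), i.e. $d\,\theta\,\mathrm{ppcm}$ pixels.
`acuity_blur()` applies an isotropic Gaussian with
$\sigma = d\,\theta\,\mathrm{ppcm}/k$. The cycle-to-sigma factor $k$ is not
dictated by any physical law; we equate one resolvable cycle with $2\sigma$
(default $k = 2$, a FWHM-like convention) and expose $k$ as a config knob so
comparisons with other acuity-modelling conventions are possible. Boundary
handling is reflective so channel totals are conserved and frame edges are
not darkened (which would bias edge statistics).

**RNL ranked filtering.** After blurring, each pixel is replaced by the
channelwise mean of the `ceil(keep_fraction * kernel)` neighbours closest to
it in combined contrast $\sqrt{\Delta S_{chrom}^2+\Delta S_{achrom}^2}$,
iterated. This pools sub-threshold texture and photographic noise while
leaving perceptually sharp boundaries intact. The original description of
the filter does not fix radius, iteration count or selection rule; our
defaults (radius 2, 5 iterations, keep 0.5) were chosen to visibly suppress
2 %-level multiplicative noise on synthetic scenes while preserving a
13.9-jnd step edge (the test suite asserts both properties). All three are
configurable.

## LEIA and the two focal statistics

`local_edge_map()` tiles the processed image into non-overlapping
`block_px × block_px` blocks (default 2, the scale of an edge-detecting
receptive field) and, for each block whose centre lies in the region mask,
computes chromatic and achromatic $\Delta S$ against the forward neighbour
along the horizontal, vertical and two diagonal axes whose centres are also
in-mask. The per-location value is the mean over available axes; the number
of contributing axes is kept as the location's abundance weight, so
locations at ragged mask borders are down-weighted rather than dropped.
Forward-only neighbours mean no pair is double counted.

Two interpretation choices here are genuinely open and are fixed as
follows:

* *Abundance weighting.* The weight is the count of valid axis comparisons
  at a location — the only quantity in the computation that measures local
  comparison abundance. `weighted_cov()` uses frequency-style weights with
  the population (biased) variance; the choice of variance convention is
  arbitrary but changes small-sample values, so it is stated and tested
  (doubling all weights is a no-op; CoV is scale invariant).
* *Tiling vs sliding.* Blocks tile (stride = block size). A sliding window
  would correlate adjacent locations without changing the weighted CoV
  appreciably, at 4x the cost.

The two statistics are then:

* **Boldness** — `Lum.CoV` and `Col.CoV` of the *animal* map alone: the
  internal contrastiness of the pattern once detection has occurred.
* **Detectability** — $|CoV_{animal} - CoV_{background}|$ per channel type:
  the degree of edge-statistic mismatch against the immediate visual
  background; low values mean background matching.

A flat region has an undefined CoV (zero mean); such records are dropped
with a warning rather than imputed, mirroring listwise handling in
small-sample field datasets.

The background ROI on synthetic scenes is an annulus from the animal's
outline to twice its extent — a stand-in for "the animal's respective
visual background", whose exact spatial extent the field protocol leaves
unspecified.

## The synthetic world

`generate_scene()` builds cone-catch scenes that are analytically
invertible: textures are binary blob maps (thresholded smoothed Gaussian
fields) whose two phases are placed in noise-scaled log space exactly
$\Delta S_{target}$ apart, so realized pre-noise contrasts equal their
targets identically. Pixel noise is multiplicative lognormal (camera and
scene noise are multiplicative in linear catch space). Each texture has two
layers:

* a **fine layer** (default 4 px elements, coverage 0.5) carrying the
  within-pattern detail that acuity blur removes at far distances, and
* an optional **coarse layer** (default 8 px elements) emulating
  large-scale markings — the bold rims common in aposematic species — and
  the large-scale structure of natural backgrounds, which survive far
  viewing distances.

Every texture mixture is centred on its realized spot coverage in log
space, so the pooled (blurred-to-uniform) appearance of any pattern equals
its base colour. Without this, sparse bold patterns would carry a
blur-proof mean offset against their background and could never
background-match at distance — an artefact, not a signal.

`generate_cohort()` encodes the hypothesis structure the statistics are
meant to recover, with the 13-species design as default: 3 undefended (NR),
4 weakly-toxic/unpalatable (Class II) and 6 toxic-and-unpalatable
(Class I & II) species with per-species sample sizes
(24, 21, 17, 15, 27, 15, 15, 25, 10, 8, 23, 8, 18; 226 individuals), and an
unpalatability score $u \in [0,1]$ (the 1 − ED50, range-normalized
convention) rising with class severity. The monotone effect map is:

* fine-layer contrast $\times (1 + 1.5u)$ and coverage
  $0.5(1 - 0.8u)$ — defended species carry sparse, high-contrast markings
  (it is the *sparseness* that raises the edge-contrast CoV; a uniformly
  fine high-contrast checkerboard is not "bold" under a CoV statistic);
* fine element size interpolating from the background's 4 px to 3 px —
  sub-resolvable at 30 cm for the default observer at 50 px/cm;
* coarse-layer coverage interpolating from 0.35 to 0.08 — defended species
  have sparser, hence more heterogeneous, large markings whose boldness
  signature survives 30 cm;
* every background is individual: contrasts jittered ±20 %, coarse
  coverage drawn from [0.05, 0.30] and coarse contrast from 1–3x base per
  scene. The animal's coarse layer is drawn independently of its
  background's, with contrast fixed at the middle of the background range:
  background matching is imperfect at the coarse scale for defended and
  undefended species alike, and a defended animal's surviving coarse
  pattern sits *inside* the distribution of backgrounds rather than outside
  it.

Setting `effect_gain = 0`, `sparseness_gain = 0`,
`fine_pattern_for_defended = FALSE`, `coarse_contrast_span = 1` and equal
`animal_coarse_coverage` endpoints yields a null cohort in which u is
independent of every pattern parameter.

This world was designed (before freezing) so that the mechanism under
study is actually present: at 2 cm the fine defended phenotype separates
animals from backgrounds; by 30 cm the fine layers of all species and
backgrounds fall below the post-filter noise floor, the folded difference
$|CoV_a - CoV_b|$ decorrelates from $u$ against the broad background
distribution, while within-animal boldness ordering partially persists
through the coarse layer. What a green recovery test establishes is that
the pipeline recovers this stated structure — not that real nudibranchs
have these parameter values. Features of real data the generator does not
emulate include non-elliptical bodies, spatially correlated illumination,
depth-dependent light attenuation (negligible at the field protocol's
working distances) and pattern elements with directional anisotropy.

Scene parameters worth restating with units: scenes default to 64 px at
50 px/cm (a 1.3 cm field of view, macro-photography scale; the animal fills
~70 % of the frame height); cohort pixel noise is sdlog 0.05 (5 %
multiplicative noise, typical of field photography), single test-bench
scenes default to 0.02.

## The statistics battery

* `range_normalize()`: $(x-\min)/(\max-\min)$.
* `kruskal_wallis()` and `dunn_posthoc()` implement the tie-corrected H and
  Dunn z with Bonferroni adjustment in-package (the usual helper packages
  are deliberately not dependencies); both are tested against brute-force
  rank oracles and `stats::kruskal.test`.
* `ordered_quantile_normalize()`: rank-based inverse-normal scores
  $\Phi^{-1}((r-0.5)/n)$ with average ties.
* `lmm_class_distance()` fits random-intercept models
  (`sqrt(response) ~ factor(distance) + (1|species)` within each defence
  class, and `~ defence_class + (1|species)` at each distance). Because no
  Satterthwaite helper package is available in the target environment, the
  Satterthwaite denominator df is implemented here for the
  random-intercept case: the REML profile is evaluated in closed form per
  grouping structure, the variance-parameter covariance comes from a
  numerical Hessian of that profile, and multi-df contrasts use the
  eigendecomposition construction with $\nu = 2E/(E-q)$. A residual-df
  method is provided as a fallback and the tests assert that conclusions
  are df-method robust at cohort sizes. Singular fits (species variance
  estimated at zero) fall back to fixed-effects ANOVA with a logged note.
* One printed-methods inconsistency is worth recording: the source
  protocol describes applying a square-root transform to "left-skewed"
  data, although a square root conventionally treats *right* skew. The
  package applies the square root as printed (CoV statistics here are
  right-skewed, where the transform behaves sensibly) and exposes
  `transform = "none"` for sensitivity analysis.
* `distance_correlation_regression()` computes, per metric and distance,
  Pearson's R between ordered-quantile-normalized species *medians* (as
  printed in the protocol; medians, not means) and range-normalized u,
  then fits OLS of R on distance (4 points, F with 1 and 2 df) — the
  summary that shows whether a statistic's association with chemical
  defence decays with viewing distance.

## Numerical choices and degenerate inputs

* Cone catches are floored at $10^{-6}$ of each channel's maximum before
  log transforms; dark pixels exist in field imagery and $\ln 0$ does not.
* Blur kernels truncate at $4\sigma$ and renormalize; $\sigma$ below
  $10^{-3}$ px short-circuits to the identity (the acuity → ∞ limit).
* Ranked-filter ties in $\Delta S$ break deterministically by kernel
  position, so results are bit-reproducible.
* All randomness flows from one top-level seed; per-scene substreams are
  derived with a fixed integer recurrence, so cohorts are reproducible
  and individual scenes can be regenerated in isolation.
* The TIFF codec (no TIFF reader exists in the target R environment)
  writes uncompressed little-endian 32-bit-float grayscale pages, one per
  channel, and reads back float32/uint8/uint16 pages of either byte order;
  integer pages are rescaled to [0, 1] with a message. It is
  cross-validated against an independent Python TIFF implementation in the
  test suite.

## Scaling in the test suite

The acceptance tests run the full image pipeline on cohorts scaled to 8
individuals per species and 64 px scenes (the 13-species, 3-class design
and all couplings unchanged) to stay inside a CI-scale time budget; the
mixed-model type-I calibration uses record-level simulation, which is what
that criterion tests. The full 226-individual default exists for users, not
for CI.

## Known limitations

* The Satterthwaite implementation covers the single-random-intercept
  models this analysis uses, not arbitrary mixed designs.
* Detectability compares CoV summaries, not full edge-contrast
  distributions; two regions with equal CoV but different distribution
  shapes count as matched.
* The generator's defended phenotype confounds contrast, sparseness and
  element size by design (they covary in the hypothesis being encoded);
  recovering their separate contributions is not a goal.
* Viewing geometry is frontal and planar; oblique views and
  size-dependent subtended angles are out of scope.
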