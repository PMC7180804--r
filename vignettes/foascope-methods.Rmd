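---
title: "Counting live and dead yeast through a fiber optic array: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting live and dead yeast through a fiber optic array: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A portable microscope built around a tapered fiber optic array (FOA) relays
a magnified image of a specimen onto a camera sensor. Two artifacts dominate
its micrographs: a periodic core/gap lattice (light passes through the fiber
cores but not the lighttight gaps between them) and uneven illumination (the
field center is darker than the rim). On top of these, a methylene-blue
viability assay renders dead yeast cells as uniformly dark disks while
unstained live cells show a bright interior surrounded by a darker rim.

`foascope` implements the full analysis chain for such images: artifact-aware
synthetic data generation, contrast-limited adaptive histogram equalization
(CLAHE) preprocessing, hexagonal scan-window detection of live and dead
cells, particle counting with a minimum-size rule, matching against ground
truth with cluster exclusion, k-fold cross-validated threshold selection,
and the closed-form optics of the tapered fiber bundle.

## The synthetic scene generator

No public micrographs exist for this instrument class at the required level
of annotation, so every downstream stage is exercised on synthetic scenes
with exact ground truth. A scene is composed as

```
image = quantize8( clip( base * lattice_gain * illumination_gain + noise ) )
```

where `base` paints cells on a uniform background, and the two gain rasters
reproduce the instrument's artifacts.

**Coordinates.** Throughout the package, `x` is the column and `y` the row
index, 1-based, with pixel centers at integer coordinates (the natural
convention for R matrices).

**Defaults and what they emulate.** The geometry follows the instrument's
stated hardware numbers: 3--5 µm yeast cells at 6× magnification over a
1.4 µm sensor pixel give 13--21 px cell diameters (radius range 6.5--10.5 px);
a ~9 µm large-end fiber core gives a ~6 px core image (core radius 3 px,
pitch 7 px, hexagonal). Intensity levels are background 0.55, live interior
0.85, live rim 0.25 (2 px thick), dead 0.30 — satisfying the orderings the
assay produces (dead < background < live interior; rim < background). Gap
transmission is 0.45 versus 1.0 in the cores, a strong lattice artifact.
Illumination rises quadratically from 0.7 at the center to 1.0 at the
corners. Additive Gaussian noise with sd 0.02 (on the [0, 1] scale) is the
default acquisition noise; the benchmark uses 20 scenes of 256 × 256 px with
15 live + 15 dead cells each. These values were fixed once as the package's
study conditions.

**Placement** is rejection sampling with a hard cap (default 10,000 attempts
per cell): non-cluster cells keep at least `min_separation_px` (26 px ≈ 1.5
mean diameters) between centers; a configurable `cluster_fraction` of cells
is instead placed 0.4--0.9 separations from a random partner and flagged, so
cluster-exclusion logic is testable. Failure to place raises an error naming
the failing cell rather than silently under-populating.

**What the generator does not emulate:** optical point-spread blur,
Poisson/shot noise, staining variability, out-of-focus debris, and cell
shape irregularity. Passing the benchmark therefore shows that the chain is
correct and robust under the modeled artifacts, not that the fixed default
thresholds transfer to real acquisitions — on real data the cross-validated
threshold selection path is the supported route.

## Preprocessing

The enhancement chain mirrors the device protocol: convert RGB to CIE
L\*a\*b\* (D65 sRGB, via `grDevices::convertColor`), scale L to [0, 1], run
CLAHE on the L channel, rescale, convert back to sRGB, and reduce to
grayscale with fixed BT.601 luma weights (0.299, 0.587, 0.114). Grayscale
input is replicated across channels first; because the chroma channels are
then neutral, the chain collapses to CLAHE on the gray values up to
histogram-bin misalignment (measured below 0.05 absolute on 8-bit data).
Both the enhanced L channel and the re-grayscaled image are available
(`keep_intermediates = TRUE`); the grayscale output is the default detection
input.

**CLAHE semantics** (all are choices the protocol leaves open, fixed and
documented here):

* tile grid 25 × 25, histogram bins 256, clip limit 0.1;
* the clip limit is a *fraction of the tile's pixel count per bin*
  (`clip_limit = 1` never clips), matching its documented 0.01--1 range;
* one clipping pass with the excess redistributed uniformly over all bins
  (no iterative re-clipping);
* each tile's mapping is its clipped-histogram CDF; pixels are mapped by
  bilinear interpolation of the four surrounding tile mappings, and border
  half-tiles fall back to the nearest tile (standard CLAHE convention);
* ties inside a bin share the CDF value, so mappings are monotone
  non-decreasing.

The per-pixel moving-template form (`moving_window_equalize`) — slide an odd
window over the image, equalize the window histogram over the full gray
range, assign the transformed center value — is implemented as the exact
reference: with replicate padding (index clamping), so no histogram mass is
invented from outside the image. It is O(N · window area) and serves as the
oracle against which tiled CLAHE is validated on small images.

**What the enhancement does and does not fix.** On every seeded scene the
center/border intensity ratio moves strictly toward 1 (illumination
flattening), and live-cell interior-versus-rim contrast is not reduced. The
core/gap gray difference, however, is *not* reduced: histogram equalization
is rank-based, and the gaps remain the darkest consistent background
structure, so their contrast survives (and can grow) under any clip limit.
The lattice is neutralized one stage later, by the detector's region
averaging: a scan window integrates ~160 pixels, spanning several lattice
periods, so the residual background fluctuation of the window mean is less
than a third of the weakest dead-cell dip on noise-free scenes. This is the
mechanistically honest reading of why the chain works, and it is what the
test suite asserts.

A related limitation: on a *featureless* noisy image, equalization
manufactures full-range contrast out of noise (noise spreads over many bins,
none of which ever reaches a 10% clip limit), which can produce spurious
live-score peaks around 0.17. Blank-scene behavior at the default thresholds
is therefore guaranteed only for noise-free blanks; in practice a cell-free
field should be recognized by its score distribution, not by thresholding.

## Detection

The scan window is a flat-topped regular hexagon of circumradius `R`
(default 8 px ≈ the mean cell radius), rasterized on the pixel grid and
split into an edge ring (pixels within `ring_thickness` = 2 px of the
boundary, measured as half-plane slack) and an interior. Membership uses the
six half-plane inequalities; the mask is symmetric under 180° rotation.

Two score maps are computed at every position where the window fits (border
positions are invalid, never detected):

* **live score** = mean over interior − mean over ring. Live cells (bright
  interior, dark rim) are maxima. Region sums are normalized to means so the
  threshold does not rescale with window size, and the score is invariant
  under global additive intensity shifts. The sign convention (interior
  minus edge) is chosen so that "the largest difference" is a live cell,
  consistent with the described cell appearance.
* **dead score** = mean over the whole hexagon. Stained dead cells are
  minima.

Peaks are retained by thresholding plus greedy non-maximum suppression:
candidates are local extrema over the 8-neighborhood (plateau-inclusive),
filtered by the threshold (strictly beyond it), then accepted from most
extreme outward, suppressing anything closer than `nms_radius_px` (13 px ≈
one cell diameter) to an accepted detection. Ties break deterministically
(lower row, then lower column). Cross-class conflicts within the suppression
radius keep the detection with the larger margin over its threshold,
normalized by its score map's spread.

**Default thresholds.** The live threshold defaults to a fixed contrast of
0.17 — the live score is shift-invariant, so a fixed value is meaningful
across exposures. The dead threshold defaults to *median(dead score map) −
0.095*: equalization places the background at a data-dependent absolute
level, so a fixed window-mean cutoff cannot transfer between images; the
median of the map is a robust background estimate and 0.095 sits just under
the enhanced dead/background contrast. Both defaults were calibrated on the
synthetic study conditions; for anything else, choose thresholds by
cross-validation (below).

## Counting, matching, and cross-validation

**Particle counting** reproduces the "Analyze Particles" rule: connected
components (8-connected by default, the common particle-analysis
convention; 4-connectivity available) of at least 2 px, with no upper size
limit, each contributing its area centroid. Detections are painted as small
disks into a binary mask before counting, so each detection is one particle.

**Matching** is greedy one-to-one by increasing distance among same-label
(detection, ground-truth) pairs within `max_dist_px` (default 10 px, about
one cell radius). Ground-truth cells flagged as cluster members — either by
their `cluster_member` flag or geometrically (any neighbor closer than 1.5
mean diameters) — are excluded from matching and from the denominator,
mirroring the manual protocol's cluster exclusion. A detection landing on an
excluded cluster cell is reported as a `cluster_hit`, not a false detection;
remaining unmatched detections are false detections. Conservation holds per
class: matched + missed + excluded = total ground truth. The identification
rate is 100 · matched / ground-truth (one decimal); e.g. 129/139 → 92.8 and
183/214 → 85.5 (85 at integer precision).

**Cross-validation.** The pipeline's only free parameters are the two score
thresholds, so that is what the k-fold procedure selects: scenes are
shuffled into k = 5 folds by a seeded permutation; for each fold the
threshold pair is chosen on the other folds by grid search, maximizing the
mean identification rate minus the false-detection rate (false detections as
a fraction of ground truth); the chosen pair is then scored on the held-out
fold. The default grids (live 0.14--0.26 by 0.02, dead 0.39--0.47 by 0.01)
bracket the operating points observed across noise levels. On the 20-scene
default benchmark the fold-mean rates are ≥ 98% for both classes with under
1% false detections; the package's acceptance bar is ≥ 90% and ≤ 10%,
run in under a minute on one CPU.

```{r cv-example}
library(foascope)
scenes <- simulate_scenes(20, seed = 42)
cv <- kfold_evaluate(scenes, k = 5, seed = 42)
glance(cv)   # fold-mean identification and false-detection percentages
tidy(cv)     # per-fold rates and chosen thresholds
autoplot(cv)
```

## Optics of the tapered fiber bundle

`tapered_fiber_spec()` gathers the optical parameters (lengths in µm, angles
in radians) with the instrument's values as defaults: core radius 0.6 µm at
the small end, 550 nm illumination, core/cladding indices 1.52/1.50.

* **Normalized frequency** `V = 2πr/λ · sqrt(n_core² − n_ext²)`;
  `V < 2.405` means only the fundamental mode propagates. The instrument's
  design notes swap the core/cladding labels between formulas; the package
  stores a single explicit `(n_core, n_clad)` pair (with `n_ext` defaulting
  to `n_clad`) and requires `n_core ≥ n_ext`, the only assignment under
  which guided propagation and the evanescent formula below are defined.
* **Reflection-angle recursion** `φₙ = π/2 − (n₀/n₁)·arcsin(θs) + (2n−1)δ/2`
  (strictly increasing in the reflection count for δ > 0) and **mode feature
  angle** `θₙ = (n₀/n₁)·arcsin(θs) − (n−1)α` (strictly decreasing for
  α > 0). The `arcsin(θs)` form is kept exactly as designed — `θs` is
  validated as an arcsine argument (|θs| ≤ 1) rather than silently replaced
  by `sin(θs)`. The two cone angles δ and α are stored as distinct
  parameters since the design relates them nowhere.
* **Evanescent penetration depth** `dp = λ / (2π·sqrt(n_core²·sin²θ −
  n_clad²))`, valid only under total internal reflection
  (`n_core·sinθ > n_clad`), strictly decreasing in θ.
* **Lattice packing and sampling**: effective transmission area fraction
  `(π/3.464)(d/D)²`; sampling periods `√3·d` (hexagonal) and `2d` (square),
  read as spatial frequencies `1/(√3 d)` and `1/(2 d)` — the only reading
  that reproduces the 2/√3 ≈ 1.15 hexagonal resolution gain; and the
  field-of-view area ratio, e.g. (950 × 700)/(625 × 475) = 2.24.

**Known inconsistencies in the instrument's quoted design figures, retained
as open discrepancies rather than reproduced:** the normalized-frequency
formula at the stated parameters (r = 0.6 µm, λ = 550 nm, 1.52/1.50)
evaluates to ≈ 1.685, not the quoted 0.41 (both are below 2.405, so the
single-mode conclusion stands); and `√3 · 0.61 µm ≈ 1.056 µm`, not the
quoted 0.95 µm resolution. The package computes the formulas as written and
documents the mismatch; the tests assert the computed values.

## Numerical and degenerate-input choices

* Equal illumination levels or equal lattice gains are allowed and produce
  constant rasters (degenerate but valid).
* Histogram binning: `bin = min(floor(v·n_bins), n_bins − 1)` on [0, 1];
  constant images are fixed points of every equalizer.
* NMS and matching are fully deterministic (explicit tie-breaks); renders
  are bit-identical for a fixed seed (`withr::with_seed` around every draw).
* The identification rate is undefined at zero ground truth and raises an
  error instead of returning NaN.
* 8-bit quantization is `round(255·v)/255` after clipping to [0, 1].

## Problem sizes

The shipped tests and the acceptance script use 256 × 256 px scenes
(20 scenes for the benchmark), oracle comparisons on rasters of 64 × 64 or
smaller, and exhaustive enumerations on 5 × 5 to 32 × 32 inputs — sizes at
which brute-force oracles are exact and the whole suite stays fast while
every code path is exercised at the study's geometric scale.
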