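---
title: "Monitoring enzymatic cell detachment from lens-free image pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring enzymatic cell detachment from lens-free image pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detachmon)
```

## The problem

Adherent cell cultures are harvested by proteolytic enzymes (trypsin,
TrypLE). Stopping the reaction too early leaves cells on the substrate;
stopping too late degrades viability and differentiation potential. The
usual endpoint call — an operator watching the flask — is neither
standardised nor reproducible, and the classical quantitative surrogate,
cell circularity measured on a segmented image, is fragile at high density.

Lens-free imaging reconstructs two co-registered modalities per acquisition:
a *phase* image (equivalent to phase contrast), in which both spread and
rounded cells are visible, and an *intensity* image (equivalent to bright
field), in which a detaching, balled-up cell produces a compact bright
region while spread cells produce essentially nothing. `detachmon` exploits
this asymmetry. Its core feature is the **percentage of detached cell
regions**,

$$\mathrm{pct}_t \;=\; 100\cdot\frac{|D_t|}{|C_t|},$$

where $C_t$ is the set of cell pixels in frame $t$ and $D_t \subseteq C_t$
the subset classified as belonging to detached cell regions. The feature is
deliberately *region*-based, not cell-based: no instance segmentation or
tracking is attempted, which is what keeps it usable in overconfluent
cultures where single-cell segmentation fails.

## The extraction pipeline

Per frame, three stages run in a fixed order.

**1. Pixel classification (phase image).** A random forest classifies each
pixel as cell or background from a multi-scale filter bank: six families
(Gaussian smoothing, Laplacian of Gaussian, Gaussian gradient magnitude,
difference of Gaussians, structure-tensor eigenvalues, Hessian eigenvalues)
at six scales $\sigma \in \{0.7, 1, 1.6, 3.5, 5, 10\}$ px — a 36-cell
selection grid. The two eigenvalue families contribute two channels each,
so the forest consumes 48 image channels; this is the standard reading of
that selection grid and the only one consistent with covering intensity,
edge and texture cues at every scale. Filters use reflective boundary
padding. The forest has 100 trees (probability forest, argmax decision,
ties to background); the tree count is a configuration default — the
workflow this emulates does not pin it down, which is why accuracy claims
in this package are made on synthetic data only. The raw mask is then
post-processed: background holes smaller than 200 px (4-connectivity) are
filled, then foreground objects smaller than 50 px (8-connectivity) are
removed — in that order, both comparisons strict.

**2. Mask algebra (both modalities).** With the frame normalized to
$[0,1]$:

1. threshold the phase image at **0.65** and the intensity image at
   **0.35** (inclusive $\ge$, so saturated halos stay in-mask);
2. OR the two bright masks; fill holes smaller than **1000 px**
   (4-connectivity); AND with the cell mask; drop regions smaller than
   **30 px** (8-connectivity) — these are the *seeds*;
3. dilate the seeds with a Euclidean disk of radius **5 px** (zero padding
   outside the image); AND with the cell mask; every 8-connected component
   of the attached remainder smaller than **50 px** is reassigned to the
   detached mask.

The result always satisfies $D_t \subseteq C_t$, and
$C_t = D_t \,\dot\cup\, (C_t \setminus D_t)$ is asserted as a partition
invariant after every frame. "Disk of 5 pixels" is read as *radius* 5 (the
radius/diameter ambiguity is real, so the radius is configurable), and all
area comparisons are strict `<`, exactly as the parameter names
(`*_lt`) say.

**3. Scalar features.** `percent_detached()` as above; when a frame has no
cell pixels the percentage is *missing*, never zero, so degenerate frames
cannot drag a profile down silently. The comparison baseline
`mean_circularity()` computes $4\pi A/P^2$ per 8-connected component,
averaged unweighted over components (an area-weighted mode exists but is
not the default; whether the historical baseline weighted by area is
unknowable from its description, and unweighted matches "averaged over the
cell population" most directly).

### Normalization

The 0.65/0.35 thresholds presuppose a $[0,1]$ scale that raw instrument
output does not come with. File-loaded frames are therefore normalized by
robust percentile min–max scaling (1st/99th percentile by default, clipped,
per frame). Per-frame scaling has a known failure mode: a frame whose
intensity image contains *no* bright content stretches its noise floor
across $[0,1]$ and the 0.35 threshold then fires on noise. Three mitigations
are built in: (a) a `global` normalization mode pools the percentiles over
the whole time-lapse and is the recommended setting for profiles; (b)
synthetic frames are generated directly on the reconstructed scale and are
flagged `normalized = TRUE`, so no stretch is ever applied to them; (c) the
`reconstructed_pair` type tracks its normalization state and the segmenter
refuses un-normalized input rather than guessing.

### Circularity estimator

Digital perimeters are biased: counting boundary edge steps overestimates
$P$ so badly that $4\pi A/P^2$ for a disc lands near 0.8, while naive
corrections push it far above 1. We use a Crofton-style 4-direction
estimator — weighted boundary intercept counts along rows, columns and the
two diagonals,
$P = \tfrac{\pi}{8}\,(c_h + c_v + (c_{d1} + c_{d2})/\sqrt{2})$ — which is
asymptotically exact on discs (radius-50 disc: within 2%). Its documented
bias: flat axis- or diagonal-aligned edges are shortened, so convex
polygons read up to ~12–13% high (a filled square measures ≈ 0.87 against
the analytic $\pi/4 \approx 0.785$), and very small components can exceed
1. The estimator is pluggable (`perimeter = "edge"` gives the naive count
for comparison). Elongation at fixed area strictly decreases the estimate,
which is the property the historical feature actually relied on.

## Profiling and the inhibition rule

`build_profile()` runs the pipeline over a time-lapse (default 20-s
interval, 20-min window, both configuration rather than hard limits) with
no smoothing — the threshold rule is applied to the extracted percentages
directly; an optional smoother exists but defaults off, since any filtering
would shift the reported endpoint. One failing frame is logged and recorded
as missing rather than aborting the run. Pre-enzyme reference frames are
carried in the profile and flagged.

`inhibition_time()` returns the time of the **first** point with
$\mathrm{pct} \ge 92.5$ (the default threshold), skipping missing points.
First-crossing semantics matter because real detachment curves are not
monotone: a transient stationary/re-attachment phase early in harvesting
can dip the curve after a crossing, and the rule deliberately ignores the
dip. If the threshold is never reached within the monitored window, the
final non-missing percentage is reported instead — exactly one of the two
outputs is present. `summarize_conditions()` lays results out donor ×
condition in minutes, with unreached cells labelled by their final
percentage.

## The synthetic generator

Every claim in this package is tested against synthetic scenes with exact
pixel-level ground truth, because no reference image data ship with the
method. The generator emulates what the pipeline needs to be true of the
reconstructed domain — contrast ordering, shapes, co-location, clumping,
kinetics — and nothing more. In particular it does **not** simulate
holographic diffraction, twin-image artifacts or sensor physics, so a green
test suite demonstrates correctness of the *algorithm* under the stated
appearance contract, not instrument-level performance on real cultures.

**Appearance.** Background sits at 0.15 (phase) and 0.08 (intensity) with
additive Gaussian noise (sd 0.025) and a 1-px Gaussian blur. Attached cells
are ellipses with semi-axes 16–24 × 4.5–6.5 px (aspect ratio ≥ 2) at a
plateau of 0.40–0.52 in phase and nothing in intensity. Detached cells are
round (radius 7–10 px, axis ratio ≥ 0.88) with an in-cell plateau of 0.45
plus a bright core reaching 0.98 in phase and a co-located halo core
reaching 0.90 in intensity. The core sizes are calibrated to the imagery
the pipeline was designed for: the 0.65 level set of the phase core sits
about one dilation radius (5 px) inside the cell rim (with a 3.6-px floor
so seeds survive the 30-px filter), which is precisely the geometry that
makes a 5-px seeded dilation recover the full detached footprint. Cells in
their first frame after detachment render as a dimmer "transitioning"
state. The contract that the whole method exploits — mean intensity-image
value inside detached regions exceeds that inside attached regions by a
clear margin — is asserted as a property test.

**Density regimes.** `medium` (0.00085 cells/px, 401×401 validation crops),
`high` (0.0018, 301×301) and `overconfluent` (0.0028, 301×301). Medium and
high place centres with a minimum-distance dart process (16 / 10 px),
emulating a monolayer; overconfluent places cells in clusters (Gaussian
scatter, sd 12 px around cluster centres) so attached cells touch and
overlap and detached cells clump into merged regions — the regime where
region-based extraction has to prove itself. Crop sizes and the 16-image
set size mirror the validation protocol the method was originally assessed
with; the per-image detached fractions are spread over (0.05, 0.95).

**Kinetics.** The trajectory model is the simplest parametric family that
reproduces all four qualitative phases reported for harvesting curves: two
exponential hazard compartments (fast fraction 0.75 at 0.01/s, slow at
0.003/s), a re-attachment window (120–240 s, probability 0.15, re-detaching
under the slow hazard) and a never-detaching residual (plateau 97% of
cells). Note that the plateau is specified in *cell counts* while profiles
measure *pixel areas*; because detached cells occupy a smaller footprint
than spread ones, a 97% cell plateau corresponds to a pixel-area plateau in
the high 80s — a culture that detaches well but does not necessarily cross
the 92.5% endpoint within 20 min, which is one of the two behaviours
reported for real donors (the other, an early crossing, is obtained with a
higher plateau or faster hazards). These defaults are appearance choices
for a plausible donor, not claims about any particular cell biology. The model sits behind `kinetics_params()` so another family can be
substituted. A single-compartment configuration reduces to
$1 - e^{-rt}$ and is checked against that closed form within three
standard errors at $n = 1000$ cells.

## Numerical and design choices

* **Connectivity.** Holes are background components under 4-connectivity
  that do not touch the image border; objects and remainders use
  8-connectivity. Labeling runs over an explicit pixel-adjacency graph, so
  both connectivities share one code path, and every morphological
  primitive is tested for exact equality against an independent brute-force
  oracle (propagation labeling, offset-list dilation) on hundreds of random
  masks.
* **Determinism.** All generators take explicit seeds and restore the
  caller's RNG state; the forest trains and predicts single-threaded with a
  stored seed; repeated CLI runs reproduce CSV outputs byte for byte.
* **Degenerate inputs.** Empty masks, constant images, zero-cell frames and
  all-missing profiles each have defined behaviour (empty output, all-zero
  normalization, missing percentage, explicit error) rather than incidental
  behaviour.
* **Training labels.** The synthetic training set samples 1500 labelled
  pixels per class per frame from the exact truth masks of one frame per
  density regime, emulating sparse brush annotation anchored to visible
  cell boundaries.
* **Problem sizes.** The shipped tests run the full pipeline on 16-image
  validation sets per regime (401²/301²), a 60-frame 192² time-lapse for
  the partition invariant, and 500 randomized 64² masks per morphological
  primitive; these sizes were chosen to exercise every regime of the
  method at desk scale.

## Known limitations

* The generator's appearance model is smooth-blob plus noise; it does not
  produce reconstruction artifacts (twin images, fringe halos around
  *attached* cells) that could fire the 0.35 intensity threshold spuriously
  on real data.
* Per-frame normalization of real frames with featureless intensity images
  inflates the early profile; use `normalize = "global"` for time-lapses.
* The forest hyperparameters of the original interactive workflow are
  unknown; transfer of the shipped defaults to real imagery will require
  retraining on a handful of annotated frames (`detachmon train`).
* Circularity inherits the documented Crofton bias on polygonal shapes; it
  is provided as the comparison baseline, not as the endpoint feature.
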