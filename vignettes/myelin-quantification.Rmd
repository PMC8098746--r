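---
title: "Quantifying myelination in organoid image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myelination in organoid image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myeliquant)
```

## The measurement problem

Human myelinating organoids ("myelinoids") contain neurons, astrocytes and
oligodendrocytes; by twelve weeks after myelin induction their
oligodendrocytes have wrapped axons in compact myelin. Assessing how much
myelin a culture has made — and how that quantity responds to a drug, a
mutation, or suppressed synaptic vesicle release — requires an unbiased
readout from confocal z-stacks of immunostained whole mounts: a myelin
marker (MBP or CNP) and an axonal marker (NF-H), acquired as shallow stacks
(12 planes at 1 µm) on a high-content confocal at 20X.

The difficulty is that the myelin channel also stains oligodendrocyte cell
bodies and picks up debris. The pipeline implemented here segments the
myelin channel plane by plane, rejects everything that is not an elongated,
internally textured, tube-like structure, assembles the survivors into 3D
objects, and reports the segmented myelin volume normalized to axonal
density — so that myelinoids with more axonal substrate are not trivially
scored as more myelinated.

## The segmentation cascade

Per z-plane of the myelin channel, in order:

1. **Adaptive threshold** — foreground where intensity exceeds the local
   mean (window radius 20 µm, exposed) plus an offset. A local rather than
   global threshold tolerates the large illumination and staining gradients
   of whole-mount organoids.
2. **Filter Mask 1** — remove 2D objects with fiber breadth > 16 µm, fiber
   length < 10 µm, or area < 45 µm². The *fiber model* treats an object as a
   rectangle with the observed area A and perimeter P, giving
   L = (P + √(P² − 16A))/4 and B = A/L; it is exact for ideal rectangles,
   which the test suite exploits.
3. **Shrink by 4 px** — morphological erosion with a disc. Thin structures
   vanish; the cores of compact blobs survive.
4. **Filter Mask 2** — on the shrunk objects, remove those with elliptical
   form factor < 3.7 (round), fiber breadth > 8 µm (bulky), or intensity SD
   < 1000 counts (internally uniform — cell bodies stain homogeneously,
   myelin does not). The elliptical form factor is the axis ratio of the
   second-central-moment ellipse, with the 1/12 per-pixel variance term so
   one-pixel-wide objects remain finite.
5. **Keep Marked Objects** — retain, at full extent, the Filter-Mask-1
   objects that overlap any surviving shrunk object. Steps 3–5 jointly ask:
   "does this object contain a compact, elongated, textured core?"
6. **Blob subtraction** — detect round structures 8–100 µm wide, dilate the
   detections by 5 px, and subtract them from the retained mask; repeat for
   4–6 µm blobs. This removes soma and debris pixels that ride along inside
   retained objects.
7. **Connect Touching Objects** — 3D components: 8-connectivity within a
   plane, connection across consecutive planes wherever voxels touch within
   a 26-connected neighbourhood.
8. **3D filter** — remove objects with volume ≤ 450 µm³ **and** diameter
   ≤ 45 µm. The conjunction matters: a long thin sheath has a small volume
   but a large extent, and removing it would defeat the assay. Diameter is
   the exact maximum pairwise distance between member voxel centres
   (computed over per-line extreme voxels, which contain every convex-hull
   vertex, so the maximum is exact).

Axonal density is measured on the NF-H channel with a single global
threshold (Otsu on the integer histogram by default, a fixed count value as
override) and summed integrated intensity over the thresholded volume; the
site's normalized myelin volume is myelin volume divided by NF-H integrated
intensity. Sites are averaged per myelinoid, and myelinoid values divided by
their batch's control-group mean when a batch control is designated.

All removal comparisons are strict exactly as written above: an object at a
"<" or ">" boundary is retained, an object at the 3D "≤" boundary is
removed. Removal within each 2D filter mask is disjunctive (any criterion
fires), modelling sequential filter application; a conjunctive variant is a
configuration switch (`filter_logic = "and"`). Count-valued settings (the
intensity-SD threshold, the adaptive offset) are defined at 16-bit camera
counts and rescaled by (2^bit_depth − 1)/65535 for other depths.
Micrometre-valued settings are converted to pixels from the stack
calibration, rounding half up; the shrink (4 px) and blob enlargement (5 px)
radii are pixel-valued by definition and used as given.

### Blob detection

"Find blobs of width d₁–d₂" is implemented as multi-scale Laplacian of
Gaussian: scale-normalized responses at ten log-spaced scales
σ = d/(2√2), detections as interior local maxima in (x, y, σ) above a
threshold relative to the plane's intensity range (default 0.1). Two
implementation choices matter and are exposed as parameters:

* **Scale-range padding.** The scale list is padded by one step on each
  side, and only interior-scale maxima are reported. Without this, any
  structure whose characteristic width lies outside the requested range
  surfaces as a spurious detection at the range edge.
* **Ridge rejection.** The scale-normalized LoG response along a tube of
  profile width σ_b is ≈ 0.35·A at the matched scale and decays only like
  σ_b/σ — far above any usable threshold. A bare response threshold
  therefore fires continuously along exactly the sheaths the mask is meant
  to keep, and the dilate-and-subtract step would carve them up. Candidate
  detections are therefore screened by the local Hessian of the smoothed
  image: a detection is kept only when its principal-curvature ratio is at
  most `blob_max_axis_ratio` (default 2; the classic trace²/determinant
  bound). Round somata and debris pass untouched; sheath cross-sections and
  end caps are rejected.

For efficiency the plane is processed at a block-mean-reduced resolution
chosen so the smallest scale stays ≥ 2 px, with parabolic sub-pixel
refinement of detection centres; the scale space itself is computed with a
single FFT of the padded plane per pass and analytic Gaussian transfer
functions per scale.

## What the synthetic generator emulates — and what it does not

No imaging data are bundled; every claim the test suite makes is against
the seeded generator in `generate_stack()`, which emulates:

* acquisition geometry: 12 planes at 1 µm z-step, 512 × 512 px in-plane,
  16-bit counts;
* myelin sheaths as capsule-shaped tubes lying nearly in-plane (±2° tilt),
  with per-voxel intensity jitter (SD 1400 counts) so the intensity-SD
  filter criterion is meaningfully exercised;
* distractors: spherical somata 8–20 µm wide with low internal jitter
  (SD 200 — cell bodies stain uniformly) and debris 4–6 µm wide with
  moderate jitter (SD 600);
* an NF-H channel of long thin axons, half of which run along sheath axes
  so axonal density correlates with sheath placement;
* camera noise: additive read noise (SD 50) plus a signal-proportional
  variance term (Gaussian approximation of shot noise), applied after
  ground truth is recorded.

Two geometry defaults deserve comment because they are *derived from the
filter cascade itself* rather than free choices:

* **Tube radius 2.5 µm.** An isolated tube of 1–2 µm breadth — a single
  internode at true scale — is at most 8 px wide at 0.25 µm/px and is
  erased by the 4-px shrink, never reaching Filter Mask 2; and at any
  coarser pixel size it fails even earlier. The cascade's printed
  parameters (shrink 4 px, minimum area 45 µm², 3D volume/diameter floor)
  are evidently sized for the dense myelinated-fiber bundles that dominate
  whole-mount acquisitions, not for isolated single sheaths. The
  generator's "sheaths" are therefore rendered at bundle scale
  (breadth 5 µm).
* **Length prior N(87, 28) truncated to [55, 115] µm.** The mean and SD
  are the reported per-cell sheath-length statistics of mature cultures.
  The truncation keeps rendered objects within what the 3D filter is
  designed to retain: an object shorter than 45 µm with bundle-scale girth
  has volume ≤ 450 µm³ and is removed *by design*, so including such
  objects would merely measure the filter doing its job.

The in-plane pixel size of the 20X acquisition is not derivable from the
assay's printed parameters; the generator defaults to 0.25 µm/px and the
readers require it as explicit configuration for real data.

Features of real data the generator does **not** emulate: the optical PSF
(objects have hard edges), spectral bleed-through, photobleaching, the
curvature and branching contact of real sheath networks, and intensity
heterogeneity across an organoid. Passing the recovery suite therefore
shows that the cascade is implemented correctly and behaves sensibly on
idealized geometry — not that it would reproduce any particular biological
measurement on real stacks.

## Statistics: cluster bootstrap instead of a mixed model

Treatment effects on normalized myelin volume are multiplicative, and the
experimental unit is the myelinoid, nested in differentiation batches. The
package estimates the fold change as the ratio of geometric means of
myelinoid-level values and quantifies uncertainty with a nonparametric
bootstrap that resamples whole myelinoids with replacement, stratified by
batch and group, with percentile intervals (default 2000 replicates). The
bootstrap is fully specified and validated by coverage simulation at the
study design (13 vs 13 myelinoids in 3 batches): measured coverage is
within Monte-Carlo error of the nominal 95%, with the mild undercoverage
expected of percentile intervals at ~13 clusters per group. A generalized
mixed model with a log link is the classical alternative; `glmm_export()`
emits a model-ready table, and the test suite cross-checks the bootstrap
point estimate against a lognormal mixed-model fit. Resampling is
stratified by batch *and* group so every replicate preserves the design; a
percentile interval from a degenerate bootstrap distribution is widened to
include the point estimate, so the interval always brackets it.

Quartiles everywhere (including `tukey_box_summary()`) use linear
interpolation (R type 7); whiskers extend to the most extreme points within
1.5 IQR of the quartiles. The convention is fixed for reproducibility; a
hinge-based alternative would shift quartiles by at most one interpolation
step at these sample sizes.

## Morphometrics conventions

* Sheath lengths are polyline arc lengths from trace tables (the tracing
  itself is interactive and out of scope; SWC input is accepted read-only
  and branched structures are rejected, since sheaths are unbranched).
* Nearest-neighbor oligodendrocyte density is the count of *other*
  myelinating cells within 100 µm, boundary inclusive, reported as a raw
  count per disk rather than a per-area rate.
* Sholl intersections are counted as connected foreground runs along the
  digitized circle at each radius; total outgrowth is skeleton length
  (Zhang–Suen thinning; orthogonal steps count 1, diagonal steps √2).
* The g-ratio regression is ordinary least squares of g on ln(axon
  diameter) (`log10` available), matching the logarithmic trend curve
  convention of g-ratio scatter plots.

## Numerical and degenerate-input choices

* Voxel indices are 0-based with physical coordinates at voxel centres;
  areas scale exactly as s² and volumes as s²·z under calibration rescaling
  (property-tested).
* A constant plane thresholds to an empty mask; an empty mask measures to
  an empty object list; a zero NF-H channel makes the normalized volume
  `NA` with a warning rather than an error.
* Simulator placement is by rejection sampling with a minimum clearance of
  2 µm between myelin-channel objects; objects that cannot be placed within
  500 attempts are dropped, logged, and reported in the ground truth. A
  512 × 512 field at 0.25 µm/px accommodates roughly 6–9 of 12 requested
  ~90 µm bundles; ground truth always reflects what was actually rendered.
* Ground-truth class labels are mutually exclusive with priority
  sheath > soma > debris > axon; recorded per-class volumes equal voxel
  counts times voxel volume exactly.
* Erosion/dilation use EBImage disc brushes; the 20×20-square-erodes-to-
  12×12 identity pins the disc convention in the tests.

## Problem sizes used by the validation suite

The bundled checks run, per invocation: 20 seeded 12×512×512 stacks for
segmentation recovery (object-level precision/recall, volume error,
distractor leakage); 200 simulated two-group experiments with 2000-replicate
bootstraps for CI coverage; 100 noisy g-ratio tables of 124 axons for
coefficient recovery; and 100 random point sets against an O(n²)
nearest-neighbor oracle. These sizes give Monte-Carlo error comfortably
below the tolerances they are checked against while keeping a full run in
the minutes range on a single core.

## Known limitations

* The cascade quantifies myelinated-bundle volume, not internode-resolved
  myelin: single thin sheaths below the printed size floors are invisible
  to it by construction.
* MetaXpress operator semantics (the origin of the cascade's vocabulary)
  are proprietary; the fiber model, form factor, perimeter and blob
  definitions used here are the standard open definitions and are validated
  against closed forms, but they are not guaranteed to be bit-compatible
  with any vendor implementation.
* Otsu's method assumes a bimodal NF-H histogram; for sparse axonal fields
  a manual threshold override is advisable.
* The bootstrap treats batches as strata, not as a sampled random effect;
  with very few batches the between-batch component is under-propagated —
  the same regime where a mixed model would also struggle to estimate it.
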