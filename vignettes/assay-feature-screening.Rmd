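---
title: "Screening a cellular feature library for image-based assay quality"
author: "assayScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a cellular feature library for image-based assay quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayScreen)
```

## The screening approach to assay development

Image-based high-content assays are usually scored by a single numerical
readout per well. The *design* approach picks that readout up front from
intuition about the phenotype; the *screening* approach instead measures a
large library of per-cell features — intensities, sizes, shapes, channel
correlations, radial intensity distributions, textures, in every cellular
compartment — and tests each one for how well it separates positive from
negative control wells, with precautions against overfitting. assayScreen
implements that screening workflow for two-channel fluorescence images
(a DNA stain plus a green marker): it covers the two classic phenotypes, a
cytoplasm-to-nucleus translocation (CNT) readout and a speckle-formation
(Transfluor-type) readout in which marker aggregation produces small
bright spots.

The pipeline is: illumination correction, nucleus segmentation, derived
compartments (whole cell, cytoplasm, dilated nucleus and ring at several
dilation distances in parallel), the per-cell feature library, derived
ratio and classified-fraction features, per-image aggregation, and
screening of every feature with assay-quality statistics.

## Assay-quality statistics

For a feature $x$ measured per image, with positive and negative control
groups,

$$Z' = 1 - \frac{3(\sigma_{\mathrm{pos}} + \sigma_{\mathrm{neg}})}
                {|\mu_{\mathrm{pos}} - \mu_{\mathrm{neg}}|}$$

with sample standard deviations. $Z' = 1$ is perfect separation; a score
above 0.5 is conventionally an excellent assay, above 0 potentially
screenable. The V factor generalizes this to a full dose-response series:

$$V = 1 - \frac{6\,\overline{\sigma_d}}{|\mu_{\mathrm{high}} - \mu_{\mathrm{low}}|}$$

where $\overline{\sigma_d}$ is the mean within-dose sample SD and the
denominator is the response range between the extreme dose groups. With
exactly two dose groups, $6 \cdot \mathrm{mean}$ of two SDs equals
$3 \cdot$ their sum, so V reduces *algebraically* to $Z'$ — a property the
test suite asserts to $10^{-12}$. A variant that replaces the per-dose SDs
with the residual SD around a fitted four-parameter logistic curve is
available (`vFactor(..., method = "fit_residual")`); the per-dose form is
the default because it involves no curve-fit convergence edge cases. Both
statistics are invariant under affine transforms of the feature and
undefined (reported as missing, never $-\infty$) when the group means
coincide; invalid features always rank last.

Because picking the best of hundreds of features on a handful of control
wells invites selection bias, `splitValidate()` splits the control wells
into training and held-out halves (seeded, stratified by control class),
ranks features on the training half only, and re-scores the winners on the
held-out half. On pure-noise features the held-out score regresses toward
zero — the suite checks this over 100 seeded splits.

## The measurement library

Per compartment and channel the library measures: 12 intensity statistics
(integrated/mean/median/SD/max/min/MAD plus five statistics on the
object's internal boundary pixels); 7 shape statistics (area, perimeter,
form factor, eccentricity, solidity, extent, equivalent diameter); 13
Haralick texture statistics at each of the offsets {1, 3, 5} px; a
4-bin radial intensity distribution (intensity fraction, density-
normalized fraction, and angular coefficient of variation per bin); and 3
cross-channel correlation statistics. With the default compartments —
nucleus, propagated cell, cytoplasm, and a dilated-nucleus + ring pair for
each dilation distance in {5, 10, 15} px — this yields well over 500
distinct per-cell features, matching the scale at which feature screening
is practised. Dilation distances, texture offsets and classification
thresholds are *screened in parallel*: each value gets its own
compartment/feature-name suffix in one run, and the screening stage
simply ranks them all.

Numerical choices that matter:

* **Perimeter** uses the Benkrid chain-code weighting of boundary pixels
  (straight runs 1, diagonal steps $\sqrt 2$, corners $(1+\sqrt 2)/2$). A
  raw boundary-pixel count would give a digital disk a form factor of
  about 1.27; the weighted estimate gives 0.92, close to the ideal 1.
* **Texture** quantizes each object over its *own* min–max range into 8
  levels before building the co-occurrence matrix (pooled symmetrically
  over the four direction offsets, pairs restricted to the object). Per-
  object quantization makes texture robust to residual illumination
  differences at the cost of comparability of absolute gray levels —
  acceptable because screening compares distributions of the statistic
  across wells, not gray levels. Natural logarithms throughout; objects
  with zero intensity range or fewer than 4 pixel pairs are missing.
* **Radial distribution** normalizes each pixel's centroid distance by the
  maximal object radius in its angular sector, so elongated cells bin
  sensibly. The per-bin angular CV uses per-wedge *mean* intensities
  (wedges with no pixels excluded): on a digital grid the wedge pixel
  counts are necessarily unequal, so wedge sums would report spurious
  angular variation for perfectly uniform objects, while wedge means are
  exactly zero-CV there.
* **Solidity** uses the rasterized convex hull of pixel centers
  (regionprops convention), so convex digital shapes score 1.
* **Std** uses one delta degree of freedom everywhere; a single-pixel
  object has Std 0 by definition. Division by a zero denominator in
  derived ratios yields a missing value, never infinity; classification
  uses strict ">" so ties at the threshold fall below.

## Segmentation and compartments

Nuclei come from the DNA channel: Gaussian pre-smoothing, a global Otsu
threshold (optionally on log intensities), hole filling, area and border
filtering, and optional declumping by marker-controlled watershed on the
negated Euclidean distance transform, with markers at distance-transform
maxima thinned to a minimum separation of $\sqrt{\mathrm{minArea}}/2$
(deterministic raster-order tie-breaks). Objects are 4-connected by
default (8-connectivity is a configuration option). Border-touching nuclei
are removed because their compartments would be truncated and bias
intensity features.

Whole cells are grown from nuclear seeds by geodesic propagation across
the green-marker foreground: a step of length $L$ between neighbouring
pixels costs $\sqrt{\lambda L^2 + \Delta I^2}$, so boundaries follow
intensity ridges when the regularization $\lambda$ is small and approach
nearest-seed (Voronoi-like) assignment as $\lambda$ grows. The
implementation is an exact multi-source Dijkstra search with
deterministic lower-label tie-breaks; the test suite checks it against an
independent whole-grid relaxation solver on grids up to 64×64, and checks
the exact Euclidean nearest-object dilation against per-pixel exhaustive
search. The default $\lambda = 0.05$ favours the intensity term at the
step scale of typical cell-edge gradients; the exact value used by
published pipelines is not documented anywhere we know of, and results are
insensitive to it on the synthetic conditions below because cells there
are touching-free.

Speckles are enhanced with a white top-hat (image minus its opening with a
disk of radius 4 px) and thresholded *per parent cell* with Otsu's method,
which absorbs per-cell background differences; parents with fewer than 64
pixels or zero intensity range fall back to the global threshold.
Components outside the [6, 400] px² area gate are rejected. The lower gate
is set by geometry, not tuning: opening a hard-edged digital disk with a
digital disk element leaves boundary residual fragments of at most ~5
pixels (we enumerated radii 13.5–17.5 px against the radius-4 element),
while a credible diffraction-limited spot (Gaussian $\sigma \approx 1.5$
px) thresholds to a core of 15+ pixels, so 6 separates artifact from
signal with margin on both sides.

Per-object thresholds are additionally bounded below
(`speckles$min_threshold`, default 0.1): an unbounded Otsu threshold
always "finds" a split, so in a cell containing no true speckles it would
segment its own noise into spurious spots. The floor encodes the smallest
enhancement a real speckle produces — the default is roughly a quarter of
the synthetic spot amplitude (0.45) and about seven times the 99.9th
percentile of the default read noise (SD 0.01), so it suppresses
noise-splitting without touching genuine spots; set it to 0 to disable.
The whole-cell propagation threshold shares the known weakness of
seed-propagation methods on strongly transformed positive controls: when
the marker histogram is dominated by bright aggregates, a global Otsu can
land above the diffuse cell body, truncating cytoplasm (and any speckles
in it). The dilated-nucleus compartments, which do not depend on the
marker channel, are screened in parallel precisely so a readout survives
that failure mode.

## Illumination correction

All images of a channel are averaged and the average is smoothed with a
large square median filter (default window 151 px — much larger than any
cell, so only smooth shading survives; odd, so the window has a center
pixel). The surface
is clipped below at $10^{-6}$ and normalized to mean 1, so division leaves
corrected intensities on the original scale on average; min-1 scaling was
rejected because it would systematically brighten every image. Averaging
rather than summing differs only by a constant that the normalization
removes, and keeps the accumulator bounded. The median filter's border
bias is accepted; accuracy claims (2% recovery of a known synthetic
gradient) are therefore made on the central 80% region.

## What the synthetic generator emulates — and what it does not

`generateTranslocationSet()` and `generateSpeckleSet()` render two-channel
16-bit TIFF image sets with a plate-map CSV and per-cell ground truth.
Cells are non-overlapping disks (radius 14–17 px) with elliptical nuclei
(semi-axes 6–9 px), about 30 per 360×360 image; a dose grid maps to a
phenotype effect through a logistic curve (EC50 1, Hill 2, maximal effect
0.9), negative controls at dose 0 and positives at the top dose. In the
CNT model the green marker moves from cytoplasm (level 0.4, baseline 0.05)
into the nucleus (level 0.1 rising to 0.5) as the effect grows; in the
speckle model a diffuse level of 0.25 gains $K \sim
\mathrm{Poisson}(\lambda(e))$ Gaussian spots per cell ($\sigma$ 1.5 px,
amplitude 0.45, $\lambda$ from 0.3 to 8). A low-order polynomial
multiplicative illumination gradient (amplitude 0.3) and Gaussian read
noise (SD 0.01) emulate shading and sensor noise; intensities chosen to
sit well inside the 16-bit range. Everything is deterministic given the
seed, down to file bytes.

The generator is deliberately simple: no cell-to-cell intensity
heterogeneity, no overlapping or border-clipped cells beyond what
placement produces, no photobleaching, no cell-cycle or confluency
effects, hard-edged objects rather than PSF-blurred ones. Passing tests on
these conditions therefore demonstrate that the *measurement and screening
machinery* is correct and that designed features are recovered when the
data contain them — not that the pipeline segments difficult real images
well. The noise-free configurations are constructed so recovery is exact:
rendered compartment intensities are constant up to 16-bit quantization,
so the measured nucleus:cytoplasm ratio equals the recorded truth to
machine precision, and planted spot counts are recovered exactly.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full screens at the
study conditions (2-dose sets with 8 images per group and ~30 cells per
image for the end-to-end checks; 20-image 5-dose series for the
dose-response screens), and the statistic Monte-Carlo checks at n = 200
per group over 500 replicates; these sizes give each check comfortable
statistical margin while keeping a complete run in minutes on one CPU.
Every stage is a pure function of (inputs, configuration, seed):
re-running the pipeline byte-reproduces feature tables, and the train/test
split is reproducible from its seed.

## Known limitations

* Only two-channel (DNA + marker) experiments; no multi-site stitching,
  no OME metadata, TIFF/PNG input only.
* Per-object texture quantization means texture values are not comparable
  against CellProfiler's globally-quantized Haralick output, though their
  screening behaviour is equivalent.
* The propagation regularization and speckle size gates are configuration
  defaults chosen for the synthetic conditions; real assays should screen
  several values in parallel, which the configuration supports.
* The V factor's dose-response-fit variant uses a four-parameter logistic
  and falls back to per-dose SDs when the fit fails to converge.
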