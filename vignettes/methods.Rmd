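---
title: "Methods: image quantification for neuromuscular cocultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quantification for neuromuscular cocultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the quantification procedures implemented in
`nmjquant`, the conventions and numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the package's known
limitations.

## Geometry and intensity conventions

Images are plain matrices indexed `[row, col]`, 1-based, origin top-left —
the native convention of R matrices. All physical quantities derive from a
caller-supplied pixel size in µm per pixel edge: a k-pixel run is
`k * pixel_size_um` µm and a pixel covers `pixel_size_um^2` µm². Pixel
calibration is deliberately an explicit argument everywhere, because
file-metadata calibration is unreliable in practice and the pipeline's
pixel-denominated parameters (filter sizes in px, class boundaries in µm²)
must never be silently rescaled. Reading never normalizes intensities;
filtering converts to floating point internally.

Connectivity is 4-connected everywhere, consistent with the 3 × 3 diamond
structuring element's topology. Object moments are computed over
pixel-center coordinates with *no* per-pixel variance correction (no
+1/12 term): the major axis length is `4 * sqrt(lambda_max)` of the
coordinate covariance and eccentricity is `sqrt(1 - lambda_min /
lambda_max)`. Under this convention a single-pixel object has axis 0 and
eccentricity 0; the test suite's independent moment oracle uses the same
convention so the two can disagree only through implementation error,
which is checked at 1e-9 relative tolerance.

## Nucleus detection and segmentation

Nucleus centers come from a scale-normalized Laplacian-of-Gaussian blob
detector: responses `-sigma^2 * Laplacian(G_sigma * image)` over a small
scale range (default 3–6 px, 5 scales), 3 × 3 × 3 local maxima above a
caller threshold, then greedy non-maximum suppression so that no two
retained blobs (radius `sqrt(2) * sigma`) overlap by more than half the
smaller blob's area. The detector is deterministic and
parameter-transparent; it assumes roughly isotropic, well-separated
nuclei, which holds for DAPI staining at moderate confluence. For a
Gaussian blob of amplitude A the matched-scale response is about A/2,
which is how detection thresholds should be chosen.

Per-nucleus masks come from intensity-guided propagation
(`EBImage::propagate`) of the detected seeds over the smoothed-image
foreground (Otsu's threshold by default, always overridable — thresholds
in this pipeline are user-defined by design). Each seed yields exactly one
label containing its seed pixel. No declumping beyond the seeded
partition is attempted.

## Marker positivity

Both classification rules share strict-inequality semantics: a score
exactly at the threshold is negative. The point rule smooths the marker
channel with a σ = 0.5 px Gaussian and takes the maximum over the
3 × 3 px window at the nucleus center; windows at image borders are
clipped, not discarded, since discarding would bias fields with dense
edges. The nuclear-mean rule averages the marker channel over the
segmented nuclear area. With `window_px = 1` and smoothing disabled the
point rule degenerates to center-pixel thresholding (tested). Raising the
threshold can only shrink the positive set (tested as a monotonicity
property).

Thresholds have no defaults on purpose: they are the chief
reproducibility gap of this kind of analysis, so the package forces an
explicit value (or an explicit request for Otsu) and the pipeline driver
logs every threshold with its provenance.

## The elongation index

The statistic proceeds: smooth with σ = 8 px → threshold (strict `>`) →
remove narrow structures by 8 binary erosions then 8 binary dilations
with the 3 × 3 diamond → XOR the opened mask with the raw mask → delete
residual objects with area < 960 px², eccentricity < 0.75 or major axis
< 120 px → sum the survivors' major axes and divide by the number of
marker-positive cells. Defaults are fixed at these values; the
segmentation threshold is user-defined.

Numerical choices:

- **Border handling.** Outside-image pixels are background for both
  erosion and dilation. This keeps opening exactly anti-extensive
  (`open(X) ⊆ X`), so the XOR equals the set difference `X \ open(X)`;
  the implementation computes the cheaper set difference after asserting
  the inclusion. The cost is that wide objects touching the border shed a
  boundary residual; synthetic fixtures keep objects ≥ 20 px from
  borders, and real fields should be interpreted with the same caveat.
- **Strict filter boundaries.** "Smaller than" is implemented strictly:
  objects exactly at 960 px² / 0.75 / 120 px survive. The boundary pair
  (an 8 × 120 px rectangle of exactly 960 px² kept, the same rectangle
  minus one pixel deleted) is asserted in the tests.
- **Denominator.** The positive-cell count is an input, not recomputed
  internally, keeping the residual analysis and the classification
  independently testable; a zero denominator is an explicit error, never
  a silent NaN. The per-field index is linear in 1/N (tested).
- **Aggregation.** Indices are computed per image; condition summaries
  (mean ± SD across fields) are a separate, explicit step
  (`summarize_results`), so per-image and pooled views are both
  available rather than silently conflated.

Morphology itself is implemented as vectorized zero-fill shifts (one
erosion is the conjunction of the mask with its four edge-neighbor
shifts), because the required outside-is-background convention must hold
exactly; an exhaustive per-pixel neighborhood-sweep oracle in the test
suite confirms bit-exactness on random grids, and the identity
`k iterations of the 3 × 3 diamond = one L1 ball of radius k` is asserted
analytically.

## AChR clusters and myotubes

Cluster segmentation is thresholding plus 4-connected labeling, with a
minimum-area filter (default 4 px²) standing in for manual artifact
deselection — the only automatable reading of that step; an exclusion
list of images remains the caller's responsibility. Counts are normalized
to the myotube area obtained by percentile-based contrast stretching,
thresholding and labeling; the density is `n_clusters /
myotube_area_mm2` exactly. Co-staining rules (`mean_gt`, `overlap_frac`)
must be selected explicitly because no published rule exists to default
to; the overlap rule at 0.25 is offered as the automated analogue of
manual colocalization counting and is documented as non-equivalent to it.

Myotubes straddle the 200,000 µm² class boundary strictly: exactly
200,000 µm² is "small". In automated mode connected components are
treated as individual myotubes (no declumping), which the records note;
manual outlines can be imported as polygons and rasterized by even-odd
ray casting. Class coverages are sums of per-myotube percent coverage of
the analyzed image's own area (recorded with the records), and conserve
the total exactly. Density-curve data are emitted raw with log10
transforms; the KDE bandwidth is an explicit parameter and degenerate
(all-equal) inputs are flagged instead of smoothed.

Hypothesis testing across conditions (ANOVA, paired tests, mixed models)
is deliberately out of scope: tables are exported in long format
(condition, replicate, metric, value, units) for standard statistical
routines.

## The synthetic-data generator

The generator emulates the phenotypes the pipeline measures, with exact
ground truth and a single seeded RNG stream per call (identical specs ⇒
bit-identical images):

- **Nuclear fields**: Gaussian blobs (σ = radius/2, default radius 8 px)
  at centers ≥ 2 radii apart by bounded rejection sampling; exactly
  `round(positive_fraction * n)` nuclei carry marker signal. Defaults:
  512 × 512 px, 200 nuclei, positive fraction 0.6, SNR 10 — a
  well-stained, moderately confluent field.
- **Cell bodies**: spindle cells as capsules (default 150 × 8 px; the
  width is kept below the 17 px that a radius-8 diamond opening removes)
  at random orientations, versus round cells as discs of equal area
  (radius ≈ 20 px, containing no narrow structures). Bodies are placed
  without overlap (≥ 8 px gaps) and ≥ 20 px from borders, 8 per field.
- **Coculture fields**: the myotube mask is a smoothed Gaussian random
  field thresholded at the quantile matching the requested coverage
  (default 0.4), giving a few large smooth blobs; 25 cluster discs
  (radius 6 px) are planted fully on the mask, non-overlapping, each with
  its own uniform intensity; a seeded 60% subset repeats in the rapsyn
  channel.

Noise is additive Gaussian with σ = peak/SNR plus a constant background
offset of 4σ, clipped at zero; the offset makes clipping negligible so
blank-region noise keeps its nominal σ (a tested contract). Poisson
(shot) noise, point-spread-function optics beyond Gaussian blobs,
photobleaching, uneven illumination and the z-dimension are deliberately
not modeled. Passing tests therefore demonstrate correctness of the
*computation* on images whose ground truth is known exactly — they do not
demonstrate robustness to the full variability of real micrographs, and
threshold choices on real data remain the user's scientific decision.
Analysis thresholds used on synthetic fields follow the signal model
(e.g. background + 0.3 × peak for capsule segmentation under σ = 8
smoothing, which keeps the segmented body narrower than 17 px so the
opening removes it entirely).

## Problem sizes

The shipped tests and analyses run on 512 × 512 px fields (200 nuclei, 8
cell bodies, 25 clusters), 20 fields per morphology for the
spindle-vs-round contrast, 100 random 64 × 64 grids for the morphology
oracle, and 3–5 replicate fields per analysis script — sizes chosen so
the whole suite completes in about a minute on one core while every
statistic is still exercised at realistic density.

## Known limitations

- Learned detection (the kind of network-based nucleus detector used in
  high-content pipelines) is intentionally replaced by the deterministic
  LoG detector; touching nuclei beyond the seeded partition are not
  declumped.
- Border-touching wide objects contribute spurious elongation residuals
  (see border handling above).
- No intensity normalization across images: comparisons assume fixed
  acquisition settings within an experiment.
- 2D single planes only; no proprietary microscope formats (export to
  TIFF/PNG first).
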