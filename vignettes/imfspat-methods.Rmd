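---
title: "Methods: extracting and spatially characterising intramuscular fat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and spatially characterising intramuscular fat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imfspat)
```

## The problem

Quantitative Dixon MRI yields a per-voxel fat fraction (FF), the fat signal
divided by the total fat + water signal. In healthy muscle most voxels are
predominantly muscle tissue with low FF, but intramuscular fat (IMF)
accumulates in spatially structured clusters — often elongated, branch-like
formations running through the muscle volume. Summarising a muscle by its
mean FF throws that structure away. `imfspat` extracts the IMF clusters
explicitly and characterises *where* they sit (along-muscle profiles) and
*how they are arranged* (3D point-pattern statistics), so that, e.g., an
age contrast in clustering density can be tested even when mean FF differs
little.

## Cluster extraction by median-thresholded region growing

Extraction runs per axial slice within one muscle segmentation:

1. **ROI erosion.** The slice segmentation is eroded `erosion_pixels`
   times (default 2) with a 4-connected cross element, excluding boundary
   voxels and blood vessels. A slice emptied by erosion is skipped and
   recorded, never zero-filled.
2. **Slice median.** `FF_median` is the median FF over the eroded ROI.
   Because muscle tissue dominates healthy muscle, this is a robust local
   estimate of the pure-muscle signal, and it adapts slice by slice along
   the muscle.
3. **Region growing.** The seed is the ROI pixel whose FF is closest to
   `FF_median` (ties: smallest row, then column — the result is
   seed-invariant anyway, which the test suite checks by regrowing from
   random alternative seeds). The region repeatedly admits any ROI pixel
   within Euclidean distance `r` pixels (default 20) of a region pixel
   whose deviation satisfies `|FF − FF_median| ≤ FF_median`, i.e.
   `FF ≤ 2·FF_median`. The deliberately long radius lets growth jump
   across fat bands so muscle pockets *enclosed* by fat are still
   classified as muscle; growth iterates to a fixed point (a
   `single_pass` switch restricts it to one disk sweep for comparison).
4. **Complement.** IMF pixels are the eroded ROI minus the grown muscle
   region.
5. **3D filter.** Stacked IMF pixels are labelled in 3D
   (`connectivity_3d`, default 26) and components below
   `min_cluster_voxels` (default 4) are removed as imaging noise.

Parameter defaults (2, 20, 4, 26) are the protocol values; all are exposed
in `growth_params()`, including `threshold_scale`, the knob used by the
threshold sensitivity analysis (scaling `FF_median` by ±5% leaves the
extracted geometry essentially unchanged on phantoms, because genuine
cluster FF sits far above `2·FF_median`).

Interpretation choices that were genuinely open:

* The growth inequality is read as `ΔFF(x,y) = |FF − FF_median| ≤
  FF_median`; this is the only reading under which the criterion separates
  low-FF muscle from high-FF fat.
* The neighbourhood is a Euclidean disk in **pixel** units (the radius is
  specified in pixels, not mm).
* Growth is strictly 2D per slice; three-dimensionality enters only at the
  cluster filter, whose connectivity is configurable because "connected
  voxels" admits 6/18/26 readings — 26 (the most permissive) is the
  default and the choice is covered by a sensitivity test.
* The erosion border convention treats pixels outside the image as
  background, so ROIs touching the image edge erode there too.

## Along-muscle 2D profiles

For every analyzed slice: `mean_ff` (mean FF over the full eroded ROI, not
just IMF pixels) and `ff_pixel_percentage` (100 × IMF pixels / ROI
pixels). Slice indices map linearly to percent muscle length, 0% distal to
100% proximal; the orientation is an explicit input flag because NIfTI
header orientation codes are unreliable across exporters.

Profile contours use a Gaussian product-kernel density over
(percent length, metric) with per-axis Scott's-rule bandwidths
`h = sd·n^(−1/5)`. The KDE is computed directly rather than through
`MASS::kde2d` because the latter rescales its bandwidth argument (h/4),
and the Scott bandwidth is pinned exactly here. The grid spans the data
range padded by four bandwidths so the density integrates to 1 on its own
grid (checked to 1e−3). The reported peak is taken from the density
*ridge* (the modal metric value per length column): near a smooth maximum
the ridge is flat, so the peak location is the median of the near-maximal
plateau, restricted to the observed 0–100% range — considerably stabler
than the first grid cell attaining the maximum.

## 3D spatial statistics

IMF voxels become points at voxel centres, `(index − 0.5) × spacing`
(0-based), a convention chosen for symmetry under mask reflection.
Anisotropic spacing (the defaults mimic ~1.1 mm in-plane, 2 mm slices) is
carried into all mm geometry.

**Delaunay tessellation.** No installed R package provides 3D Delaunay
triangulation, so the package implements incremental Bowyer–Watson in C++.
Voxel-grid clouds are cospherical almost everywhere — maximally degenerate
input — so a deterministic, seed-fixed uniform jitter (≤ 1e−6 distance
units) resolves the topology, while edge lengths and volumes are always
measured on the *original* coordinates. Consequences worth knowing: metric
summaries are exactly scale-equivariant, the summed tetrahedron volume
equals the convex-hull volume to jitter precision, and for degenerate
inputs the *count* of tetrahedra (hence the mean volume) depends on the
tie-break, as it does in any Delaunay code. Summaries are the mean
unique-edge length (each edge counted once however many tetrahedra share
it; per-tetrahedron counting would overweight interior edges) and the mean
tetrahedron volume, plus variants normalised by `muscle_volume^(1/3)` and
`muscle_volume` respectively for dimensional consistency. The
implementation was validated against an independent triangulation oracle
(identical simplex count, unique-edge set, means) and is re-checked in the
tests by brute-force re-enumeration of its own simplex output.

**Ripley's K.** `K(r) = (V/n²) Σ_{i≠j} 1[d_ij ≤ r]` with V the domain
volume — the muscle bounding box by default, the mask volume as an option.
No edge correction is applied by default, for fidelity with the reference
protocol; uncorrected K is biased downward at radii comparable to the
domain size, which is why envelope comparisons (data vs. CSR simulated *in
the same domain with the same estimator*) are the supported inference
route, and why the closed form `(4/3)πr³` is only matched closely at small
radii. Radii default to voxel ("a.u.") units via the point-cloud `units`
switch; Delaunay metrics are always mm.

**L function.** The default transform is `L = sqrt(K/π)`, centred by the
same transform of the CSR expectation so CSR plots at zero; the standard
3D variance-stabilised form `(3K/4π)^(1/3) − r` is available as
`mode = "standard3d"`.

**Maximum clustering distance** is the largest r at which the upper
envelope bound stays above the CSR line, linearly interpolated at the
down-crossing, 0 when never above, and flagged when censored at the grid
end. The envelope is Monte-Carlo over CSR simulations for a single
subject (199 by default; at least 39 for a meaningful 95% band) and over
participants for group curves (`participant_envelope()`).

## Group inference

Per muscle, Shapiro–Wilk per group and median-centred Levene
(Brown–Forsythe — the robust default; the protocol names only "Levene")
gate the branch: parametric iff all p > 0.05. Parametric: two-way
age × sex ANOVA with Type-II sums of squares (`car::Anova`; Type II is the
standard choice for unbalanced designs without a detected interaction,
and equals the classical decomposition on balanced data, which the tests
exploit as an oracle) followed by Tukey HSD over the four age × sex cells.
Nonparametric: Friedman across the muscles within participants, then
Kruskal–Wallis across groups and Dunn's post hoc with Bonferroni ×6 —
the Friedman-then-Kruskal ordering is preserved from the protocol even
though it is unusual (Friedman addresses repeated measures, Kruskal–Wallis
independent groups); no intent is guessed beyond running both. Dunn's test
is implemented in-package (rank z statistics with tie correction) since no
installed package provides it. Hedges' g
(`J·(m_a−m_b)/s_pooled`, `J = 1 − 3/(4n−9)`) accompanies every
comparison, as effect sizes remain interpretable at small n. α = 0.05
throughout.

## The phantom generator

`generate_phantom()` builds an elliptical muscle cylinder (default grid
48 × 48 × 40 voxels at 1.1 × 1.1 × 2 mm — sizes chosen to keep a full
pipeline run around a second while leaving room for tens of distinct
clusters) containing:

* truncated-normal background FF (0.03 ± 0.01, truncated to
  [0, 1.8 × mean]) — the truncation guarantees background never reaches
  `2 × FF_median`, so threshold separability holds *by construction*;
* branch-like clusters: persistent random walks along the slice axis
  (correlated in-plane steps, default 1 mm/slice noise) stamped as
  radius-1 disks, FF drawn from 0.25–0.60. A vascular atlas is deliberately
  not modelled — only the geometry class matters for validating the
  pipeline;
* optional diffuse spherical clusters (the multifocal, soleus-like mode);
* noise singletons: isolated high-FF voxels placed ≥ 2 voxels from any
  cluster, which the 4-voxel filter must remove — their separation makes
  filter behaviour unambiguous.

Branches are confined to the ellipse eroded by a 4-pixel margin so the
ground truth survives ROI erosion; fragments below 4 voxels (possible when
a fast walk disconnects a tube) are dropped from the truth so it is exactly
the filter-recoverable object. Presets: `young` (4 branches), `old` (12 —
denser clustering at the same muscle volume), `sol_diffuse` (2 branches +
5 blobs). A `proximal_gradient` option anchors branches at the proximal
end, producing the distal-to-proximal increase used to validate profile
peaks.

What the phantom does *not* emulate: MR noise and bias fields, partial
volume at cluster boundaries, water–fat swaps, and any anatomically
realistic vascular branching. Passing recovery tests therefore shows the
pipeline implements its specification faithfully on separable geometry;
it does not certify performance on clinical data with high diffuse FF,
where the median threshold itself shifts.

## Problem sizes and determinism

The validation suite runs phantoms at the default grid, Ripley calibration
with 100 uniform clouds of n = 200 against a 199-simulation envelope, and
a simulated 10 + 10 ageing cohort; these sizes give stable statistics
(binomial envelope coverage within 90–99/100, Hedges' g far above 0.8)
in about two minutes total. Every stochastic step (phantom, jitter, CSR
simulation) takes an explicit seed and restores the caller's RNG state, so
cohort runs are byte-reproducible.

## Known limitations

* Uncorrected K near domain boundaries (documented above); a translation
  correction would be the natural extension.
* Region growing is 2D per slice by design; clusters thinner than a slice
  are connected only through the 3D filter.
* FF-weighted (mark-weighted) clustering and IMCL/EMCL separation are out
  of scope.
* Mean tetrahedron volume on exactly degenerate grids depends on the
  tessellation tie-break; mean edge length and total volume do not.
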