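# imfspat

Spatial analysis of intramuscular fat (IMF) from quantitative MRI
fat-fraction maps.

Healthy skeletal muscle carries fat not as a uniform tint but as spatially
structured clusters — elongated, branch-like formations running through the
muscle volume. `imfspat` extracts those clusters from Dixon fat-fraction
(FF) volumes and quantifies both *where* they sit along the muscle and
*how tightly* they cluster in 3D, so that group contrasts (e.g. ageing)
can be tested on spatial organisation rather than on mean FF alone.

The pipeline, per muscle:

1. **Extraction** — for each axial slice, the segmentation is eroded by 2
   pixels, the slice-median fat fraction FF<sub>median</sub> estimates the
   local muscle signal, and a region is grown from the closest-to-median
   seed by admitting any pixel within radius *r* = 20 px whose deviation
   satisfies |FF − FF<sub>median</sub>| ≤ FF<sub>median</sub>
   (i.e. FF ≤ 2·FF<sub>median</sub>). The IMF mask is the ROI complement
   of that region; 3D components under 4 voxels are discarded as noise.
2. **Along-muscle profiles** — mean FF over the ROI and the FF pixel
   percentage per slice, mapped to percent muscle length (0% distal,
   100% proximal), with Scott's-rule (h = σ̂·n<sup>−1/5</sup>) kernel
   density contours and Pearson correlation between the two profiles.
3. **3D point-pattern statistics** — IMF voxel centres are tessellated
   (Delaunay; mean unique-edge length and mean tetrahedron volume,
   normalised to muscle volume) and tested against complete spatial
   randomness with Ripley's
   K(r) = (V/n²)·Σ<sub>i≠j</sub> 1[d<sub>ij</sub> ≤ r], the centred
   L(r) = √(K/π) transform, Monte-Carlo CSR envelopes, and the maximum
   clustering distance (largest r with the envelope's upper bound above
   the CSR line).
4. **Group inference** — Shapiro–Wilk + Levene gate a parametric branch
   (two-way age×sex ANOVA, Type II, Tukey HSD) or a nonparametric branch
   (Friedman, Kruskal–Wallis, Dunn–Bonferroni), with Hedges' g throughout.

A ground-truthed **phantom generator** (elliptical muscle, random-walk
branch clusters, diffuse blobs, noise singletons; `young`/`old`/
`sol_diffuse` presets) makes the whole pipeline testable without MRI data.

## Worked example

```r
library(imfspat)

ph  <- generate_phantom(phantom_preset("young", seed = 42))
res <- extract_imf(ph$ff, ph$mask)            # growth_params() defaults
res
#> <imf_result> 524 IMF voxels across 40 slices; 8 small clusters removed

cl <- mask_to_point_cloud(res$imf_mask, ph$mask)
delaunay_summary(cl)
#> <tessellation_summary> 524 points, 2864 tetrahedra
#>   mean edge 5.9478, mean volume 8.8264

clv <- mask_to_point_cloud(res$imf_mask, ph$mask, units = "voxel")
rip <- ripley_analysis(clv, seq(0.5, 30, 0.5), n_sims = 99, seed = 1)
rip
#> <ripley_result> 524 points, 60 radii; max clustering distance 20.773

prof <- slice_metrics(ph$ff, res)
profile_correlation(prof$mean_ff, prof$ff_pixel_percentage)
#> [1] 0.9789289
```

Reading: the extractor recovered the planted clusters (the 8 removed
components are exactly the planted noise singletons); their Delaunay mean
edge length of 5.95 mm measures inter-cluster spacing — denser phantoms
(`phantom_preset("old")`) give shorter edges; the cloud stays more
clustered than random out to ~21 voxel units; and the two along-muscle
profiles track each other closely (r ≈ 0.98).

For cohorts, `run_cohort()` drives manifest rows of NIfTI paths through
extraction → profiles → spatial statistics → `stat_report()`. A thin CLI
(`inst/cli/imfspat.R`) exposes `extract`, `profile`, `spatial`, `phantom`
and `run` subcommands.

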