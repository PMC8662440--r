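# stemvol

Individual-tree structural parameters and standing-volume tables from
paired near-field LiDAR point clouds of planted forests.

Forest inventories need standard (two-way) volume tables — stem volume as
a function of DBH *D* (cm) and total height *H* (m) — but building them
classically means felling sample trees. `stemvol` implements a
non-destructive route for regularly planted stands that combines two
complementary scans:

* an above-canopy **ULS** cloud (UAV laser scanning) that sees every
  treetop → tree heights,
* an under-canopy **BLS** cloud (backpack laser scanning) that sees stems
  up to ~9 m → breast-height and upper-stem diameters.

The chain is: denoising → progressive-TIN ground filtering → 1-m DEM with
IDW gap filling → height normalization → top-down distance-judgement crown
segmentation (ULS) → DBSCAN trunk detection with gravity-centre circle
fits (BLS) → control-point + tree-pattern rigid co-registration → pooled
(D, H, h, d) diameter–height samples → stem taper equations → volume
models, tables, and stand volume.

The statistical core fits five classical taper forms d² = f(D, H, h) by
Levenberg–Marquardt — among them the modified Schumacher form

    d² = a0 · D^a1 · (H − h)^a2 / H^a3

— selects the best by RMSE, and integrates it to volume,

    V = K ∫₀ᴴ d(h)² dh,   K = π / 40000,

the constant that turns cm² · m into m³. Plot volume is expanded from
standard trees (within ±5% of the quadratic mean diameter Dg and mean
height Hg) by the basal-area ratio M = G · ΣVᵢ / Σgᵢ, and reported per
hectare. Tree-detection quality is scored by recall, precision and the
overall accuracy F = 2rp/(r + p).

A synthetic planted-forest generator (`generate_plot()`,
`sample_uls_cloud()`, `sample_bls_cloud()`) with per-point ground truth
makes the whole chain testable end to end without any field data; presets
reproduce the structural attributes of seven surveyed 30 × 30 m plots.

## Worked example

Simulate the medium-density conifer preset (26 trees), run the whole
pipeline, and look at the results:

```r
library(stemvol)
rep <- run_pipeline(pipeline_config(seed = 1))
#> [simulate] preset b: 26 trees, ULS 75600 pts, BLS 458700 pts
#> [preprocess] ULS: 73750 pts, 6184 ground, DEM 31x30
#> [detect-uls] 26 trees (t1=2.0, t2=2.5)
#> [preprocess] BLS: 458700 pts, 6128 ground, DEM 32x32
#> [detect-bls] 26 trunks (eps=0.20, minpts=15)
#> [register] 26 matches, mean error 7.1 cm, 2 iter
#> [profile] 208 diameter-height samples from 26 trees
#> [fit-taper] selected M2 (RMSE 0.18 cm)
#> [volume] M = 24.16 m3, stand volume 268.49 m3/ha

rep$uls_detection
#> Nt=26 No=0 Nc=0  r=1.00 p=1.00 F=1.00

rep$selected_fit
#> Taper fit: M2  (n = 208 )
#>                a0     a1     a2     a3
#> Estimate   1.4559 2.0049 1.3949 1.4927
#> Std. error 0.0878 0.0100 0.0087 0.0189
#> CI 2.5%    1.2829 1.9851 1.3777 1.4554
#> CI 97.5%   1.6290 2.0247 1.4121 1.5299
#> R2 = 0.997  RMSE = 0.177 cm  rRMSE = 0.63%

rep$plot_summary
#> Plot summary: Dg = 31.14 cm, Hg = 27.44 m, 7 standard tree(s)
#> G = 1.981 m2, M = 24.16 m3, stand volume = 268.49 m3/ha

round(rep$volume_table[1:4, 1:4], 4)
#>       H_m
#> DBH_cm     25     26     27     28
#>     24 0.5098 0.5282 0.5465 0.5647
#>     26 0.5986 0.6201 0.6416 0.6630
#>     28 0.6944 0.7195 0.7444 0.7692
#>     30 0.7975 0.8262 0.8548 0.8833
```

Reading the output: all 26 trees were found in both clouds (F = 1.00); the
two clouds align to 7 cm; the pooled 208 diameter–height samples are
fitted to 0.18 cm RMSE; the fitted a1 ≈ 2 reflects that measured DBH is by
definition the stem diameter at 1.3 m, which pins the Schumacher size
exponent (see the methods vignette for the identifiability discussion and
for the simulation-mode recovery diagnostic that refits against true
covariates); and the volume table entries are m³ per tree by DBH and
height class. The plot's 24.16 m³ on 900 m² scale to 268 m³/ha.

Individual stages are exported and usable on their own — e.g.
`classify_ground()`, `segment_trees()`, `detect_trunks()`,
`refine_by_tree_matching()`, `fit_taper()`, `build_volume_table()`,
`stand_volume()`. Clouds are read/written as whitespace-delimited XYZ
(`read_xyz()`/`write_xyz()`), DEMs as ESRI ASCII grids, tables as CSV.

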