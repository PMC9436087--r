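# sxtseg

Intensity-based instance segmentation of organelles in soft X-ray
tomograms.

## The problem

Soft X-ray tomography (SXT) reconstructs whole hydrated cells as 3D grids
whose voxel values equal the local linear absorption coefficient (LAC), a
proxy for molecular density. Semantic segmentation — marking every voxel of
one organelle class — is routine, but biology usually needs *instances*:
how many insulin vesicles, how large is each mitochondrion, how do volumes
and densities shift under treatment. Touching organelles defeat the obvious
answer (connected-components labelling fuses them into one object), and
plain watershed over-segments noisy tomograms.

`sxtseg` splits a semantic mask into instances using the raw tomogram
intensity and a shape prior. Each organelle individual carries its own
interior intensity peak, so the pipeline:

1. splits the mask into 26-connected clusters and crops each with a 2-voxel
   pad;
2. denoises each cluster crop with ten truncated 3×3×3 Gaussians
   (σ = 1…10 voxels) and collects 26-neighbourhood intensity maxima as
   candidate blob centers, screened by the mask;
3. estimates each blob radius from the overlapping ratio
   `a_r = V_m(r) / V_s(r)` (mask voxels vs. discrete-sphere voxels within
   distance `r`), scanning from `r_min = 1.5` voxels until `a_r` first
   drops below 0.8;
4. greedily keeps non-overlapping blobs ranked by raw center intensity;
5. *sphere-like* organelles (vesicles): each blob is one instance;
   *columnar* organelles (mitochondria): blobs are chained via reference
   vectors — a near-collinear triplet (`|cos θ| > cos 30°`) nucleates an
   instance whose axis then attracts aligned blobs within a
   sum-of-diameters reach, K-means with an elbow-selected K clustering the
   leftovers;
6. assigns every mask voxel to the blob minimising `distance / radius` and
   labels it with that blob's instance.

The package also ships the three comparison baselines (connected-regions
labelling, 3D watershed, watershed after σ = 1 Gaussian smoothing), a
parametric synthetic benchmark generator (touching sphere/column phantoms
with ground-truth labels), score-free average-precision evaluation at IoU
0.50–0.95, per-instance volume/intensity statistics with Mann–Whitney
comparisons, and MRC/multi-page-TIFF volume I/O. Volumes are `(z, y, x)`
arrays with 1-based voxel coordinates throughout.

## Worked example

Generate a synthetic dataset of five touching vesicle-like phantoms, split
it, and evaluate against the generator's ground truth:

```r
library(sxtseg)

ds <- assemble_dataset(phantom_spec("sphere", seed = 42), n_instances = 5)
ds
#> <benchmark_dataset> sphere morphology, 5 instances, 100 x 100 x 100 voxels, seed 42

fit <- segment_instances(ds$tomogram, ds$semantic, morphology = "sphere")
tidy(fit)
#> # A tibble: 5 × 4
#>   instance_id volume n_blobs mean_radius
#>         <int>  <int>   <int>       <dbl>
#> 1           1   1237       1           7
#> 2           2   1839       1           8
#> 3           3    203       1           4
#> 4           4    739       1           6
#> 5           5    925       1           6

mean_ap(ds$truth, fit$mask)
#> <sxt_eval> mAP 100.0% (5 truth vs 5 predicted instances)
#>    AP50=100.0 AP55=100.0 AP60=100.0 AP65=100.0 AP70=100.0 AP75=100.0 AP80=100.0 AP85=100.0 AP90=100.0 AP95=100.0

mean_ap(ds$truth, baseline_connected(ds$semantic))
#> <sxt_eval> mAP 0.0% (5 truth vs 1 predicted instances)
#>    AP50=0.0 AP55=0.0 AP60=0.0 AP65=0.0 AP70=0.0 AP75=0.0 AP80=0.0 AP85=0.0 AP90=0.0 AP95=0.0
```

All five touching vesicles are recovered with voxel-accurate boundaries
(every instance matches its ground-truth twin at IoU ≥ 0.95), while
connected labelling sees a single fused object and scores zero.
Per-instance morphometrics come from `instance_statistics()`:

```r
instance_statistics(ds$tomogram, fit$mask, condition = "synthetic")
#> # A tibble: 5 × 4
#>   instance_id volume mean_intensity condition
#>         <int>  <int>          <dbl> <chr>
#> 1           1   1237          0.261 synthetic
#> 2           2   1839          0.261 synthetic
#> 3           3    203          0.289 synthetic
#> 4           4    739          0.259 synthetic
#> 5           5    925          0.241 synthetic
```

`volume` is in voxels (multiply by `prod(voxel_size(ds$tomogram)) / 1e9` for
µm³) and `mean_intensity` in raw LAC units. Condition tables from two
treatments feed `compare_conditions()` for a rank-sum test.
`run_benchmark()` reproduces the full method comparison
(tool / connected / watershed / watershed+Gaussian, averaged over seeded
datasets), and `run_pipeline()` is the file-to-file entry point (MRC/TIFF
in, instance mask + JSON provenance out); `inst/scripts/sxtseg.R` wraps the
same functions as a shell command with `segment`, `baseline`, `synth`,
`evaluate`, `stats` and `benchmark` subcommands.

See `vignettes/sxtseg-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the design notes.

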