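---
title: "Splitting organelle masks into instances: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting organelle masks into instances: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxtseg)
```

## The problem

Soft X-ray tomography (SXT) images intact, hydrated cells in the water
window, producing 3D grids whose voxel intensities equal the local linear
absorption coefficient (LAC) — a proxy for molecular density. Organelle
*semantic* masks (all voxels of one organelle class) are comparatively easy
to obtain, manually or with CNNs, but they do not distinguish *individuals*:
organelles in a crowded cytoplasm touch, and a connected-components pass
fuses every touching group into one blob. `sxtseg` post-processes a semantic
mask into an *instance* mask using two extra sources of information: the raw
intensity of the tomogram (organelle interiors are denser than their rims,
so each individual carries its own intensity peak) and prior knowledge of
the organelle's shape — sphere-like (insulin secretory vesicles) or columnar
(mitochondria).

All volumes are 3D arrays in `(z, y, x)` axis order with 1-based voxel
coordinates. We deliberately use 1-based indices everywhere, including JSON
and CSV exports: the package is R-native, R arrays are 1-based, and a mixed
convention is the classic source of off-by-one defects. Physical units enter
only through the per-axis voxel size (default 35 nm, the sampling of the
beta-cell tomograms that motivated the tool); every distance and radius in
the pipeline is expressed in voxels.

## The pipeline

**Clusters.** The semantic mask is first split into 26-connected components
("clusters"); each cluster is processed independently and blobs never claim
voxels across clusters. 26-connectivity is chosen because diagonal contact
is visually contiguous at this sampling; the same connectivity is used by the
connected-labeling baseline so the comparison is fair. Each cluster is
cropped with a 2-voxel pad (clipped at volume borders), giving the filters
and the radius scan room beyond the organelle surface.

**Multi-scale denoising.** The cluster's raw intensity crop is filtered with
ten Gaussians, sigma = 1..10 voxels in unit steps, each truncated to a
3x3x3 support. The truncated kernel is renormalised to unit sum so that
constant fields — and therefore mean LAC values — are preserved exactly; the
continuous Gaussian prefactor cancels in that renormalisation. Borders are
handled by edge replication so output shape equals input shape even for
crops thinner than the kernel. Scales below 1 voxel add nothing at this
sampling; scales above 10 flatten organelle-sized structure.

**Candidate centers.** A voxel is a candidate blob center if, in at least
one of the ten denoised volumes, it is `>=` all of its 26 neighbours and
strictly `>` at least one. The strict part means perfectly flat plateaus
yield no candidates — important for degenerate synthetic inputs (a constant
cluster produces no maxima and falls through to the whole-cluster fallback
below). Out-of-volume neighbours are ignored on both counts. Maxima are
found per scale and deduplicated by voxel position, keeping the smallest
sigma at which each position peaked; the alternative (a 4D scale-space
maximum) would suppress genuinely coincident detections that the later
greedy selection is better placed to arbitrate. Candidates off the semantic
mask are discarded.

**Radius from the overlapping ratio.** For a candidate center the
overlapping ratio at radius `r` is `a_r = V_m(r) / V_s(r)`, where `V_s(r)`
counts voxels within Euclidean distance `< r` of the center (the discrete
sphere volume) and `V_m(r)` the subset on mask foreground. `a_r` starts at 1
for well-interior centers and decays towards 0 as the sphere outgrows the
organelle. The scan runs from `r_min = 1.5` voxels (the minimal meaningful
blob) to half the crop-box diagonal in steps of 0.5 voxels and stops at the
first value below 0.8; the previous radius is kept, and if even `r_min`
fails, `r_min` is returned. The 0.5-voxel step resolves radii finer than the
1.5-voxel floor without measurable cost; "first drop below threshold" makes
the rule deterministic even when ragged masks make `a_r` non-monotone.

**Greedy selection.** Candidates are ranked by raw-tomogram center
intensity, descending, with ties broken lexicographically by `(z, y, x)`.
The best candidate is always kept; each further candidate is kept only if
its distance to every already-selected blob strictly exceeds that blob's
radius. Strictness matters: at exact equality the candidate sits on the
selected blob's surface and is treated as part of it.

**Sphere route.** For sphere-like organelles each selected blob *is* one
instance.

**Columnar route.** Blobs are grouped into chains before labelling:

1. *Reference vectors.* For every unassigned blob, take its two nearest
   unassigned blobs and the angle `theta` between the two connecting
   vectors. If `|cos(theta)| > cos(30 deg)` the blob proposes a direction —
   the vector sum when `theta <= 90 deg` (both neighbours on one side), the
   difference otherwise (neighbours flanking it). The proposal with the
   largest `|cos(theta)|` wins, its three blobs seed a new instance, and the
   winning direction becomes the instance's fixed reference vector. Only
   unassigned blobs are eligible as nearest neighbours so one blob cannot
   nucleate two instances.
2. *Growth.* Unassigned blobs join the instance when any vector from their
   center to a current member is within 30 degrees (in absolute cosine) of
   the reference vector and shorter than the sum of the two blobs'
   diameters. Members added during growth immediately extend the instance's
   reach; the reference vector itself is never re-estimated, which keeps a
   gently bending chain from drifting into a turn of more than 30 degrees
   total.
3. *K-means fallback.* When no reference vector can be located (fewer than
   three unassigned blobs, or no near-collinear triplet), the leftovers are
   clustered on their coordinates with `stats::kmeans` (10 restarts, fixed
   seed). K runs over `1..min(8, n)` and is chosen as the maximiser of the
   second difference of the within-cluster sum of squares — a standard
   operationalisation of the elbow; with two or fewer blobs, or zero
   variance, K = 1. Short, near-ellipsoidal organelles end up here by
   design.

**Voxel assignment.** Every mask voxel is scored against every blob of its
cluster as `distance / radius`, so larger blobs claim proportionally farther
voxels, and takes the instance label of its lowest-scoring blob (ties go to
the lower blob id, for determinism). The output therefore partitions the
semantic support exactly, with labels contiguous `1..K`. A cluster in which
no blob survived (all maxima screened out, or a perfectly flat cluster)
becomes one whole-cluster instance anchored at a synthetic blob placed at
its intensity-weighted centroid — the partition invariant is maintained
unconditionally.

## Baselines

*Connected-regions labeling* is the 26-connected component labelling of the
mask. *Watershed* floods the intensity field restricted to the mask downhill
from its 26-neighbourhood regional maxima; each maximum seeds a basin and
every other voxel joins its highest already-flooded neighbour. The
implementation is a descending-order flood written for this package because
no installed 3D watershed was available; it is deterministic (intensity
ties break by voxel index). The *watershed + Gaussian* variant first filters
the whole tomogram with the same truncated 3x3x3 Gaussian at sigma = 1.
Watershed's known failure mode — a basin per noise-induced maximum — is
deliberately left untreated (no h-maxima suppression, no tolerance), as the
baselines exist to measure exactly that behaviour.

## The synthetic benchmark

Real hand-segmented instances of the source study are not public, so the
benchmark is parametric. Sphere phantoms are discrete balls (radius 3–8
voxels) whose intensity falls off quadratically from a per-instance peak
(0.35–0.45, the LAC scale reported for insulin vesicles) to the background
(0.10) at the mask boundary — one strict interior maximum each, which is the
structural assumption of blob detection. Column phantoms are chains of 3–7
overlapping balls along a polyline that bends at most 10 degrees per step;
each ball has its own peak, emulating the intensity variation along a
mitochondrion. The per-column ball radius is drawn from 3–5 voxels and the
center spacing is 1.5 radii: the balls then overlap enough to be one
26-connected tube while their maxima remain separable after smoothing. A
dataset attaches five phantoms in sequence: each new phantom slides inward
along a random ray towards the composite and stops at the first touching
(26-adjacent) position, so contact is tangent and any overlap is limited to
the few voxels a one-voxel step can create (always under 10% of either
instance; the later-placed label wins in overlap voxels and the event is
logged). Voxelwise Gaussian noise (sd 0.01) is added last. Everything is
reproducible from a single seed.

What this emulates: touching composites with per-instance intensity peaks,
the exact ambiguity the tool resolves. What it does not: reconstruction
artifacts (missing wedge, rings), correlated noise, uneven interior density,
rater errors in the semantic mask, and curved/branched mitochondria beyond
the gentle per-step bend (loop- and vase-shaped mitochondria are out of
scope). Passing the benchmark therefore demonstrates correct mechanics and
favourable behaviour under idealised contrast, not performance on raw
experimental tomograms. Two consequences of the clean conditions are worth
stating plainly: after sigma = 1 smoothing a sphere phantom retains exactly
one maximum, so the smoothed watershed baseline can saturate on the sphere
benchmark; and because every constituent ball of a column carries a strict
maximum, both watershed variants fragment columns into per-ball basins and
floor near zero there. The benchmark's method ranking is correspondingly
compressed at the extremes compared with noisy real data.

## Evaluation

Instances are matched one-to-one by greedy descent over the IoU table
(ties by lower truth then prediction label); the matching is computed once
and reused for all thresholds. Because the tool emits no confidence scores,
AP at threshold `t` is the score-free ratio `TP / (TP + FP + FN) * 100`,
the standard convention for unscored instance masks; it coincides with
ranked AP at the perfect and empty endpoints. mAP averages the ten
thresholds 0.50–0.95. Per-instance statistics (voxel volume, mean raw
intensity) feed a two-sided Mann–Whitney U test for between-condition
comparisons, exact for small untied samples and tie-corrected normal
approximation otherwise; p-values are reported raw, matching the three
pairwise comparisons the analysis was designed for.

## Problem sizes and reproducibility

The package's own benchmarks use ten datasets of five instances in 100^3
volumes per morphology — large enough that every dataset contains a
multi-instance touching composite, small enough to run on a laptop in about
a minute per morphology. The test suite additionally fuzzes 100 smaller
seeded datasets for the partition invariant and checks every core operation
against an independent brute-force oracle (flood fill, exhaustive
neighbourhood scans, literal rule re-execution, rank-arrangement
enumeration). All randomness flows from explicit integer seeds through R's
default generator; K-means draws are isolated with `withr::with_seed` so
package functions never disturb the caller's RNG state.

## Known limitations

Sphere and column are the only supported morphologies; branched, looped or
sheet-like organelles (ER, Golgi) need different grouping rules. The
columnar growth rule measures angles against a fixed reference vector, so a
chain that genuinely turns more than 30 degrees in total will be split; and
conversely, two columns attached end-to-end along nearly collinear axes are
merged — with touching composites this is the dominant error mode and is
inherent to the rule set, not to its implementation. Radius estimation
assumes locally convex masks; deeply concave clusters can underestimate.
The watershed baseline is intensity-based with plain regional-maxima seeds;
marker-controlled or tolerance-based variants would score differently.
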