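---
title: "Network and fractal characterization of retinal vasculature: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network and fractal characterization of retinal vasculature: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusgraph)
```

## The model

A fundus photograph shows the retinal blood vessels as a dark branching
structure converging on the bright optic disc. fundusgraph reduces a
segmented vessel mask to a weighted, undirected, tree-like graph: nodes are
bifurcation points and vessel endpoints, links are the vessel segments
connecting them. Each segment carries a centerline length $L$ (skeleton
pixels spanned) and a width $W$ estimated from the raw mask pixel count $N$
through $N = L \times W$. Link weights are

$$w_{ij} = L_{ij}^{\,l}\, W_{ij}^{\,a},$$

with adjustable exponents: $(l=0, a=1)$ is the vessel width, $(l=1, a=2)$
is proportional to vessel volume, and $(l=1, a=-2)$ behaves like a
Poiseuille flow resistance. Because $L, W \ge 1$, weights are strictly
positive for any exponent pair.

Three per-image distributions summarize a graph, each using the optic disc
node as the origin of transport:

* **C-NDD** — for every node, the weighted shortest-path distance to the
  central node;
* **CMWD** — the mean link weight along that shortest path (distance
  divided by hop count);
* **WDD** — every node's strength $s_i = \sum_j w_{ij}$.

Images are compared pairwise by the Jensen–Shannon divergence between their
normalized histograms (shared bins across the cohort), giving an $N \times
N$ divergence matrix that IsoMap embeds into two coordinates per image.
Group differences are then tested on these 2-D features, and in parallel on
the box-counting fractal dimensions of the raw and skeletonized masks (the
"fractal dimension plane") and on four basic counts (nodes, links,
endpoints, bifurcations).

## Pipeline stages and their parameters

**Contrast enhancement.** The green channel (highest vessel contrast) is
background-corrected by subtracting a large-kernel median estimate (radius
`min(dim)/24`, at least 8 px) and equalized with CLAHE (8×8 tiles, clip 2).
The output is a vesselness image in $[0,1]$, vessels bright.

**Segmentation.** Felzenszwalb–Huttenlocher graph-based region merging on
the enhanced image (8-connected grid, weight = absolute intensity
difference, adaptive threshold $k/|C|$ with $k = 0.4$, minimum region 30
px), classification of regions as vessel when their mean enhanced intensity
exceeds an Otsu threshold computed on range-based bins (hence invariant to
adding a constant), a 3×3 morphological closing to bridge one-pixel
classification gaps, and retention of the largest 8-connected component. A
largest component below 1% of the image pixels is a segmentation failure;
the pipeline records it and discards the image, mirroring how cohort
studies discard images their segmenter cannot handle. External masks (e.g.
expert manual segmentations) bypass this stage entirely.

**Optic-disc location.** Pixels are scored by the product of a
difference-of-Gaussians brightness (disc-scale bump detector, vignette
cancels) and smoothed vessel density (all vessels converge at the disc).
Confidence is the baseline-relative ratio of the best peak to the best peak
outside three estimated disc radii; below 1.2, or without any bright bump,
the image is discarded as disc-not-found. User-supplied coordinates bypass
detection.

**Skeletonization.** Zhang–Suen thinning followed by a sequential
8-simple-point minimality pass: any non-tip pixel whose set neighbours
remain mutually 8-connected without it is removed. The pass eliminates the
redundant staircase corners and run-end pixels thinning leaves on shallow
diagonals — pixels that would otherwise read as spurious junctions —
while provably preserving connectivity (only simple points are removed,
sequentially).

**Graph extraction.** Tips (1 neighbour) become endpoints; junction pixels
(≥ 3 neighbours) are clustered with their 8-adjacent junction neighbours
into a single bifurcation node at the cluster centroid; segments are traced
along degree-2 chains, $L$ = chain pixels + one pixel per terminal node.
Three artifact-repair rules follow, all configurable:

* spurs shorter than `min_spur = 3` px attached to a junction are pruned;
* junction nodes joined by links shorter than `junction_merge = 6` px are
  consolidated (thinning splits a wide Y into two or three nearby
  3-junctions, sometimes with a tiny loop);
* nodes left with exactly two incident segments are contracted, their
  segments merged with lengths adding — degree-2 points are path points,
  not nodes.

Self-loops and parallel links from genuine crossings are retained; an
isolated pure cycle gets one node and a self-loop. Raw-mask pixels are
assigned to their nearest labelled skeleton pixel by multi-source BFS, so
segment pixel counts partition the mask exactly ($\sum N$ = mask area) and
$W = N/L$, floored at 1 px.

**Feature space.** Histograms use 64 uniform bins spanning the pooled
0.5th–99.5th percentile across the cohort (JS divergence needs one common
support; extreme shortest-path outliers would otherwise dictate the
range). JS divergence uses natural logs, so values live in $[0, \ln 2]$.
IsoMap builds a k-nearest-neighbour graph (`k = 10`, incremented
automatically until connected and logged), computes geodesics with igraph,
and applies classical MDS; with $k = N-1$ it reduces exactly to classical
MDS, which the tests exploit as an oracle. Signs are fixed so each
coordinate's largest-magnitude entry is positive, making runs bit-identical.

## Group testing and the selection problem

The per-method scalar p-value comes from projecting the 2-D features
(IsoMap plane, or the fractal-dimension plane) onto their Fisher
discriminant direction — the "best direction" of the plane — and applying
the pooled-variance two-sample t-test to the projections. The projection
maximizes the very statistic being tested: the squared projected t equals
Hotelling's $T^2$, so treating it as a plain $t$ is anti-conservative
(about 15% rejection at the nominal 5% level for 15 + 15 samples under the
null). `group_separation()` therefore converts the maximized statistic
through the exact $T^2$ null distribution,

$$F = T^2\,\frac{n_1+n_2-p-1}{(n_1+n_2-2)\,p} \sim F_{p,\,n_1+n_2-p-1},$$

which is calibrated: with identical group-generating processes the
reported p-values are uniform (the test suite verifies this over 200
replicate null cohorts). The naive projected t-test remains available as
`p_correction = "none"`, and testing the first IsoMap coordinate alone as
`method = "first_coordinate"`. Basic counts and the two individual fractal
dimensions are scalar features and use the plain pooled t-test.

Pixel-unit lengths and widths are not comparable across image resolutions,
so `run_cohort()` rejects mixed-resolution manifests unless explicitly
overridden; no rescaling is attempted.

## The synthetic-data generator

`generate_vessel_tree()` emulates the features the pipeline actually
consumes: a bright disc at the tree root, `n_trunks = 4` dark vessels
fanning out and bifurcating dichotomously with per-generation length decay
(0.82) and width decay (0.8, floored at 1 px), anti-aliased thick strokes
thresholded at 0.5 so mask boundaries have realistic staircases, an orange
background with vignette and mild Gaussian noise. Defaults (512² px, root
width 8, branch probability 0.85, depth 6) give a few hundred segments per
image, comparable in graph size to downsampled fundus photographs. Two
disease surrogates exist: `thin_branch_rate` grafts short thin side
branches (a neovascularization proxy, adding endpoints and width-1
vessels), and `width_scale` rescales all calibres (a pressure proxy).
A collision-avoidance rule (minimum stroke clearance of 3 px plus half
widths, and a minimum angular separation of 0.35 rad between vessels
leaving one node) keeps the rasterized tree's graph recoverable, and the
ground-truth bookkeeping contracts construction nodes so that its node,
link, endpoint and bifurcation counts are directly comparable to the
extracted graph.

What the generator does **not** emulate: lesions, exudates, texture,
camera vignetting masks, artery/vein distinction, curvature of vessels
(segments are straight between nodes), and true hemodynamics. Passing the
recovery tests therefore shows the graph machinery is correct on clean
tree-like structures, not that segmentation of pathological photographs is
solved.

`generate_dla()` grows on-lattice diffusion-limited aggregation with
noise reduction: walkers stick on 4-neighbour contact with probability
0.05, are launched just outside the cluster, take exact long jumps while
in empty space (walk-on-spheres steps, preserving the harmonic measure)
and die beyond three cluster radii. Noise reduction is the standard
device for reaching DLA's asymptotic scaling at desk-scale particle
counts: with sticking probability 1 a 20,000-particle cluster consists of
single-pixel branches whose small-scale "dust" depresses box counts (the
same clusters' mass–radius dimension is ≈ 1.71 while the composite
box-count slope reads ≈ 1.5). With noise reduction the box-count estimate
converges to the known planar DLA dimension: `dla_dimension()` reports
D ≈ 1.71 (3 seeds, 20,000 particles, 1024² lattice), run by
`scripts/acceptance.R`.

## Numerical choices

* Box counting uses dyadic scales anchored at the origin, no grid-offset
  averaging; default top scale is a quarter of the image side, but
  dimension measurements of isolated objects (such as DLA clusters) cap
  scales at a quarter of the **object's** radius — beyond that the counts
  saturate toward a constant and flatten the slope.
* `fit_dimension()` needs ≥ 4 scales, drops the single largest scale when
  its residual exceeds 3× the median residual (saturation guard, flagged
  in the result), and returns $R^2$ of the log–log fit.
* Ties in central-node assignment break to the lowest node id; a nearest
  node farther than 3 disc radii is a central-assignment failure and the
  image is discarded.
* All generators are pure functions of their seed (`withr::with_seed`);
  the full cohort pipeline is deterministic, and reruns are byte-identical.
* Degenerate inputs: empty masks warn and yield empty skeletons; a
  skeleton that is one pure cycle raises an error; zero-variance
  histograms raise an error at binning; zero-variance t-tests return
  $p = 1$ (equal means) or $p = 0$ flagged degenerate (unequal means).

## Problem sizes used by the test suite

Chosen as the package's own test design: graph-recovery checks use 20
trees at 512² (depth 4, root width 6); null calibration uses 200 replicate
cohorts of 5 + 5 images at 384² on ground-truth masks with the supplied
disc; the end-to-end discrimination check uses 15 + 15 images at 512² with
a 1.2× width contrast through the full automated pipeline (the contrast
gives a pooled t-test power well above 0.99 at this sample size); DLA uses
3 × 20,000 particles on a 1024² lattice.

## Known limitations

* The default segmenter is designed for the synthetic fundus model and for
  reasonably clean photographs; it is not tuned to any public database,
  and expert manual masks should be preferred when available.
* Segment length counts skeleton pixels, not √2-weighted diagonal steps,
  so diagonal vessels are up to 41% "shorter" than their Euclidean length
  and correspondingly "wider" through $W = N/L$; this follows the pixel
  definition of $L$ and cancels in within-cohort comparisons at uniform
  resolution.
* Junction consolidation (6 px) and spur pruning (3 px) are resolution
  dependent; for images much larger than ~1000² they should be scaled with
  expected vessel width.
* Crossovers of the 2-D projection (artery over vein) are kept as
  ordinary graph nodes; no disambiguation is attempted.
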