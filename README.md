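# fundusgraph

Network-based and fractal characterization of the retinal vasculature in
fundus photographs, for researchers comparing cohorts of healthy and
pathological retinas (diabetic retinopathy, glaucoma) through the
*structure* of the vessel network rather than individual lesions.

## What it computes

From each fundus photograph (or a supplied binary vessel mask), the
package extracts a weighted, undirected, tree-like graph: nodes are vessel
bifurcations and endpoints, links are the vessel segments between them,
and the optic-disc node is marked central because all transported blood
enters and leaves there. Each segment has a centerline length *L*
(skeleton pixels) and width *W* from its raw-mask pixel count *N* = *L* ×
*W*, and every link carries the weight

> *w*<sub>*ij*</sub> = (*L*<sub>*ij*</sub>)<sup>*l*</sup> (*W*<sub>*ij*</sub>)<sup>*a*</sup>

with adjustable exponents — width (*l* = 0, *a* = 1), volume (*l* = 1,
*a* = 2), flow resistance (*l* = 1, *a* = −2). Per image it derives

* **C-NDD** — distribution of weighted shortest-path distances of all
  nodes to the central node,
* **CMWD** — distribution of mean link weight along those shortest paths,
* **WDD** — distribution of node strengths *s*<sub>*i*</sub> =
  Σ<sub>*j*</sub> *w*<sub>*ij*</sub>,
* box-counting fractal dimensions *D* of the raw and the skeletonized
  mask (*N*(ε) ~ ε<sup>−D</sup>),
* basic counts: nodes, links, endpoints, bifurcation points.

Cohorts are compared by the pairwise Jensen–Shannon divergence between the
per-image histograms, embedded into a plane with IsoMap; group separation
is tested on the Fisher-discriminant ("best direction") projection of that
plane with a two-sample t-test whose p-value is corrected for the
direction selection (Hotelling's T²), and with plain pooled t-tests for
the scalar features.

A ground-truthed synthetic fundus generator (branching trees with optic
disc, width tapering, and disease surrogates), a noise-reduced
diffusion-limited-aggregation simulator, and analytic fractal phantoms
make every stage testable without access to clinical image databases.

## Worked example

Generate a 5 + 5 synthetic cohort whose disease group has all vessel
calibres scaled by 1.2 (an intraocular-pressure surrogate), run the full
pipeline — automated segmentation, disc detection, graph extraction,
distributions, divergences, IsoMap, group tests — and read the report:

```r
library(fundusgraph)

healthy <- tree_spec(image_size = 512, seed = 1)
disease <- tree_spec(image_size = 512, width_scale = 1.2, seed = 1)
cohort  <- generate_cohort(healthy, disease, n_per_group = 5, seed = 42)
report  <- run_cohort(cohort, run_config())
report
#> <cohort_report> 10 usable image(s), 0 discarded
#> # A tibble: 11 × 5
#>    analysis              l     a statistic  p_value
#>    <chr>             <dbl> <dbl>     <dbl>    <dbl>
#>  1 CNDD                  1    -2     8.66  0.000279
#>  2 CNDD                  1     2    -4.77  0.00901
#>  3 CMWD                  1    -2    -9.88  0.000120
#>  4 WDD                   0     1    -5.49  0.00422
#>  5 nodes                NA    NA     1.38  0.204
#>  6 links                NA    NA     1.29  0.235
#>  7 endpoints            NA    NA     1.56  0.157
#>  8 bifurcations         NA    NA     1.21  0.261
#>  9 FD skeletonized      NA    NA     1.05  0.323
#> 10 FD raw               NA    NA     0.296 0.775
#> 11 FD best direction    NA    NA     2.08  0.220
```

The weighted-distribution methods (C-NDD, CMWD, WDD) detect the calibre
contrast at p < 0.01 while the topology-only features (counts, fractal
dimensions) correctly stay non-significant — a pure width change leaves
the branching structure untouched. `autoplot(report$embeddings$wdd_l0_a1,
labels = ...)` shows the IsoMap plane, `plot_fd_plane(report$fd)` the
fractal-dimension plane, and `write_cohort_report(report, "out/")` exports
everything as CSV.

The fractal estimator itself can be checked against an analytic phantom:

```r
fit_dimension(box_count(make_phantom("sierpinski_carpet", 729),
                        scales = 3^(1:5)))
#> <fractal_fit> D = 1.8928 (R^2 = 1.0000, eps 3..243 over 5 scales)
```

(log 8 / log 3 ≈ 1.8928.)

Real images enter through a manifest CSV with columns `path`, optional
`mask_path` (expert segmentations bypass the automated segmenter),
`label`, and optional `disc_row`/`disc_col`/`disc_radius`; pass it
directly to `run_cohort()`. A thin command-line wrapper is installed at
`inst/scripts/fundusgraph` (subcommands `synth`, `run`, `dla`).

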