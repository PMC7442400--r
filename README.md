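# bonetex

Three-dimensional gray-level co-occurrence (GLCM) texture analysis of
trabecular bone for R.

Areal bone mineral density (BMD) from DXA is the clinical workhorse of
osteoporosis assessment, yet it ignores the spatial microarchitecture
that also determines bone strength. Texture statistics computed inside a
segmented vertebral body on routine MR images offer an indirect,
widely-available window on that microarchitecture. `bonetex` is for
imaging researchers who want that measurement chain as tested,
scriptable code: it reads NIfTI volumes and masks, quantizes a volume of
interest (VOI), builds 3-D co-occurrence matrices over the 13
antipodally-deduplicated lattice orientations at voxel distances 1–5
(65 matrices per VOI), derives the 22 classical co-occurrence
attributes, relates each attribute to BMD, and quantifies interobserver
reproducibility.

At its core, a co-occurrence matrix for displacement **d** estimates

    p(i, j) = Pr[ level(v) = i  and  level(v + d) = j ],  both voxels in the VOI,

after equal-width quantization of in-mask intensities into *N<sub>g</sub>* = 32
levels. Each matrix yields the classical attribute family — energy
Σp², entropy −Σp log₂ p, contrast Σ(i−j)²p, homogeneities, cluster
moments, information measures of correlation, sum/difference statistics
— and the 65 per-matrix vectors are averaged into one 22-attribute
feature vector per subject. Associations use ordinary least squares of
BMD on each attribute (model 1) and an age/BMI-adjusted fit (model 2)
with Pearson correlations; interobserver agreement uses Lin's
concordance correlation coefficient (CCC) with its asymptotic
confidence interval and the conventional strength labels
(poor … almost perfect). A synthetic phantom/cohort generator with a
known texture–density coupling exercises every stage without clinical
data.

## Worked example

Simulate a 49-subject cohort with two raters' segmentations, extract
features, and run both analyses:

```r
library(bonetex)

dir <- file.path(tempdir(), "demo")
generate_cohort(cohort_sim_spec(n = 49, seed = 11), dir)

fa <- run_extract(dir, masks = "masks_a")   # rater A
fb <- run_extract(dir, masks = "masks_b")   # rater B
fa[1:3, c("id", "energy", "entropy", "contrast", "n_matrices")]
#> # A tibble: 3 × 5
#>   id     energy entropy contrast n_matrices
#>   <chr>   <dbl>   <dbl>    <dbl>      <int>
#> 1 S001  0.00279    8.88     59.6         65
#> 2 S002  0.00208    9.24     77.5         65
#> 3 S003  0.00299    8.90     51.7         65
```

Each subject's 65 co-occurrence matrices were all non-empty
(`n_matrices`), and coarser-textured subjects show lower entropy and
contrast. Associating the attributes with BMD:

```r
assoc <- run_associate(fa, file.path(dir, "cohort.csv"))
dplyr::filter(assoc, significant)[, c("attribute", "coefficient_model1",
                                      "p_model1", "pearson_r")]
#> # A tibble: 13 × 4
#>    attribute          coefficient_model1 p_model1 pearson_r
#>  1 contrast                     -0.00326  0.00381    -0.406
#>  2 correlation                   0.381    0.00376     0.406
#>  3 difference_entropy           -0.191    0.00264    -0.420
#>  4 dissimilarity                -0.0557   0.00338    -0.411
#>  5 energy                       60.5      0.0171      0.339
#>  6 entropy                      -0.155    0.00982    -0.365
#>  ...
```

Thirteen attributes reach p < 0.05; slopes are in g/cm² per attribute
unit, and the Pearson r of roughly ±0.3–0.4 reflects the simulated
coupling between trabecular coarseness and density. Interobserver
reproducibility against the second rater's masks:

```r
cc <- run_concordance(fa, fb)
dplyr::arrange(cc, ccc)[1:3, ]
#> # A tibble: 3 × 6
#>   attribute            ccc ci_low ci_high strength           n
#> 1 cluster_prominence 0.942  0.900   0.967 almost perfect    49
#> 2 cluster_tendency   0.963  0.935   0.979 almost perfect    49
#> 3 sum_variance       0.963  0.935   0.979 almost perfect    49
sum(cc$strength == "almost perfect")
#> [1] 22
```

Even the least reproducible attribute has CCC 0.94: all 22 attributes
are "almost perfect" under a one-voxel segmentation disagreement.
`autoplot(assoc)` and `autoplot(cc)` draw the corresponding summary
figures, and `tidy()`/`glance()` work on `lin_ccc()` results.

A thin CLI wrapper (`inst/cli/bonetex.R`) exposes `simulate`,
`extract`, `associate`, and `concordance` subcommands over the same
functions.

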