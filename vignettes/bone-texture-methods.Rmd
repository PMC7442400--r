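---
title: "Methods: 3-D co-occurrence texture analysis of vertebral bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3-D co-occurrence texture analysis of vertebral bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetex)
```

## The problem

Areal bone mineral density (BMD) from dual-energy X-ray absorptiometry is
the clinical standard for osteoporosis assessment, but it summarizes bone
as a single mass measurement and misses microarchitectural quality. The
spatial arrangement of signal inside a vertebral body on a routine
T2-weighted MR image carries texture information that plausibly reflects
trabecular microarchitecture. `bonetex` implements the quantitative side
of that idea: gray-level co-occurrence texture attributes of a segmented
vertebral volume of interest (VOI), their association with BMD, and the
interobserver reproducibility of the whole measurement chain.

## The co-occurrence model

A 3-D gray-level co-occurrence matrix (GLCM) for a displacement vector
$\mathbf{d}$ estimates the joint probability $p(i, j)$ that a voxel of
quantized gray level $i$ has a partner of level $j$ at offset
$\mathbf{d}$, with both voxels inside the VOI. The pipeline is:

1. **Quantization.** In-mask intensities are binned into $N_g$ equal-width
   levels over the in-mask range:
   $\ell(v) = \min\!\big(N_g, \lfloor (v - v_{\min}) N_g / (v_{\max} -
   v_{\min}) \rfloor + 1\big)$. Binning is range-relative, so the features
   are invariant to global intensity shifts and rescalings — important for
   MR, which has no absolute intensity scale. A constant VOI maps to a
   single level.
2. **Counting.** For each of 13 lattice directions (the 26-neighbourhood
   with opposite directions identified) and each distance
   $d \in \{1, \dots, 5\}$ voxels, ordered in-mask pairs are counted,
   symmetrized ($C \leftarrow C + C^{\mathsf T}$), and normalized. That
   yields $13 \times 5 = 65$ matrices per VOI. Displacements are pure
   lattice offsets (`direction * distance`); voxel anisotropy is recorded
   in the header but deliberately not used to rescale offsets, matching
   standard lattice-GLCM practice.
3. **Attributes.** Each matrix yields the 22 classical co-occurrence
   statistics (`glcm_attributes()`): energy $\sum p^2$, entropy
   $-\sum p \log p$, contrast $\sum (i-j)^2 p$, two homogeneities,
   cluster shade/prominence/tendency, the information measures of
   correlation, sum/difference statistics, and so on. All
   $0 \log 0$ terms are 0.
4. **Aggregation.** The per-matrix values are averaged (unweighted, over
   all non-empty matrices) into one 22-element feature vector per VOI.

### Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_levels` | 32 | Enough levels to discriminate texture without making a 65-matrix set sparse on VOIs of a few thousand voxels. Configurable. |
| `distances` | 1–5 voxels | Short-range trabecular-scale structure. |
| `directions` | 13-orientation set | Complete antipodally-deduplicated 26-neighbourhood. |
| `symmetric` | `TRUE` | Symmetric counting is what makes one matrix per antipodal axis sufficient. |
| `log_base` | 2 | Entropies in bits; natural log selectable. |
| `aggregation` | mean over matrices | The dominant convention; a mean-over-directions-then-distances variant is selectable and coincides with it whenever no matrix is empty. |

### Numerical and degenerate-case choices

* `correlation` and `imc1` are defined as 0 when their denominators
  vanish (constant texture); the `imc2` radicand is clamped at 0;
  `inverse_variance` sums off-diagonal cells only. Constant VOIs therefore
  produce finite, testable features (energy 1, entropy 0).
* A displacement with no valid in-mask pair (possible for thin VOIs at
  distance 5) is skipped with a classed warning rather than failing the
  VOI; `n_matrices` records how many matrices contributed.
* `variance` is the moment about the mean level of the matrix mass, which
  equals the marginal mean for symmetric matrices. `sum_variance` is the
  second moment of the cross-sum distribution about the *sum average*
  (the literature also contains a variant about the sum entropy; the
  sum-average form is implemented).
* Because the 13-direction set is closed (up to antipodes) under
  90-degree grid rotations and counting is symmetric, the aggregated
  feature vector is exactly rotation-invariant; the suite checks this to
  1e-10.

## Association and reproducibility statistics

For each attribute the package fits BMD on the attribute by ordinary
least squares ("model 1", slope, two-sided $t$ p-value, $n-2$ df) and
with age and BMI as covariates ("model 2", $n-4$ df), and reports the
Pearson correlation. Raw p-values at $\alpha = 0.05$ are reported over
the 22 attributes without multiplicity correction, mirroring the
conventional radiomics report; an optional Benjamini–Hochberg column can
be switched on (`add_bh = TRUE`). Constant covariates are dropped by the
fit (model 2 then degrades to model 1); a feature collinear with the
covariates is an error, not a silent NA.

Interobserver agreement uses Lin's concordance correlation coefficient
with $1/n$ moment estimators,

$$\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

confidence intervals through the inverse-hyperbolic-tangent transform
with Lin's asymptotic variance, and the conventional agreement labels
(poor < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤ substantial < 0.80 ≤
almost perfect ≤ 1). Boundaries belong to the upper label because the
printed ranges are disjoint at two decimals; negative coefficients are
"poor". $|\hat\rho_c| \le |r|$ always (arithmetic–geometric mean
inequality), and the suite verifies this on random fixtures. At
$|\hat\rho_c| = 1$ the asymptotic variance degenerates and the interval
collapses to the point estimate.

Two-group demographic comparisons use one-way ANOVA, which for two
groups is exactly the squared pooled-variance $t$ test. Identical data
across groups is reported as $p = 1$.

## What the synthetic cohort emulates — and what it does not

There is no public imaging behind this pipeline, so the package ships a
generator whose outputs exercise every stage:

* **Phantom.** Unit white noise smoothed by a separable Gaussian of
  scale $\ell$ voxels (the *coarseness*), plus white noise whose SD is
  `noise_sd` times the smoothed-field SD (an inverse SNR, default 0.1),
  windowed at ±2 SD about the mean and rescaled to [0, 1000]. The fixed
  ±2 SD window (the analogue of MR display windowing) keeps the
  gray-level histogram shape comparable across coarseness levels, so
  entropy falls — and energy rises — monotonically with $\ell$, the
  qualitative behaviour expected of coarsening trabecular texture. In
  the $\ell \to \infty$ limit the field's dynamic range collapses below
  1e-6 and the volume is emitted exactly constant, the clean degenerate
  case. Default grid 32×32×16 at 0.8×0.8×3.0 mm emulates an anisotropic
  sagittal FSE acquisition; the VOI is the inscribed ellipsoid minus a
  2-voxel margin (~4900 voxels).
* **Cohort.** Subject coarseness $\ell_i \sim U(1, 4)$ (chosen once as a
  range that spans visibly fine to visibly coarse texture at 32 levels);
  $\mathrm{BMD}_i = 1.0 + \beta\,\tilde\ell_i + \varepsilon_i$ with
  $\tilde\ell$ standardized, default $\beta = 0.05$ g/cm² per SD and
  residual SD 0.13 g/cm² — the DXA scale of a healthy adult cohort, and a
  coupling whose implied correlations (|r| ≈ 0.3–0.4) sit in the range
  such studies report. BMD couples to the coarseness *parameter*, not to
  any attribute, so recovery tests cannot tautologically encode a feature
  formula. Ages are uniform on 20–68 years, BMI on 18–25 kg/m²
  (typical eutrophic-volunteer inclusion windows); sex is drawn 29:20
  F:M. All randomness descends from one seed (subject $i$ uses
  `seed + 7919 i`).
* **Second rater.** `perturb_mask()` dilates about a quarter of the
  boundary and erodes another quarter (patches selected by a smooth
  random field thresholded at the ±75% normal quantiles), to a depth of
  `jitter` voxels — a caricature of where two humans disagree when
  tracing the same vertebra. At jitter 1 on a ~1000-voxel mask the Dice
  overlap stays ≥ 0.85.

The generator is deliberately *not* a biophysical bone model: no Rician
noise, bias fields, marrow heterogeneity, cortical shell, or partial
volume. Passing tests therefore demonstrate that the measurement chain
is correct and well-calibrated, not that these attributes predict
density in real patients — the latter claim can only come from imaging
data.

## Problem sizes used by the checks

The statistical checks run at the study's natural scale: type-I
calibration uses 1000 null replicates at $n = 49$; coupling recovery a
200-subject cohort at $\beta = 0.05$; the two-rater reproducibility
simulation 49 subjects at jitter 1, where at least 18 of the 22
attributes are expected to exceed a concordance of 0.80. Unit fixtures
(oracle enumeration, rotation invariance) use small grids where
brute-force enumeration is exact.

## Known limitations

* Features are computed on the acquired lattice; anisotropic voxels mean
  the 13 directions are not isotropic in physical space. This matches
  common practice but is worth remembering when comparing protocols.
* Range-relative quantization ties the level scale to the in-mask
  min/max, which is outlier-sensitive on real images (here the phantom's
  ±2 SD window performs that role).
* Lin's CI is asymptotic; at small $n$ or $|\rho_c|$ near 1 it is
  approximate, and degenerate inputs fall back to the conservative
  interval $[-1, 1]$.
* The 65-matrix aggregation is a single unweighted mean; distance-wise
  feature profiles are not retained (extract per-distance vectors by
  restricting `distances` if needed).
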