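---
title: "Morphometric similarity imaging transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity imaging transcriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msntx)
```

This vignette documents the statistical models behind `msntx`, the
parameters that matter, the synthetic-data generator's assumptions, and the
design decisions taken where more than one reasonable choice existed. It
states no empirical result beyond what the package's tests and acceptance
script compute.

## Cohort classification

Subjects are stratified by two CSF biomarkers. The negative group requires
amyloid-beta at or above `abeta_threshold` (980 pg/mL) **and** tau at or
below `tau_threshold` (24 pg/mL), with inclusive comparisons; the positive
group requires both comparisons reversed, strictly. The two definitions
plus the residual `EXCLUDED` label partition the biomarker plane exactly:
a mixed profile (one marker positive, one negative) is never silently
assigned to a group. Mixed profiles are retained in the covariate table
with the `EXCLUDED` label and dropped — with a count — by every group
analysis, because the two clean groups maximize the contrast of interest
and mixed biology is a separate question.

Gender is coded numerically as M = 1, F = 0 wherever it enters a design
matrix, so reported coefficients are reproducible from the documentation
alone.

## Morphometric similarity

Each subject contributes a 34 x 13 matrix: the 34 left-hemisphere
Desikan-Killiany cortical regions by 13 regional features (area, folding
index, curvature index, Gaussian curvature, mean curvature, thickness,
volume; mean/radial diffusivity, fractional anisotropy, and the three
diffusion-tensor eigenvalues). Feature names are the package's own; the
canonical region order is fixed by `dk_rois()` and unknown labels are a
hard error rather than a silent reindex.

Features are z-scored per column across the 34 regions (sample SD,
denominator n − 1; the statistic is invariant to that choice as long as it
is applied uniformly, and the sample convention matches common statistical
practice). The MSN is the 34 x 34 Pearson correlation matrix between
regional feature rows; its diagonal is set to 1 and always excluded from
summaries. Regional MS is the mean absolute off-diagonal entry per row, a
number in [0, 1]: how similar a region's morphometric/microstructural
profile is to the rest of the cortex. Z-scoring makes the whole chain
invariant to affine rescaling of any raw feature (units of mm^2 vs cm^2
cannot matter), which is tested by property.

Degenerate inputs fail loudly: a zero-variance feature column cannot be
z-scored and names the offending feature; a zero-variance regional row has
no defined correlation and names the region.

## Group contrast

Per region, ordinary least squares of regional MS on an intercept, group
(positive = 1), age (years), gender, education (years) and MMSE (0–30).
The group t-statistic (df = n − 6) with two-sided p-values is the effect
measure; positive t means higher regional MS in the biomarker-positive
group. The 34 p-values are adjusted by Benjamini–Hochberg; the FDR
procedure is fixed to BH as the standard step-up choice. The t-map — not
the thresholded regions — is the response carried into the transcriptomic
association, so the analysis retains regional information even when no
single region survives correction.

`contrast_map()` solves all 34 regressions jointly from one Cholesky
factorization of the shared design matrix; a unit test checks it against
per-region `lm()` fits, and `fit_roi_model()` against an explicit
normal-equations solve (tolerance 1e-10). A constant response (zero
residual variance and zero effect) is defined to give t = 0, p = 1 rather
than 0/0.

## Expression preprocessing

The donor-level chain mirrors the standard atlas-based microarray
workflow, with these parameter choices:

* **Intensity filter** (`min_fraction = 0.5`): a probe is kept when it is
  flagged above background in at least half of all samples, pooled across
  donors. The 0.5 fraction is the common toolbox default; pooling (rather
  than per-donor filtering) keeps a single probe universe across donors.
  The boundary is inclusive.
* **Differential stability**: for each probe, the mean over donor pairs of
  the Spearman correlation between regional profiles, computed on regions
  both donors sampled (at least 3 in common; pairs with a constant profile
  are skipped as the correlation is undefined). One probe per gene is kept
  by maximal DS, ties broken to the lexicographically smallest probe id so
  the selection is deterministic.
* **Sample assignment** (`radius = 2` mm): nearest region centroid within
  the radius, Euclidean distance. Regions a donor did not hit receive that
  donor's single globally nearest sample as a fallback, so every donor
  covers every region. Centroid distance abstracts the volumetric parcel
  geometry; voxel-level assignment is out of scope.
* **Scaled robust sigmoid**: per donor and gene,
  `s = 1 / (1 + exp(-(x - median(x)) / (IQR(x)/1.35)))` over regions,
  then min-max rescaled to [0, 1]. IQR/1.35 approximates the SD of a
  normal distribution, making the transform comparable to a z-score-based
  sigmoid but robust to outliers; it is strictly monotone and invariant to
  affine transforms of the input. A zero-IQR profile is degenerate and the
  gene is dropped for that donor.
* **Donor averaging** is unweighted over the donors contributing a value;
  a cell no donor covers is an error, never an imputed value.

## PLS association

With standardized predictors `X` (34 x G) and centred response `y`, the
first PLS component with a univariate response has the closed form
`w = X'y / ||X'y||`, scores `t = Xw`. The package fits exactly this form;
the test suite checks it against an independently coded cross-covariance
route on random instances (cosine within 1e-10). PLS components are
sign-indeterminate, so the component is oriented to make the
score–response correlation non-negative; with the closed form the
orientation is automatic (`cov(Xw, y) = ||X'y|| >= 0`), and the guard
exists for roundoff and for API clarity.

**Permutation test.** The statistic is the score–response correlation *r*
(equivalently, any monotone function of R² gives the same p). The response
is shuffled uniformly over the 34 regions; `p = (1 + #extreme)/(n_perm + 1)`
(add-one estimator, so p is never 0). For few regions an exact mode
enumerates all permutations, with `p = #extreme / n!` including the
identity; the 4-region worked example (a single perfect predictor) gives
exactly 2/24, realized by the identity and the full reversal. Spatial
autocorrelation-preserving nulls ("spin" tests) are intentionally out of
scope; the naive exchangeable null is what this design specifies, and its
calibration is verified by simulation (rejection rate at the 5% level
within the binomial band over 200 null datasets).

**Bootstrap gene scores.** Regions are resampled with replacement
(`n_boot` default 1000; the original analysis does not fix a value);
within each replicate the predictors are re-standardized — the fitted
object is defined on standardized predictors, so the replicate must be
too — and the refit weight vector is sign-aligned to the original by dot
product before accumulation, because unaligned replicates would inflate
the SE for every gene at once. `z = w / SE`; two-sided normal-tail
p-values are BH-adjusted over **all** scored genes (the alternative —
correcting only pre-selected genes — is circular), and the lists are
`z > 3, q < 0.05` (positive) and `z < -3, q < 0.05` (negative), strict
comparisons, sorted by |z|. A replicate with fewer than 3 distinct
regions, a zero-variance resampled column, or a constant resampled
response is redrawn (bounded retries); a gene with zero bootstrap SE has
no defined z and is excluded from selection with a message.

## Enrichment

Overlap between a query list and a target set within a background universe
is tested by the one-sided (enrichment) Fisher exact test, computed as the
hypergeometric upper tail `P(X >= a)`. The reported odds ratio is the
sample estimate `a*d/(b*c)` from the 2x2 table — not the conditional-MLE
that `fisher.test()` prints — so numbers are directly comparable with
overlap tools that report the sample OR; `Inf` (b·c = 0 with overlap) and
0 (no overlap) are explicit. Only enrichment is tested, not depletion. BH
adjustment is applied within each query-by-collection family and never
pooled across collections, matching how cell-type and disease-list
analyses are corrected "for the number of cell types". Query genes outside
the background are dropped with a message, consistent with defining the
universe by the expression pipeline's final gene list.

## The synthetic-data generator

The generator makes the pipeline testable without the restricted imaging
and expression resources. What it emulates, and how:

* **Cohort**: group sizes default to 172 negative / 126 positive; age,
  education and MMSE are Gaussian per group with the study-summary means
  and SDs (age 71.05 (7.10) vs 77.18 (7.92) years; education 16.70 (2.38)
  vs 16.01 (2.54) years; MMSE 28.85 (1.47) vs 26.06 (4.62), rounded and
  clipped to [0, 30]); male proportions 71/172 and 60/126. CSF values are
  truncated normals drawn inside each group's classification region, so
  labels and concentrations are consistent by construction.
* **Features**: for subject *s*, region *i*, the 13-vector is
  `sqrt(alpha_i) * l_si * g_s + sqrt(1 - alpha_i) * e_si`, where `g_s` is
  a subject-level profile of unit-magnitude random-sign feature weights,
  `l_si` a random region sign, and `e_si` standard normal noise. Each
  feature has unit variance, of which `alpha_i` comes from the shared
  profile; the absolute correlation between regions *i* and *j* approaches
  `sqrt(alpha_i * alpha_j)`, so regional MS increases in alpha and
  saturates at 1. Two modelling points are deliberate. First, the shared
  term must carry a region-varying factor: without `l_si` it is a constant
  per-feature offset across regions, which the pipeline's z-scoring
  removes exactly, leaving no similarity signal at all. Second, the
  feature weights have unit magnitude rather than Gaussian draws: Gaussian
  weights leave near-zero-weight features as pure noise and cap the
  attainable similarity well below 1 even as alpha approaches 1. The
  group effect adds `effect_delta` (default 0.15) to alpha in the target
  regions (default: caudal anterior cingulate, lateral occipital, cuneus,
  pars triangularis) for positive-group subjects only. Planting the effect
  in the similarity structure — not in feature means — makes it visible to
  regional MS and invisible to naive mean comparison, a built-in negative
  control.
* **Expression**: signal-gene columns are the standardized planted pattern
  times `signal_snr` (default 1) with a random sign (half positive, half
  negative) plus unit noise; null genes are pure noise; all columns are
  min-max rescaled to [0, 1]. Defaults: 1000 genes, 50 signal genes per
  sign.
* **Donor samples**: 34 centroids on a 20 mm grid (far beyond the 2 mm
  assignment radius); 6 donors, each covering a random 90% of regions with
  3 samples per region jittered at most 1 mm from the centroid, so every
  emitted sample is assignable to its true region; intensities are a
  donor-specific affine distortion (log-normal gain, additive offset) of
  the ground truth plus Gaussian noise, with 2 probes per gene — one
  low-noise (SD 0.1) flagged above background at rate 0.9, one high-noise
  (SD 0.5) at rate 0.45. These rates straddle the 0.5 intensity-filter
  threshold so the filter and the differential-stability criterion both
  have real work to do.
* **Gene sets**: one enriched set per sign drawing half its members from
  the same-signed signal genes, plus uniform null sets, all within the
  background.

What it does **not** emulate: cortical geometry and parcel shapes, scanner
and site effects, non-Gaussian feature noise, spatially autocorrelated
expression beyond the planted pattern, batch structure across donors, and
longitudinal drift. Passing tests therefore demonstrate the statistical
machinery — calibration under the null, recovery of planted effects,
determinism — not performance on real cohort data.

All generators accept a seed and are bit-reproducible; seeded calls save
and restore the caller's RNG state, and `run_pipeline()` derives
independent per-stage substreams from its single master seed, so two runs
with one seed write byte-identical outputs.

## Problem sizes in the test suite

The validation suite chooses sizes that keep the full run to a few
minutes while leaving the statistical checks well-powered: 100 random
tables for the MSN and PLS closed-form oracles (tolerances 1e-12 and
1e-10); 200 null datasets x 500 permutations for permutation calibration;
2000 genes with 100 planted at SNR 1 and 500 bootstrap replicates for
recovery (at least 80% recovered, at most 5% null contamination); 1000
global-null cohorts of 60 subjects for contrast calibration
(Kolmogorov–Smirnov uniformity of pooled p at the 1% level, family-wise
BH discovery rate at most 0.07); 500 random tables for the
hypergeometric-tail oracle and 1000 vectors for the BH oracle; a 150-gene
donor panel for end-to-end preprocessing recovery (mean per-gene Spearman
at least 0.8).

## Known limitations

* The expression chain assumes one probe-to-gene map is given; probe
  reannotation against live annotation releases is out of scope.
* Fallback assignment reuses a donor's nearest sample for uncovered
  regions; with sparse donors this duplicates information across regions,
  which donor averaging then dilutes but does not remove.
* The permutation null treats regions as exchangeable; if the contrast map
  and expression share smooth spatial structure, this null is liberal
  compared to autocorrelation-preserving alternatives.
* Enrichment inference conditions on the gene lists; uncertainty from the
  bootstrap selection step is not propagated into the Fisher tests.
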