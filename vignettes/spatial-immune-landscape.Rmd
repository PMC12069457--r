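---
title: "Methods: spatial statistics of the tumor immune microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics of the tumor immune microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timescape)
```

# Overview

`timescape` analyzes cell-level tables derived from multiplex imaging of
tumor tissue (imaging mass cytometry or multiplex immunofluorescence): one
row per segmented cell carrying planar coordinates within a region of
interest (by default 1 × 1 mm, coordinates in µm) and per-marker
intensities, together with a per-patient clinical table. The pipeline has
five analytic stages — phenotyping, inflammatory-neighborhood assignment,
cross-type nearest-neighbor (G-cross) statistics, compositional comparison
between cohorts, and survival association — plus a synthetic-cohort
generator that provides a recoverable ground truth for every stage.

This vignette is the package's methods account: the models, their
assumptions, the tunable parameters with their defaults, the numerical
choices, and what validation on synthetic cohorts does and does not
establish about real tissue.

# Phenotyping

## H-score

Staining intensity on an ordinal 0/1+/2+/3+ scale is summarized by the
H-score,

$$H = 1\cdot p_{1+} + 2\cdot p_{2+} + 3\cdot p_{3+},$$

with $p_k$ the percentage of cells in bin $k$. The score ranges from 0 (no
staining) to 300 (all cells at 3+). `compute_hscore()` validates that each
percentage lies in [0, 100] and that they sum to at most 100.

## Threshold gating

Cells are assigned phenotypes by intensity thresholds: a cell is positive
for a marker when its intensity is **at or above** the marker's threshold
(a closed bound — the common gating convention; the boundary case matters
only on artificial data, but the convention is fixed and documented).
`phenotype_rule()` objects pair required-positive and required-negative
marker sets with a priority; among satisfied rules the lowest priority
number wins the exclusive `phenotype` label, so subtype rules (CTL =
CD3+CD8+, Th = CD3+CD4+, M2 = CD68+CD163+) pre-empt their parents (T =
CD3+, TAM = CD68+). Cells satisfying no rule are labeled `other`; they
count in denominators but are never a focal type.

The taxonomy is deliberately *overlapping*: a CD3+CD8+ cell is a CTL
**and** a T cell. `classify_cells()` therefore also emits one `is_<type>`
indicator column per rule, and `cell_type_proportions()` divides each
type's count by **all** cells in the sample, so proportions of nested
populations do not sum to one. This matches reporting cytotoxic T cells
and the overall T-cell population as separate rows of one figure.

The default marker panel and rule set are a configurable stand-in: the
exact antibody panel behind any given study is not part of the package,
and NK/M2 gating markers in particular vary between panels. Thresholds
are fixed per-marker configuration values, not learned; the default is
the geometric mean of the synthetic signal model's high and low means
(√(50·1) ≈ 7.07), i.e. the midpoint of a log-normal two-population model.

# Inflammatory neighborhoods

Six inflammatory markers (CD74, CD44, MIF, iNOS, mPGES1, NT) define seven
marker combinations (CD74 CD44, CD74 MIF, MIF CD44, CD74 CD44 MIF,
iNOS mPGES, iNOS mPGES-NT, iNOS NT). A cell positive for every marker of
a combination is an *anchor*; the combination's *neighborhood* is the
union of discs of radius $R$ around its anchors — equivalently, a cell is
a member iff its nearest anchor lies within $R$ (closed bound; anchors
are members at distance 0). Membership is computed within each sample
independently and is monotone in $R$. The default $R$ is 40 µm — the
interaction range emphasized in spatial survival analyses — sweepable
over 20–80 µm. Whether the original regions of interest were disc unions
or segmentation-derived polygons is not knowable from a cell table; disc
unions are the implemented interpretation.

Neighborhoods may overlap and a cell may hold several memberships; no
exclusive tiling is imposed. Three per-sample proportion views follow:

1. **prevalence** — members / all cells (`neighborhood_proportions()`);
2. **cell types within a neighborhood** — type ∧ member / members
   (`celltype_within_neighborhood()`; undefined and excluded when a
   neighborhood has no members in a sample);
3. **neighborhoods within a cell type** — type ∧ member / type
   (`neighborhood_within_celltype()`; excluded when the type is absent).

One simplification is baked in: anchor positivity is read from the same
cell table as everything else. A study that thresholds inflammatory
markers on a co-registered second modality and transfers regions across
images collapses, in this package, to a single table — acceptable because
the analysis consumes only cell-level positivity and coordinates.

# G-cross spatial statistics

The cross-type nearest-neighbor distance function $G_{i,j}(r)$ is the
cumulative distribution of the distance from a typical type-$i$ cell to
its nearest type-$j$ cell. Under a homogeneous Poisson target process of
density $\alpha_j$ (per µm², estimated as count/window area) independent
of type $i$,

$$G_{i,j}(r) = 1 - \exp(-\alpha_j \pi r^2),$$

which serves as the no-interaction baseline: empirical curves above it at
small $r$ indicate attraction, below it dispersion.

`gcross_empirical()` estimates $\hat G$ on a radius grid (default 0–80 µm
in 1 µm steps; reported radii 20/40/60/80 µm):

* **raw**: the fraction of type-$i$ cells whose nearest $j$ lies within
  $r$. Near the window edge nearest-neighbor distances are censored by
  the window, giving a small downward bias (~10⁻³ at the default
  densities and window).
* **border** (default): the reduced-sample correction — at each $r$ the
  reference set is restricted to cells at least $r$ from the boundary, so
  no distance is censored. The estimate is undefined (`NA`) at radii
  where the restricted set is empty. Border correction is the simplest
  estimator that is unbiased for a stationary process and whose behavior
  is fully testable against a brute-force oracle; other corrections
  (Kaplan-Meier style, Hanisch) would give numerically different curves,
  a known divergence risk when comparing against analyses whose edge
  correction is unspecified.

Conventions: when $i = j$, a cell's own point is excluded from its
nearest-neighbor search; coincident points count as satisfied at every
radius; a sample with zero cells of either type cannot contribute a curve
for the pair and is excluded (and logged by `gcross_features()`), the
nearest-neighbor analogue of zero-variance exclusion. Each sample
contributes one curve; curves are never pooled across cores — patient-level
correlation is handled downstream in the survival models.

`gcross_at()` evaluates curves by linear interpolation; `gcross_auc()`
integrates by the trapezoid rule with undefined grid points dropped and
the trapezoids re-spanned, yielding the scalar infiltration feature used
for organ-stratified survival scans (units: µm; a curve pinned at 1 over
[0, 40] integrates to 40).

`gcross_within_neighborhood()` conditions the **reference** cells on
membership in a neighborhood while leaving target cells unrestricted:
the quantity is "attraction toward the full type-$j$ population, as seen
from type-$i$ cells residing in the neighborhood". Restricting targets
too is an equally defensible reading of a within-neighborhood analysis;
conditioning only the focal cell is the implemented interpretation and
the restriction is vacuous when membership is universal (a tested
identity).

# Compositional comparison

Proportion-valued features are compared between two cohorts by beta
regression: $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
$\mathrm{logit}(\mu) = \beta_0 + \beta_1\,\mathrm{group}$ and a single
precision $\phi$ (no precision covariates — the minimal model). The group
coefficient $\beta_1$ is the change in log-odds of the mean proportion.

Numerical choices:

* **Boundary handling.** The beta likelihood is undefined at 0/1, and
  image-level proportions are frequently exactly 0. The compression
  $y' = (y(n-1) + 0.5)/n$ is applied to *all* values (not just
  boundaries) so the estimator is continuous in the data.
* **Optimization.** Quasi-Newton (BFGS) on $(\beta, \log\phi)$ with
  analytic gradients; starting values from least squares on
  $\mathrm{logit}(y)$ and moment-matched $\phi$; relative tolerance
  10⁻¹², with the convergence flag additionally requiring a
  positive-definite observed information and a small scaled gradient
  norm. Standard errors are the inverse observed information; Wald z
  tests per coefficient.
* **Exclusions.** A feature with zero variance within either cohort is
  skipped with a logged reason (the model is degenerate there), as are
  non-converged fits; both are excluded from the FDR family.

`compare_cohorts()` runs one fit per feature and applies
Benjamini-Hochberg adjustment **within one call** — one FDR family per
result table (cell types; neighborhoods; each nested-fraction view),
mirroring per-figure correction. Significance tiers are `*`/`**`/`***`
at q < 0.05/0.01/0.001. Each image is one observation; patients with two
cores contribute two images, the caveat being that the compositional
models (unlike the survival models) carry no within-patient correlation
adjustment — proportions are reported "per image" and modeled as such.

# Survival models

`km_estimate()` wraps the product-limit estimator with Greenwood variance
and log-log confidence intervals; the median is the earliest time the
curve reaches 0.5 (missing when never reached), and survival at fixed
horizons (defaults 60 and 120 months) is reported. `logrank_test()` is
the standard two-or-more-sample log-rank.

`fit_cox_univariate()` fits a univariate Cox proportional-hazards model
by partial likelihood (Efron tie handling by default) with a
**cluster-robust sandwich variance**: score residuals are summed within
clusters (patients) before the outer product, so patients contributing
several cores do not masquerade as independent observations. With
singleton clusters this reduces to the ordinary robust variance. One
subtlety: duplicating every record within its cluster leaves the log-HR
and the cluster-robust SE *exactly* unchanged under Breslow tie handling,
while the naive SE shrinks spuriously; under Efron the invariance is
approximate because the duplication itself creates tied event times. The
`ties` argument exposes both; validation checks the exact identity under
Breslow and bounds the Efron perturbation.

`spatial_survival_scan()` fits one clustered univariate Cox model per
spatial feature (G-cross evaluations at fixed radii, or the AUC feature
for organ-stratified scans), per optional stratum. Features enter
untransformed (G estimates in [0, 1], AUC in µm); samples with an
undefined feature are dropped per fit, never imputed; strata with fewer
than two events or a constant feature are skipped with a reason. Raw
p-value tiers are reported by default — scan heatmaps conventionally show
unadjusted tiers — with BH adjustment available via `adjust = TRUE`.

# The synthetic-cohort generator

No spatial model of real melanoma tissue is estimated or claimed; the
generator's distributions are design choices whose purpose is a known,
recoverable ground truth.

* **Background**: each type is a homogeneous Poisson process
  (`simulate_poisson_multitype()`); counts are Poisson(density × area),
  coordinates uniform. This makes the G-cross closed form exact for
  independent pairs.
* **Attraction**: a parent-offspring cluster process
  (`simulate_attraction()`): offspring counts Poisson per parent,
  displacements isotropic Gaussian with scale σ. Offspring falling
  outside the window are **re-drawn, not clipped** — clipping piles mass
  on the boundary and corrupts edge-correction tests. Within
  `generate_cohort()`, attraction rules attach offspring to
  already-generated background parents, so a type's total intensity is
  background plus clustered surplus.
* **Markers**: log-normal intensities (strictly positive, multiplicative
  noise typical of fluorescence/ion counts) with median `high` (default
  50) for expressed and `low` (default 1) for unexpressed markers and
  shared `sdlog` (default 0.25, giving >99% recovery by default
  thresholds; recovery degrades monotonically as the separation
  shrinks — a tested property). Inflammatory-marker positivity is an
  independent per-cell Bernoulli per marker (per-marker rates generate
  all seven combination neighborhoods consistently), optionally
  restricted to a sub-window for spatially coherent neighborhoods.
* **Survival**: patient-level features are the mean of per-sample
  features; event times are exponential with rate
  $\lambda_0\exp(\sum_k \beta_k f_k)$, censoring independent exponential.
  Clustering in the data arises from repeated cores per patient, not
  from a frailty term, so the configured coefficients are exactly the
  log-HRs a correctly specified Cox model should recover. Linked
  features are named `prop_<type>`, `<i>_<j>_G<r>`, or `<i>_<j>_AUC` and
  are computed from the generated cells themselves with the default
  (border-corrected) estimator, so generator and analysis measure the
  same quantity.
* **Heterogeneity**: optional per-patient density ranges
  (`density_ranges`) draw a type's density uniformly per patient (shared
  across that patient's cores). This emulates between-patient variation
  in infiltration and is what gives spatial features patient-level
  variance; with homogeneous densities, $\hat G$ varies only by counting
  noise (SD ≈ 0.02 at the default core sizes) and no survival linkage is
  detectable at realistic cohort sizes. The validation experiments that
  recover a hazard loaded on $\hat G_{\mathrm{CTL},\mathrm{Tumor}}(40)$
  use tumor-density ranges wide enough for a feature SD of ≈ 0.2 and
  light censoring (≈ 340 events at n = 400), which at coefficient −1
  puts the expected Wald statistic near 3.7 — adequate power by design
  rather than by tuning.

Study-scale defaults (`default_simulation_config()`) mirror a two-cohort
design: a regional-disease arm of 157 patients × 2 cores and a
metastatic arm of 248 patients contributing 393 cores (145 patients with
two, 103 with one) across five metastatic-site strata (other 35%, skin
20%, GI 17%, lung 16%, lymph node 12%). Default densities give ≈ 1,900
cells per 1 mm² core; the metastatic arm raises Tumor and CTL and lowers
B, NK and double-negative T densities, and shifts inflammatory-marker
rates toward CD74/MIF-defined neighborhoods and away from iNOS-defined
ones, reproducing the direction of the advanced-stage shifts the
comparison stage is meant to detect.

**What synthetic validation shows — and does not.** Passing tests
establish that the estimators measure what they claim on data whose
generating process is known: Poisson-law counts, closed-form G-cross
agreement, oracle-exact estimators, calibrated regression recovery, and
end-to-end sign recovery of a planted hazard. They do not establish that
real tissue follows these models: real cores exhibit tissue architecture
(tumor nests, stromal tracts), inhomogeneous intensities, segmentation
error and marker spillover, none of which the generator emulates (and
inhomogeneous point processes are explicitly out of scope). Results on
real data inherit the usual caveats of threshold gating and of the
chosen edge correction.

# Problem sizes used in validation

Validation experiments are sized to be decisive yet quick: 200-replicate
Monte-Carlo envelopes for the Poisson null; 100 random instances (n ≤
500) for oracle equality; 100 replicates at n = 500/group for
beta-regression coverage; 1,000 random vectors for the BH oracle;
n = 1,000 patients for Cox recovery; 50 replicates of a 400-patient
cohort for the end-to-end scan; 200 label permutations for null
calibration of the cohort comparison. The demo pipeline uses reduced
patient counts and 40% densities so a full run completes in seconds.

# Known limitations

* Single fixed threshold per marker; no per-image normalization or
  learned gating (an Otsu-style option was considered and deferred —
  fixed thresholds keep the synthetic ground truth exactly recoverable).
* Border correction only (plus raw); other edge corrections may be
  needed to match analyses that used a different estimator.
* Beta regression has no covariates beyond cohort and no
  zero-inflation; compositional models treat images as independent.
* No multivariable or penalized Cox, no time-varying covariates.
* The generator produces stationary patterns only; no pixel-level image
  synthesis or segmentation simulation.
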