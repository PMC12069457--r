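# timescape

Spatial analysis of the tumor immune microenvironment (TIME) from
cell-level multiplex imaging data.

Multiplex imaging (imaging mass cytometry, multiplex immunofluorescence)
yields tables with one row per segmented cell: coordinates within a tissue
core (typically a 1 × 1 mm region of interest), per-marker intensities,
and — after gating — a phenotype. `timescape` is for researchers who want
to go from such tables, plus a per-patient clinical table, to a
quantitative picture of how immune and tumor cells are composed, how they
organize around inflammatory signaling hubs, how strongly cell types
attract one another in space, and whether any of that predicts survival.

## What it computes

**Phenotyping.** Intensity-threshold gating with a priority hierarchy
(subtypes such as CD3+CD8+ cytotoxic T cells pre-empt the generic CD3+
T-cell rule while still counting in the parent population), plus the
H-score

&nbsp;&nbsp;&nbsp;&nbsp;H = (% of 1+ cells)·1 + (% of 2+ cells)·2 + (% of 3+ cells)·3 ∈ [0, 300].

**Inflammatory neighborhoods.** For a marker combination (e.g. CD74 MIF),
every combination-positive cell is an anchor and its neighborhood is the
union of discs of radius R (20–80 µm, default 40) around anchors. Three
per-sample proportion views: neighborhood prevalence, cell types within a
neighborhood, and neighborhoods within a cell type.

**G-cross statistics.** The cross-type nearest-neighbor distance function
G<sub>i,j</sub>(r) — the CDF of the distance from a typical type-i cell
to its nearest type-j cell — estimated raw or with border (reduced-sample)
edge correction, against the homogeneous-Poisson baseline

&nbsp;&nbsp;&nbsp;&nbsp;G<sub>i,j</sub>(r) = 1 − exp(−α<sub>j</sub> π r²),

where α<sub>j</sub> is the target type's density. Fixed-radius
evaluations (20/40/60/80 µm) and the trapezoidal AUC serve as per-sample
spatial features.

**Cohort comparison.** Beta regression (logit mean link, single precision
φ) per proportion feature with Benjamini–Hochberg FDR per result family;
zero-variance features are excluded with a logged reason.

**Survival.** Kaplan–Meier (log-log CIs, fixed-horizon survival),
log-rank tests, and univariate Cox models with cluster-robust sandwich
variance (score residuals aggregated within patients, so repeated cores
are handled honestly). `spatial_survival_scan()` fits one clustered Cox
model per spatial feature, optionally per metastatic-site stratum.

**Synthetic cohorts.** `generate_cohort()` produces cell and clinical
tables with known ground truth — Poisson backgrounds, parent–offspring
attraction, log-normal marker signals, exponential survival linked to
configured features — at study scale (157 patients × 2 cores; 248
patients / 393 cores across 5 metastatic sites) or any smaller size.

## Worked example

Simulate a two-arm cohort, phenotype it, compare compositions, and scan a
spatial feature against survival:

```r
library(timescape)

cfg3 <- simulation_config(n_patients = 40, cores_per_patient = 2, stage = "III",
                          type_intensities = default_type_intensities("III") * 0.4,
                          seed = 10)
cfg4 <- simulation_config(n_patients = 40, cores_per_patient = 2, stage = "IV",
                          type_intensities = default_type_intensities("IV") * 0.4,
                          seed = 11)
a <- generate_cohort(cfg3); b <- generate_cohort(cfg4)
cells <- rbind(a$cells, b$cells); cells$cell_id <- seq_len(nrow(cells))
clinical <- rbind(a$clinical, b$clinical)

cells <- classify_cells(cells)
props <- cell_type_proportions(cells)
groups <- data.frame(sample_id = unique(cells$sample_id))
groups$group <- ifelse(grepl("^IV", groups$sample_id), "IV", "III")
compare_cohorts(props, groups, family = "cell_types")
```

```
  feature    beta     se         p         q tier
1       B -0.6182 0.0264 4.61e-121 1.84e-120  ***
2     CTL  0.2892 0.0210  3.67e-43  7.34e-43  ***
...
8   Tumor  0.4649 0.0110  0.00e+00  0.00e+00  ***
```

Each `beta` is the change in log-odds of that type's per-image proportion
in the IV arm relative to III — positive for Tumor and CTL, negative for
B and NK, matching the configured stage shift; `q` is the BH-adjusted
p-value and the tier marks q < 0.05/0.01/0.001.

```r
g <- gcross_empirical(cells[cells$sample_id == cells$sample_id[1], ],
                      "CTL", "Tumor")
g
#> G-cross curve  CTL -> Tumor  (border estimator)
#>   n_i = 62 reference cells, n_j = 247 target cells, alpha_j = 0.000247 /um^2
#>   radius grid: 0..80 um (81 points), 0 undefined
gcross_at(g, 40)   # 0.667: two-thirds of CTLs have a tumor cell within 40 um
gcross_auc(g)      # 47.1 um: area under the curve up to 80 um

ft <- gcross_features(cells, list(c("CTL", "Tumor")))
spatial_survival_scan(ft, clinical)
#>         feature log_hr se_robust     p tier   n n_clusters
#> 2 CTL_Tumor_G40 0.4805    1.0786 0.656      160         80
#> ...
```

The scan reports a cluster-robust log hazard ratio per feature (here not
significant — this cohort's hazard was not linked to any spatial
feature). `km_estimate(clinical$time_months, clinical$event)` prints the
median survival (28.7 months, 95% CI 19.9–38.6 for this cohort) and
fixed-horizon survival probabilities.

The full pipeline — simulate → phenotype → neighborhoods → G-cross →
compare → survive, with a run manifest and byte-stable CSV outputs — runs
via `run_pipeline(demo_pipeline_config(seed = 1), "out/")`, or from a
shell via `Rscript inst/scripts/timescape.R run --out out/ --seed 1`.

## Documentation

The methods vignette (`vignettes/spatial-immune-landscape.Rmd`) documents
the models, defaults, numerical choices, the synthetic-data design, and
known limitations. Every exported function carries roxygen documentation.
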