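# vegfsema

Angiogenesis-related gene-expression subtyping of breast tumors.

Breast cancers — triple-negative tumors (TNBC) in particular — differ
widely in how they regulate angiogenesis. Two ligand families compete for
the neuropilin co-receptors on endothelial cells: the VEGFs (VEGFA-D,
PlGF, signaling through VEGFR1-3) promote vessel growth, while the
secreted class-3 semaphorins (signaling through plexins) generally inhibit
it. `vegfsema` analyses log2 expression of a 31-gene VEGF/semaphorin panel
across a tumor cohort to find, classify and prognosticate these
angiogenesis subgroups. It is written for computational biologists who
have a genes x samples expression matrix (TSV) plus a clinical annotation
table and want the full analysis chain with every step testable.

## What it computes

* **Receptor status**: triple-negative calling from ESR1/PGR/ERBB2
  expression where IHC is missing, via class-conditional trivariate
  Gaussians — posterior `p(TN|x) = pi phi_TN(x) / (pi phi_TN(x) +
  (1-pi) phi_RP(x))`.
* **Subtype classification**: nearest-centroid with Spearman correlation
  and an unclassified cutoff at rho < 0.1; LOOCV evaluation.
* **Differential expression**: per-gene Wilcoxon rank-sum (exact when the
  pooled n is at most 20 and tie-free), log2 ratio of linear-scale means
  with 99% Hodges-Lehmann intervals.
* **PCA signatures**: component scores/loadings over the panel with a
  deterministic sign convention; logistic regression of clinical variables
  on the first eight scores; Wilks' lambda MANOVA on score planes.
* **Consensus clustering**: best-of-50-restart K-means on 100 random 80%
  subsamples; consensus matrix, CDF-area table across K, cluster labels;
  complete-linkage gene ordering for heatmaps.
* **Survival**: Kaplan-Meier, log-rank, and univariate + multivariate Cox
  tables (hazard ratios with Wald p), with median-dichotomized signature
  scores.
* **Synthetic cohorts**: a generator planting known clusters, bimodal
  receptor mixtures, and proportional-hazards survival, so the whole
  pipeline runs and is validated without external data.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort of 800 tumors and 40 normals (seeded, fully reproducible), writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_receptor_status.R
# ... through 07_survival.R
```

`02_receptor_status.R` prints:

```
TN calls: 559/800 by IHC, 241 by model
misclassification vs truth: 4.00% (32/800)
```

559 tumors had decisive IHC; the Gaussian model called the remaining 241,
and overall 4% of calls disagree with the generator's planted status —
the scale of discordance expected when IHC itself carries a 2% error rate.
`03_subtype_loocv.R` reports the centroid classifier at `LOOCV accuracy:
97.1% (777/800)` over the seven planted clusters. `06_consensus_clusters.R`
prints the per-K consensus CDF areas and then

```
k = 7: ARI vs planted clusters = 0.963
modal capture per planted cluster (%):
    A     B     C     D     E     F     G
100.0 100.0 100.0 100.0  99.0  94.4  95.1
```

i.e. at the planted K the consensus labels recover the true clusters
almost exactly (adjusted Rand index 0.96). `07_survival.R` ends with the
prognostic table and

```
log-rank TN vs RP: chi2 = 75.6, p = 3.5e-18
planted signature log-HR: estimated -0.94 (truth -0.70), HR per SD 0.39
```

the planted protective signature (high semaphorin-3 / low VEGFA
expression axis) is recovered as an independent prognostic factor next to
TN status, stage and nodal status.

Programmatic use mirrors the scripts:

```r
library(vegfsema)
cohort <- generate_cohort(cohort_config(seed = 1))
calls  <- call_tn_status(cohort$expression, cohort$annotation[cohort$annotation$group == "tumor", ])
pca    <- fit_pca(subset_panel(cohort$expression), label_suffix = "a")
```

or run everything at once with `run_pipeline(pipeline_config(seed = 1))`.

## Layout

```
R/                  package implementation (all computation lives here)
analysis/           numbered driver scripts for the full study
scripts/acceptance.R  headline-quantity reproduction script
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, parameters, design choices)
```
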