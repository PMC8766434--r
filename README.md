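# ibctx — comparative transcriptomics of inflammatory breast cancer models

Inflammatory breast cancer (IBC) is an aggressive, clinically diagnosed
breast cancer phenotype studied through a small panel of preclinical cell
line and xenograft models, virtually all ER-negative and basal-like. A
central analytical question is how faithfully those models recapitulate
the disease seen in patients, and which transcriptional programs — cell
proliferation, MYC activity, TNFα/NFκB signaling, and ER-dependent
interactions among them — define IBC biology.

`ibctx` packages the analysis machinery for that question as a set of
tested, reusable R functions, aimed at computational biologists working
with multi-batch expression compendia of cell-line models plus patient
cohorts:

* **Preprocessing** — expression filtering, empirical-Bayes location/scale
  batch correction with protected covariates, quantile normalization,
  probe collapsing by maximal SD, replicate averaging, in a fixed chain
  (`preprocess_pipeline()`).
* **Unsupervised analysis** — Manhattan/Ward clustering of the most
  variable genes, cluster-number voting over eight validity indices,
  Fisher/chi-square association of clusters with annotations, multinomial
  AIC/likelihood-ratio comparison of predictors.
* **IBC classification** — an elastic-net logistic classifier over a gene
  signature, tuned by repeated cross-validated AUROC over an α/λ grid,
  with replicate-median posterior calls, confusion statistics and
  McNemar's test; a generic nearest-centroid caller for user-supplied
  subtype centroids.
* **Differential expression** — a moderated two-group t with empirical-
  Bayes variance shrinkage (moment-matched prior df), BH control, and a
  percentile-based paired comparison (97.5th/2.5th cuts of gene-wise
  differences).
* **Co-expression networks** — biweight midcorrelation, signed
  soft-threshold selection for scale-free topology, topological overlap,
  adaptive module detection with eigengene refinement and merging, GMM
  (gene-module-membership) scores, and permutation-based module
  preservation with the <2 / 2–10 / >10 Z-score bands.
* **Prioritization** — dichotomized module/cell-line graphs and a
  deterministic minimum-spanning-tree extraction of the minimal module set
  connecting target cell lines.
* **Connectivity screening** — 150-up/150-down GMM marker queries scored
  against ranked perturbation signatures by a weighted-KS connectivity
  score in [−100, 100], with the ≥75 / ≤−75 regulator rule and the
  strict drug/target rule.
* **Enrichment and activity** — preranked weighted-KS GSEA with
  permutation NES/p, hypergeometric over-representation, and a closed-form
  rank-sum single-sample activity score; GMT readers/writers.
* **The nested interaction model** — MYC expression or activity regressed
  on a five-indicator ER-by-phenotype design (reference nIBC/ER-low, IBC
  ER effects coded as increments over IBC/ER-low), with blocking-variable
  sensitivity analysis, proximal-MYC-network correlation reports and
  90th-percentile outlier flags.
* **Synthetic data** — generators for a multi-batch cell-line compendium
  with planted co-expression modules, an L1000-like perturbation catalog
  with planted regulators and drug/target pairs, and an IBC/nIBC patient
  cohort with ER-stratum-dependent MYC effects, so that the whole pipeline
  is testable without access to restricted data.

The methods vignette (`vignettes/ibctx-methods.Rmd`) documents the models,
parameters and design decisions in detail.

## A worked example

Generate a 32-model compendium (10 IBC, 22 nIBC, triplicates, 5 batches)
with three planted 150-gene modules, preprocess it, build the signed
co-expression network, and fit the patient-cohort interaction model:

```r
library(ibctx)

cp <- generate_cell_line_compendium(compendium_spec(
  n_genes = 600,
  modules = list(list(size = 150, effect_sd = 2, phenotype_link = "IBC"),
                 list(size = 150, effect_sd = 2, phenotype_link = "nIBC"),
                 list(size = 150, effect_sd = 2, phenotype_link = "none")),
  n_cell_lines_ibc = 10, n_cell_lines_nibc = 22, seed = 1))
cp
#> expression_compendium: 600 genes x 96 profiles (32 cell lines, 5 batches)

pp <- preprocess_pipeline(cp, threshold = -Inf)   # filter/ComBat-style/QN/average
dim(pp$values)
#> [1] 600  32

r <- bicor(pp$replicate_values)
params <- pick_soft_threshold(r, candidates = 1:12)
params$power
#> [1] 8

net <- tom(((1 + r) / 2)^params$power)
modules <- detect_modules(net$dissimilarity, min_size = 100,
                          values = pp$replicate_values)
modules
#> module_assignment: 3 modules (sizes 140, 138, 133), 189 unassigned

gm <- module_eigengene(pp$replicate_values, modules)
round(cor(gm$eigengenes), 2)
#>       M1    M2    M3
#> M1  1.00 -0.66 -0.39
#> M2 -0.66  1.00 -0.38
#> M3 -0.38 -0.38  1.00
```

The three planted modules are recovered (sizes 140/138/133 of 150 planted
genes each; the unassigned set holds the 150 background genes plus
low-membership members), and the IBC-linked and nIBC-linked module
eigengenes are anti-correlated (−0.66), as their phenotype-linked latent
factors imply.

On the patient side, a default synthetic cohort (146 IBC, 252 nIBC) is
generated with ER-stratum-dependent MYC effects, and the nested
interaction model estimates them:

```r
co <- generate_patient_cohort(cohort_spec(seed = 1))
fit <- fit_nested_interaction(co$MYC, co$phenotype, co$er_stratum)
fit
#> nested ER-by-phenotype interaction fit (reference nIBC/ER-low)
#>               estimate        se            p
#> nIBC:ERmod  -0.8924663 0.1551704 1.782685e-08
#> nIBC:ERhigh -1.2107323 0.1551704 5.561712e-14
#> IBC:ERlow   -1.0714714 0.1807680 6.753986e-09
#> IBC:ERmod    0.7145468 0.2042211 5.208163e-04
#> IBC:ERhigh   1.7287887 0.2031657 3.755230e-16
```

Each row is the change in MYC expression (log2 units) for that
phenotype-by-ER-stratum cell relative to nIBC samples with low ER
expression (IBC ER-moderate/high rows are increments over IBC ER-low).
At this seed the estimates scatter around the generator's planted effects
(−0.754, −0.931, −0.832, +0.599, +1.414) within about one to two standard
errors: MYC falls with rising ER in nIBC and rises with ER within IBC —
the opposed ER–MYC patterns the model is designed to expose.

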