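# sarcoproteo

Proteomic subtyping and prognostic modelling for soft-tissue sarcoma
cohorts — a tested, reusable R implementation of the analysis pipeline used
for large multiplexed (TMT) tumour proteomes, from raw per-plex intensity
matrices to survival-stratified co-expression modules.

Soft-tissue sarcomas are rare, heterogeneous tumours; proteomic profiling of
archival (FFPE) material, quantified in 11-plex batches with a pooled
reference channel, can resolve molecular subtypes and prognostic programs
that histology alone does not. The statistical machinery behind such a study
is substantial, and most of it is usually locked inside ad-hoc scripts. This
package provides that machinery as documented, unit-tested functions:

* **Preprocessing** — pooled-reference ratio normalisation
  (sample/reference → log2 → per-protein median centring → per-sample
  standardisation), ≥75% completeness filtering, k-nearest-neighbour
  imputation, TIL-density arithmetic (area correction, ×1.274 field
  conversion, median stratification).
* **Subtype discovery** — resampling consensus clustering (80% item and
  feature resampling, hierarchical or k-means base, CDF/delta-area and
  silhouette model selection), SigClust significance with hard-thresholded
  Gaussian nulls, and Monte-Carlo-null consensus (PAC-based relative
  cluster-stability scores).
* **Markers and panels** — two-class SAM (t or moderated d statistic,
  permutation FDR, fold-change filter; subtype-unique marker calling) and
  nearest-shrunken-centroid (PAM) panel reduction with stratified
  cross-validation and centroid transfer to external cohorts.
* **Co-expression modules** — signed-hybrid adjacency (`cor^β`, β = 5),
  topological overlap, dynamic tree cutting (modules ≥ 30 proteins),
  eigengene merging at 0.25, median module scores with tertile strata, and
  thresholded edge-list export.
* **Gene-set scoring** — ssGSEA (rank normalisation, exponent 0.75),
  pre-ranked GSEA (weighted KS running sum, set sizes 9–501), and
  hypergeometric overrepresentation with BH adjustment; GMT I/O.
* **Survival** — LRFS/MFS/OS endpoint construction with 5-year
  administrative capping, Kaplan–Meier/log-rank and Cox models (via the
  `survival` package), per-SD hazard-ratio screening (HR > 2.0 or < 0.5),
  martingale-residual cutpoints, and the likelihood-ratio prognostic-gain
  statistic `gain% = 100·Δχ²/χ²_base`.
* **Proteome–transcriptome concordance** — per-gene Spearman correlation
  classes at FDR 0.05, dual-layer hazard comparison with triple-endpoint
  overlap and opposing-direction detection.
* **Synthetic cohorts** — a generator with planted subtype shifts,
  correlated modules (exact within-module correlation targets), batch
  effects, abundance-dependent missingness, proportional-hazards survival
  and a Spearman-controlled paired transcriptome, so every claim above is
  verifiable against known ground truth.

## Worked example

Simulate a 120-sample, 3-subtype cohort in 10-sample plexes, normalise it,
discover subtypes, reduce a marker panel, and test a module score against
overall survival:

```r
library(sarcoproteo)

cfg <- cohort_config(n_samples = 120, n_proteins = 400, n_subtypes = 3,
                     subtype_effect = 1.2, n_marker_proteins_per_subtype = 40,
                     module_sizes = c(50, 50), missing_rate = 0.1,
                     mnar_strength = 1, survival_betas = c(module1 = 0.7),
                     seed = 42)
sim  <- generate_raw_plexes(cfg)
norm <- reference_ratio_normalize(sim$raw, min_frac = 0.75, impute_k = 10)
dim(norm)                              # 399 proteins x 120 samples

cons <- run_consensus(norm, k_range = 2:5, reps = 200, seed = 1)
sel  <- evaluate_k(cons, norm)
sel$chosen_k                           # 3
adjusted_rand_index(sel$labels,
                    sim$truth$subtype_labels[names(sel$labels)])  # 1
sigclust(norm, sel$labels, n_sim = 1000, seed = 2)$p              # 0.000999

model <- pam_train(norm, factor(sel$labels), seed = 3)
length(model$retained)                 # 101 proteins
model$cv_error_star                    # 0

clin   <- simulate_survival(sim$truth, cfg)
rec    <- build_endpoints(clin)        # LRFS/MFS/OS, capped at 5 years
os     <- rec[rec$endpoint == "OS", ]
memb   <- setNames(ifelse(is.na(sim$truth$module_membership), "ungrouped",
                          paste0("M", sim$truth$module_membership)),
                   names(sim$truth$module_membership))
score  <- module_score(norm, memb, "M1")
strata <- tertile_stratify(score[os$sample])
hl     <- strata %in% c("high", "low")
cox_fit(os[hl, ], data.frame(high = as.numeric(strata[hl] == "high")))
```

The run above prints a chosen k of 3 with adjusted Rand index 1 against the
planted subtypes, a SigClust maximum pairwise p of 0.000999 (the smallest
value 1000 null simulations can produce), a 101-protein shrunken-centroid
panel at zero cross-validated error, and — because module M1 carries a
planted log-hazard of 0.7 per latent-factor SD — a high-vs-low tertile
hazard ratio of

```
HR 7.25 (95% CI 3.48-15.14), p = 1.3e-07
```

i.e. samples in the top expression tertile of the planted module die
substantially faster, exactly as simulated.

A configuration-driven run of the same stages (with a JSON manifest of
parameters, seeds and output hashes) is available through `run_pipeline()`;
see `?run_pipeline`.

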