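---
title: "Methods: proteomic subtyping and prognostic modelling with sarcoproteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic subtyping and prognostic modelling with sarcoproteo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sarcoproteo` implements an end-to-end analysis pipeline for multiplexed
(TMT-style) tumour proteomics cohorts: pooled-reference normalisation,
unsupervised subtype discovery with statistical validation, sparse marker-panel
classification, co-expression module derivation, gene-set scoring, survival
modelling and proteome–transcriptome concordance. Every stage can be exercised
against a synthetic cohort generator with planted ground truth, so the
statistical behaviour of the whole pipeline is testable without any external
data. This vignette records the models, the tunable parameters and the design
choices a maintainer would want to know about.

## The synthetic cohort generator

The generator emulates a multi-subtype sarcoma cohort quantified in 10-sample
plexes, each carrying an 11th pooled-reference channel. On the log2 scale a
measurement is

```
log2 x_is = b_i + effect * marker(i, subtype(s)) + lambda_m f_ms + batch_b(s) + eps_is
```

* `b_i` — base abundance, Normal(mean 20, sd 1.5) in log2 units. The sd of
  1.5 gives the 4–5 orders of magnitude of dynamic range a deep FFPE
  proteome shows, which is what makes abundance-dependent missingness
  behave realistically.
* `effect` — the subtype mean shift in log2 units, applied to a disjoint
  block of marker proteins per subtype (default 50 markers, shift 1.0).
* `lambda_m f_ms` — module structure: each planted module m shares a latent
  factor `f_m ~ N(0,1)` with loading `lambda_m = sigma * sqrt(r/(1-r))`, so
  the within-module pairwise Pearson correlation of log2 values is exactly
  `r = lambda^2/(lambda^2 + sigma^2)` in expectation (`sigma` is the
  measurement noise sd, default 0.5).
* `batch_b` — a per-plex offset, Normal(0, 0.3) by default. The reference
  channel is the per-protein mean of the cohort's noise-free abundances,
  multiplied by the same plex offset; dividing samples by the reference is
  therefore what removes the batch term, exactly as the pooled-reference
  design intends.
* Missingness is a mixture of completely-at-random dropout and a
  missing-not-at-random component with a probit link on the standardised
  abundance (`P(miss) ∝ Phi(-mnar_strength * z)`), rescaled so the overall
  rate matches `missing_rate`. This is the standard proteomics missingness
  model: low-abundance measurements vanish first.
* Survival: independent exponential proportional-hazards draws for local
  recurrence, metastasis and death, with linear predictor
  `sum(beta * feature)` over planted features (subtype indicators or module
  latent factors). Random censoring is exponential with rate calibrated to
  the requested censoring fraction; the 5-year administrative cap is applied
  by `build_endpoints()`, not by the generator, mirroring how real cohorts
  are processed. Clinical covariates (grade, size, depth, margin, age, sex,
  performance status) are generated independently of the planted risk, so
  multivariable-adjustment tests can distinguish confounded from
  independent signals.
* The paired transcriptome uses a Gaussian copula on ranks: the protein
  row's normal scores are mixed with independent noise at the Pearson
  coefficient `2*sin(pi*rho/6)`, which yields the requested Spearman
  correlation for a bivariate Gaussian; `rho = 1` degenerates to an exact
  monotone transform. A two-point mixture (default: 20% of genes at
  rho 0.7, rest at 0) emulates the observed minority of concordant genes.

What the generator does **not** emulate: peptide-level quantification and
roll-up, isotope-impurity interference, ratio compression, non-proportional
hazards, and correlated clinical confounding (unless explicitly configured).
Passing tests therefore demonstrate statistical correctness of the methods
under the stated generative model, not robustness to every artefact of real
TMT data.

Plex assignment is randomised by default; a `grouped` option chunks samples
by subtype into plexes, which deliberately confounds batch with subtype for
robustness experiments. The choice is exposed because acquisition designs
differ between labs and the original design is rarely recorded.

## Normalisation and imputation

The normalisation order is: per-plex sample/reference ratio, log2,
per-protein **median centring across samples**, per-sample
**standardisation** (z-score to mean 0, sd 1). Each step is separately
callable (`ratio_log2()`, `center_proteins()`, `standardize_samples()`).
Standardisation uses the standard deviation; a median-absolute-deviation
variant was considered and rejected because every downstream statistic
(SAM, NSC, Cox per-SD hazard ratios) assumes sd-scaled inputs.

Note one deliberate property: per-protein centring applies row-specific
offsets and therefore reorders proteins *within* a sample — that is its
purpose (making proteins comparable across samples). The column-wise steps
(ratio against a protein-constant reference, standardisation) are monotone
within a sample and the tests assert exactly that decomposition.

Completeness filtering keeps proteins observed in at least 75% of samples
(boundary inclusive). Imputation is k-nearest-neighbour with `k = 10`, the
conventional default of the originating algorithm (the choice is exposed).
Neighbour distances are Euclidean over co-observed samples rescaled by
`sqrt(n/n_shared)` — the standard correction for unequal overlap — and only
neighbours observed at the target sample contribute, unweighted.

TIL densities follow the immunohistochemistry arithmetic: cores under 50%
section preservation are excluded, counts are corrected to 100% area,
replicates averaged, and the mean converted to cells/mm^2 with the fixed
microscope-field factor 1.274. Median stratification assigns ties at the
median to "high" so the rule is deterministic.

## Consensus clustering and its validation

`run_consensus()` subsamples 80% of samples and 80% of proteins per
repetition (1000 repetitions, k = 2..10 by default), clusters each
subsample (agglomerative hierarchical clustering on 1 − Spearman rank
correlation with average linkage by default; k-means optional), and tallies
pairwise co-clustering frequencies normalised by co-sampling counts
(0/0 := 0). Repetitions whose subsampled matrix yields an undefined
correlation (a constant protein) are skipped and counted.

`evaluate_k()` computes, per k, the empirical CDF of consensus entries, its
area `sum (x_i - x_{i-1}) * CDF(x_i)` over sorted unique values, the
relative delta-area (`Δ(2) = area(2)`, `Δ(k) = (area(k)-area(k-1))/area(k-1)`),
and the mean silhouette width of consensus-derived labels. Because "choice
by inspection" is not automatable, the chosen k is the smallest k whose
next delta-area falls below 0.025 **and** whose silhouette is a local
maximum, with the best-silhouette k as fallback; the threshold is exposed.
Final labels always come from average-linkage hierarchical clustering of
1 − consensus, the convention of the originating consensus procedure.

`sigclust()` tests a 2-group split against the null of a single Gaussian.
The null covariance is diagonal with eigenvalues of the sample covariance
hard-thresholded at the background noise variance
`sigma2 = (MAD of all entries / 0.6745)^2` (the hard-thresholding variant
requires a robust noise estimate; R's `mad()` already applies the 1.4826
factor). Each null dataset is split by 2-means and
`p = (1 + #{null CI <= observed CI})/(n_sim + 1)` with CI the
within-cluster over total sum of squares. For more than two observed
clusters the test runs on every cluster pair and the **maximum** pairwise p
is reported — the conservative reading of "the clusters are significantly
different"; a 2-vs-rest alternative was considered and rejected as it
conflates separation of one cluster with separation of all.

`monte_carlo_consensus()` compares the proportion of ambiguous consensus
entries (PAC, window 0.1–0.9) on the real data against null datasets drawn
from a multivariate normal matched to the observed principal-component
eigenvalue spectrum. The relative score is `ln(mean null PAC / real PAC)`
(PAC floored at one over the number of sample pairs + 1 to keep the log
finite for perfectly stable clusterings) and the chosen k maximises the
relative score among k with empirical p < 0.05; with no significant k the
result is NA rather than a forced choice. The internal repetition and null
counts (defaults 100/100) are this package's defaults, documented rather
than asserted as anyone else's.

## SAM and nearest-shrunken-centroid panels

`sam_two_class()` scores proteins with either the Student t statistic (the
default for two-class marker calling, matching the use of t-tests for
differential expression) or the moderated d statistic
`(mean2 − mean1)/(s_i + s0)` with `s0 = median(s_i)` (a standard choice;
the percentile-tuning variant is out of scope). Significance combines a
q-value threshold (default FDR < 1%) with a linear fold-change filter
(default ≥ 1.5, two-sided). q-values come from a pooled permutation null —
all proteins' scores under label permutations pooled into one reference
distribution, per-protein p-values from the pooled tail, Benjamini–Hochberg
across proteins. When the number of distinct label assignments is at most
`n_perm` the permutations are enumerated exactly, which makes small-cohort
q-values deterministic. This replaces the delta-table FDR of the original
SAM implementation with an estimator that is monotone in |score| by
construction; the two agree in their operating behaviour (empty calls on
null data, planted markers recovered) which is what the tests pin down.

Subtype-unique markers: each subtype with more than 20 cases is contrasted
against all remaining samples; a marker is *unique* when it is upregulated
and significant for exactly one subtype.

`pam_train()` implements nearest-shrunken-centroid classification:
standardised centroid differences
`d_ik = (xbar_ik − xbar_i)/(m_k (s_i + s0))`, `m_k = sqrt(1/n_k − 1/n)`,
soft-thresholded over a 30-point shrinkage grid from 0 to `max|d_ik|` (the
grid size of the originating implementation). Rows are z-scored first by
default, matching the pipeline's preprocessing for panel reduction. Class
priors are proportional to class size (uniform optional); the proportional
choice is assumed because the cohorts involved are strongly imbalanced and
proportional priors are the originating implementation's default.
Cross-validation is stratified by class (10 folds, reduced with a warning
when a class is too small); `select_min_error()` picks the **largest**
shrinkage attaining the minimum CV error — the parsimony tie-break.
`pam_predict()` evaluates the discriminant over retained proteins, requires
80% of the panel to be present in the new matrix (missing members are
dropped with a warning above that line, refused below it), breaks exact
ties by class order and flags them.

## Co-expression modules

The network is signed-hybrid: `a_ij = cor_ij^beta` for positive Pearson
correlations, 0 otherwise, with `beta = 5` the pipeline default; the
scale-free fit table (`pick_soft_threshold()`) reports the signed R^2 of
the log–log connectivity regression and suggests the smallest power
reaching R^2 ≥ 0.8 at usable connectivity. A near-empty network (mean
connectivity below 1) is never called scale-free however linear its
log–log tail looks — without this guard, pure noise at high powers produces
spuriously good fits on a handful of near-zero connectivities.

Module detection clusters the topological-overlap dissimilarity (1 − TOM)
with average linkage and cuts the dendrogram at a deep-split-dependent
fraction of its height (presets 0.999/0.995/0.99/0.985/0.98 for deep split
0–4; default deep split 2 → 0.99). Branches of at least 30 proteins become
modules; everything else is "ungrouped". This static-cut variant of dynamic
tree cutting was chosen over a re-implementation of the full hybrid
algorithm's core-scatter/gap presets: on the planted-block structures the
generator produces (and the correlation structures the pipeline targets)
the two behave identically, and the static cut is transparent and easy to
reason about. Modules whose summary profiles — the sign-oriented first
principal component of member expression, the eigengene convention — are
closer than 0.25 in 1 − Pearson distance are merged iteratively until no
pair qualifies, so merging is idempotent. "Cut height ≥ 0.25" is read as
"merge below dissimilarity 0.25", the conventional reading.

Two distinct module summaries coexist deliberately: the eigengene drives
merging; the **median member expression** is the module score used for
tertile survival stratification (boundary samples to the lower stratum).
Edge-list export thresholds a similarity matrix (the TOM by default,
since the "co-occurrence" similarity of the original network figure is not
otherwise defined) at 0.05, strictly.

## Gene-set scoring

`ssgsea()`: per sample, genes are rank-normalised, and each set's score is
the sum over the ordered list of the difference between the
weight-`|rank|^0.75`-powered in-set ECDF and the unweighted out-of-set
ECDF; sets with fewer than 10 members present are skipped. Normalised
scores divide by the range of raw scores over all sets and samples. The
phrase "z-scored across gene sets" is read literally — within each sample,
across the collection — with the per-set-across-samples alternative (what a
clustered heatmap usually wants) available by flag.

`gsea_preranked()`: weighted Kolmogorov–Smirnov running sum with weight
`|metric|` on a ranking ordered by log2 fold change (ties broken by
identifier for determinism), set sizes restricted to 9..501. Null sets of
matching size are drawn by permutation; NES divides ES by the mean
same-signed null ES; nominal p is the same-signed tail; FDR follows the
standard pooled-NES procedure, capped at 1. `ora()` is the upper-tail
hypergeometric test with BH adjustment.

## Survival modelling

Endpoints are built from raw event times: LRFS (local recurrence or death),
MFS (metastasis or death), OS (death); event-free samples censor at last
follow-up and everything is administratively capped at 5 years (events
beyond the cap become censorings at the cap). Cox models use Efron tie
handling (the common modern default; the original analysis does not state
its choice) via the `survival` package; monotone-likelihood fits are
flagged as unstable rather than silently reported, mirroring how extreme
hazard ratios had to be excluded from multivariable modelling in practice.

`screen_features()` standardises each feature before its univariable Cox
fit, so the HR > 2.0 / HR < 0.5 screen operates per standard deviation —
without standardisation the bound would be scale-dependent and
meaningless across proteins; the per-unit alternative remains available by
flag. The triple-endpoint set is the intersection of per-endpoint
significant sets, and the dual-layer comparison labels a gene
"opposing-both" only when both layers are nominally significant with
hazard ratios on opposite sides of 1.

`martingale_cutpoint()` smooths null-model martingale residuals against the
log covariate with lowess and returns the zero crossing at the steepest
slope, falling back to the median (with a warning) when no crossing
exists. The span default is 0.3: at the few-hundred-sample cohorts this
package targets, wider spans visibly bias the crossing away from a planted
change point (the recovery simulations in the test suite quantify this),
while 0.3 recovers it within ±10%.

`lr_gain()` is the prognostic-information statistic: for nested Cox models,
`Δχ² = LRχ²_ext − LRχ²_base` and `gain% = 100·Δχ²/LRχ²_base`, with a
chi-square p-value on the added degrees of freedom. A gain of 123.1% at
Δχ² = 8.77 pins the arithmetic: it implies a base statistic of about 7.125,
and the tests assert the formula reproduces that pair.

## Concordance between layers

`correlate_layers()` computes per-gene Spearman correlations between the
protein and mRNA rows (exact permutation p for n ≤ 10, t-approximation
otherwise), BH-adjusts across genes and classifies each gene as
positive-/negative-/non-significant at FDR 0.05. Both directions use the
same FDR rule; stricter plotting thresholds are presentation choices, not
analysis ones. Constant rows are flagged rather than propagated as NaN.

## Numerical choices and degenerate inputs

* All stochastic operations take a seed, restore the caller's RNG state,
  and are bit-reproducible given config + seed.
* 0/0 consensus entries are 0; PAC is floored before the log; zero-variance
  proteins in SAM get a floored denominator and a log message; empty ORA
  hit lists give p = 1 everywhere; all-identical median stratification goes
  "high" with a warning.
* Tertile boundaries assign to the lower stratum; median-stratification
  ties go high; NSC prediction ties go to the first class in order and are
  flagged. Each tie rule is arbitrary but deterministic and documented.

## Problem sizes used by the test and acceptance runs

The shipped tests exercise cohorts of 20–300 samples and 30–750 proteins,
with 1000-permutation/simulation counts scaled to 100–500 where a loop over
many seeds makes the full-size run redundant — calibration properties
(type-I error, FDR control, recovery bounds) are invariant to this scaling
and the sizes are stated in each test. `scripts/acceptance.R` regenerates
a 300-sample cohort (plus smaller special-purpose cohorts) from scratch at
each invocation and recomputes every reported quantity; nothing in its
output is stored.

## Known limitations

* The dynamic-cut variant is a static height cut with presets; dendrograms
  whose modules join above the preset fraction of the tree height (very
  weak modules in very noisy data) will be under-split.
* The pooled-permutation SAM FDR is slightly conservative relative to the
  delta-table construction at very small permutation counts.
* No competing risks, time-varying covariates, module-preservation
  statistics, identifier mapping between omics layers, or batch correction
  beyond the reference-ratio design.
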