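Package: sarcoproteo
Title: Proteomic Subtyping and Prognostic Modelling for Soft-Tissue Sarcoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested implementation of a pan-sarcoma tandem-mass-tag (TMT)
    proteomic analysis pipeline: pooled-reference-channel normalisation,
    completeness filtering and k-nearest-neighbour imputation; resampling
    consensus clustering with delta-area/silhouette model selection, SigClust
    cluster significance and Monte-Carlo-null consensus;
    significance analysis of microarrays (SAM) differential abundance and
    nearest-shrunken-centroid (PAM) marker-panel reduction with
    cross-validation; signed-hybrid weighted co-expression networks with
    topological overlap, dynamic tree cutting and eigengene merging; per-sample
    gene-set enrichment (ssGSEA), pre-ranked GSEA and hypergeometric
    overrepresentation; Kaplan-Meier and Cox survival modelling with
    hazard-ratio feature screening, martingale-residual cutpoints and
    likelihood-ratio prognostic-gain statistics; and proteome-transcriptome
    concordance analysis. Includes a synthetic multi-plex cohort generator
    with planted subtype, module, survival and transcriptome structure so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea
Config/testthat/edition: 3
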