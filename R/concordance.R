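#' Pair proteomic and transcriptomic layers
#'
#' Restricts both matrices to their shared gene identifiers and shared
#' samples, in a consistent ordering, and reports what was dropped.
#'
#' @param protein_matrix,mrna_matrix gene-by-sample matrices with
#'   identifier rownames.
#' @return A `paired_omics` list: `protein`, `mrna` (aligned matrices),
#'   `n_shared_genes`, `n_shared_samples`, `dropped_genes`,
#'   `dropped_samples`.
#' @export
pair_layers <- function(protein_matrix, mrna_matrix) {
  assert_matrix(protein_matrix, "protein_matrix")
  assert_matrix(mrna_matrix, "mrna_matrix")
  genes <- intersect(rownames(protein_matrix), rownames(mrna_matrix))
  samples <- intersect(colnames(protein_matrix), colnames(mrna_matrix))
  assert_that(length(genes) > 0, "empty gene intersection between layers")
  assert_that(length(samples) > 0, "empty sample intersection between layers")
  structure(list(
    protein = protein_matrix[genes, samples, drop = FALSE],
    mrna = mrna_matrix[genes, samples, drop = FALSE],
    n_shared_genes = length(genes), n_shared_samples = length(samples),
    dropped_genes = list(
      protein_only = setdiff(rownames(protein_matrix), genes),
      mrna_only = setdiff(rownames(mrna_matrix), genes)),
    dropped_samples = list(
      protein_only = setdiff(colnames(protein_matrix), samples),
      mrna_only = setdiff(colnames(mrna_matrix), samples))),
    class = "paired_omics")
}

#' Per-gene Spearman concordance between layers
#'
#' Computes, for every shared gene, the Spearman correlation between its
#' protein and mRNA rows (exact permutation p-value for n <= 10 samples,
#' t-approximation otherwise), adjusts across genes by Benjamini-Hochberg,
#' and classifies each gene as positive-significant, negative-significant
#' or non-significant at the FDR threshold. Constant rows give an
#' undefined correlation and are flagged non-significant.
#'
#' @param paired a `paired_omics` from [pair_layers()].
#' @param fdr FDR threshold for the classes (default 0.05).
#' @return A `data.frame`: gene, rho, p, fdr, class, flagged.
#' @export
correlate_layers <- function(paired, fdr = 0.05) {
  assert_that(inherits(paired, "paired_omics"), "paired must be paired_omics")
  n <- paired$n_shared_samples
  assert_that(n >= 5, "need at least 5 shared samples")
  genes <- rownames(paired$protein)
  res <- lapply(genes, function(g) {
    x <- paired$protein[g, ]; y <- paired$mrna[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(gene = g, rho = NA_real_, p = NA_real_,
                        flagged = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = n <= 10))
    data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value,
               flagged = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab$class <- ifelse(
    tab$flagged | is.na(tab$fdr) | tab$fdr >= fdr, "non-significant",
    ifelse(tab$rho > 0, "positive-significant", "negative-significant"))
  tab
}

#' Dual-layer hazard comparison with triple-endpoint overlap
#'
#' Runs the univariable Cox hazard screen ([screen_features()]) on both
#' layers for each endpoint, categorises every gene x endpoint as
#' protein-only, mRNA-only, concordant-both, opposing-both (both layers
#' p < alpha with hazard ratios on opposite sides of 1) or neither, and
#' summarises the per-layer sets of genes significant for *all* endpoints
#' together with their overlap.
#'
#' @param paired a `paired_omics`.
#' @param records survival records (long format, endpoint column).
#' @param hr_bounds,alpha screen parameters (defaults HR > 2 or < 0.5,
#'   p < 0.05).
#' @return A list: `table` (gene, endpoint, per-layer hr/p, category),
#'   `protein_all_endpoints`, `mrna_all_endpoints`, `overlap`,
#'   `opposing` (endpoint -> genes).
#' @export
compare_hazards <- function(paired, records, hr_bounds = c(0.5, 2.0),
                            alpha = 0.05) {
  assert_that(inherits(paired, "paired_omics"), "paired must be paired_omics")
  scr_p <- screen_features(paired$protein, records, hr_bounds, alpha)
  scr_m <- screen_features(paired$mrna, records, hr_bounds, alpha)
  tp <- scr_p$table; tm <- scr_m$table
  key <- paste(tp$feature, tp$endpoint)
  tm <- tm[match(key, paste(tm$feature, tm$endpoint)), ]
  both_p <- !is.na(tp$p) & !is.na(tm$p) & tp$p < alpha & tm$p < alpha
  opposing <- both_p & (tp$hr - 1) * (tm$hr - 1) < 0
  category <- ifelse(opposing, "opposing-both",
               ifelse(both_p, "concordant-both",
                ifelse(!is.na(tp$p) & tp$p < alpha, "protein-only",
                 ifelse(!is.na(tm$p) & tm$p < alpha, "mRNA-only", "neither"))))
  tab <- data.frame(gene = tp$feature, endpoint = tp$endpoint,
                    hr_protein = tp$hr, p_protein = tp$p,
                    hr_mrna = tm$hr, p_mrna = tm$p,
                    significant_protein = tp$significant,
                    significant_mrna = tm$significant,
                    category = category, stringsAsFactors = FALSE)
  list(table = tab,
       protein_all_endpoints = scr_p$all_endpoint_significant,
       mrna_all_endpoints = scr_m$all_endpoint_significant,
       overlap = intersect(scr_p$all_endpoint_significant,
                           scr_m$all_endpoint_significant),
       opposing = lapply(split(tab, tab$endpoint),
                         function(d) d$gene[d$category == "opposing-both"]))
}
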