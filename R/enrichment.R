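#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a set are dropped; empty sets are rejected.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of member identifiers, with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields", call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set descriptions (defaults to the set
#'   name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (rank normalisation by
#' default) and each set scored with the rank-weighted difference of in-set
#' and out-of-set empirical CDFs accumulated over the whole ordered list:
#' in-set steps are weighted by `|rank|^alpha` (default exponent 0.75).
#' Normalised scores divide by the range of raw scores over all sets and
#' samples; by default they are then z-scored across gene sets within each
#' sample.
#'
#' @param matrix complete (post-imputation) gene-by-sample matrix.
#' @param sets named list of gene sets.
#' @param alpha rank weighting exponent (default 0.75).
#' @param rank_normalise replace expression by ranks before weighting.
#' @param min_size minimum number of set members present in the matrix
#'   (default 10); smaller sets are skipped.
#' @param zscore `"sets"` (z-score across gene sets within sample, the
#'   default), `"samples"` (across samples within set) or `"none"`.
#' @return A list: `es` (raw scores, set x sample), `nes` (range-normalised
#'   and optionally z-scored), `skipped` set names.
#' @export
ssgsea <- function(matrix, sets, alpha = 0.75, rank_normalise = TRUE,
                   min_size = 10, zscore = c("sets", "samples", "none")) {
  zscore <- match.arg(zscore)
  assert_matrix(matrix, "matrix")
  assert_that(!anyNA(matrix), "matrix must be complete (impute first)")
  genes <- rownames(matrix)
  members <- lapply(sets, function(s) intersect(s, genes))
  keep <- lengths(members) >= min_size
  skipped <- names(sets)[!keep]
  if (length(skipped)) {
    message(length(skipped), " gene sets skipped (fewer than ", min_size,
            " members in matrix)")
  }
  members <- members[keep]
  assert_that(length(members) > 0, "no gene set passes the size filter")

  N <- length(genes)
  es <- matrix(NA_real_, length(members), ncol(matrix),
               dimnames = list(names(members), colnames(matrix)))
  in_set <- lapply(members, function(m) genes %in% m)
  for (j in seq_len(ncol(matrix))) {
    v <- if (rank_normalise) rank(matrix[, j], ties.method = "average")
         else matrix[, j]
    ord <- order(v, decreasing = TRUE)
    w <- abs(v[ord])^alpha
    for (i in seq_along(members)) {
      hit <- in_set[[i]][ord]
      p_in <- cumsum(w * hit) / sum(w[hit])
      p_out <- cumsum(!hit) / (N - sum(hit))
      es[i, j] <- sum(p_in - p_out)
    }
  }
  rng <- max(es) - min(es)
  nes <- if (rng > 0) es / rng else es
  if (zscore == "sets" && nrow(nes) > 1) {
    nes <- apply(nes, 2, scale)
    dimnames(nes) <- dimnames(es)
  } else if (zscore == "samples" && ncol(nes) > 1) {
    nes <- t(apply(nes, 1, scale))
    dimnames(nes) <- dimnames(es)
  }
  list(es = es, nes = nes, skipped = skipped,
       params = list(alpha = alpha, rank_normalise = rank_normalise,
                     min_size = min_size, zscore = zscore))
}

# weighted Kolmogorov-Smirnov running-sum enrichment score; weight |metric|
gsea_es <- function(ord_metric, hit) {
  w <- abs(ord_metric)
  sum_w <- sum(w[hit])
  if (sum_w == 0) w[hit] <- 1e-12
  inc <- ifelse(hit, w / max(sum_w, 1e-12), -1 / (length(hit) - sum(hit)))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Genes are ordered by the ranking metric (log2 fold change in the
#' pipeline); each set's enrichment score is the extremum of the weighted
#' Kolmogorov-Smirnov running sum with weight `|metric|`. Significance is
#' assessed by gene-label permutation: NES divides ES by the mean
#' same-signed permutation ES, nominal p is the same-signed permutation
#' tail, and FDR follows the standard NES-pooling procedure. Ties in the
#' metric are broken by identifier order (stable, documented).
#'
#' @param ranking named numeric vector, one value per gene, no duplicates.
#' @param sets named list of gene sets.
#' @param min_size,max_size set size filters after restriction to ranked
#'   genes (defaults 9 and 501).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `data.frame`: set, size, es, nes, p, fdr, leading_edge (comma
#'   separated members up to the running-sum extremum).
#' @export
gsea_preranked <- function(ranking, sets, min_size = 9, max_size = 501,
                           n_perm = 1000, seed = 1L) {
  assert_that(!is.null(names(ranking)) && !anyNA(names(ranking)),
              "ranking must be named by gene")
  assert_that(!anyDuplicated(names(ranking)),
              "ranking has duplicate genes")
  ord <- order(-ranking, names(ranking))     # ties broken by identifier
  metric <- ranking[ord]
  genes <- names(metric)
  N <- length(genes)

  members <- lapply(sets, function(s) intersect(s, genes))
  keep <- lengths(members) >= min_size & lengths(members) <= max_size
  members <- members[keep]
  assert_that(length(members) > 0, "no gene set passes the size filters")

  hits <- lapply(members, function(m) genes %in% m)
  es <- vapply(hits, gsea_es, numeric(1), ord_metric = metric)

  sizes <- lengths(members)
  es_null <- with_seed(seed, {
    lapply(seq_along(members), function(i) {
      ns <- sizes[i]
      vapply(seq_len(n_perm), function(b) {
        h <- logical(N); h[sample.int(N, ns)] <- TRUE
        gsea_es(metric, h)
      }, numeric(1))
    })
  })

  norm_one <- function(e, null) {
    pos <- null[null >= 0]; neg <- null[null < 0]
    if (e >= 0) e / max(mean(pos), 1e-12) else -e / min(mean(neg), -1e-12)
  }
  nes <- vapply(seq_along(es), function(i) norm_one(es[i], es_null[[i]]),
                numeric(1))
  nes_null <- lapply(seq_along(es), function(i) {
    vapply(es_null[[i]], norm_one, numeric(1), null = es_null[[i]])
  })
  p <- vapply(seq_along(es), function(i) {
    null <- es_null[[i]]
    same <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
    if (!length(same)) return(1 / (n_perm + 1))
    (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }, numeric(1))

  pooled <- unlist(nes_null)
  fdr <- vapply(seq_along(nes), function(i) {
    x <- nes[i]
    if (x >= 0) {
      num <- mean(pooled >= x)
      den <- mean(nes >= x)
    } else {
      num <- mean(pooled <= x)
      den <- mean(nes <= x)
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))

  leading <- vapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    w <- abs(metric)
    inc <- ifelse(h, w / max(sum(w[h]), 1e-12), -1 / (N - sum(h)))
    rs <- cumsum(inc)
    peak <- which.max(abs(rs))
    le <- if (rs[peak] >= 0) genes[seq_len(peak)][h[seq_len(peak)]]
          else genes[peak:N][h[peak:N]]
    paste(le, collapse = ",")
  }, character(1))

  data.frame(set = names(members), size = sizes, es = es, nes = nes,
             p = p, fdr = fdr, leading_edge = leading,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric overrepresentation analysis
#'
#' For each set S, tests the upper-tail hypergeometric probability of the
#' observed overlap between the hit list and S within the universe, then
#' adjusts across sets by Benjamini-Hochberg.
#'
#' @param hits character vector of hit genes (must be a subset of the
#'   universe).
#' @param universe character vector of all assayed genes.
#' @param sets named list of gene sets.
#' @return `data.frame`: set, set_size (in universe), overlap, p, fdr,
#'   overlap_genes.
#' @export
ora <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  assert_that(all(hits %in% universe), "hits must be a subset of universe")
  N <- length(universe); n_draw <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    S <- intersect(sets[[nm]], universe)
    ov <- intersect(hits, S)
    k <- length(ov)
    p <- if (n_draw == 0) 1 else {
      stats::phyper(k - 1, length(S), N - length(S), n_draw,
                    lower.tail = FALSE)
    }
    data.frame(set = nm, set_size = length(S), overlap = k, p = p,
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab[, c("set", "set_size", "overlap", "p", "fdr", "overlap_genes")]
}
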