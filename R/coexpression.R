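#' Signed-hybrid soft-threshold adjacency
#'
#' `a_ij = cor_ij^beta` when `cor_ij > 0`, else 0 (negative correlations are
#' discarded, the signed-hybrid convention); the diagonal is 1.
#'
#' @param cor_matrix protein-by-protein correlation matrix, entries in
#'   \[-1, 1\].
#' @param beta positive integer soft-threshold power (the cohort pipeline
#'   used beta = 5).
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
signed_hybrid_adjacency <- function(cor_matrix, beta) {
  assert_that(is.matrix(cor_matrix), "cor_matrix must be a matrix")
  assert_that(beta >= 1, "beta must be >= 1")
  assert_that(all(cor_matrix >= -1 - 1e-8 & cor_matrix <= 1 + 1e-8),
              "correlations must lie in [-1, 1]")
  a <- pmax(cor_matrix, 0)^beta
  diag(a) <- 1
  a
}

#' Scale-free-topology fit across soft-threshold powers
#'
#' For each candidate power, builds the signed-hybrid adjacency, computes
#' node connectivity `k_i = sum_j a_ij (j != i)`, bins `k` and fits the
#' regression of `log10 p(k)` on `log10 k`. The signed fit index is
#' `-sign(slope) * R^2` (scale-free networks have a negative slope). The
#' suggested power is the smallest with a signed fit of at least
#' `r2_target`; when none qualifies the power with the best fit is
#' returned, flagged unreliable.
#'
#' @param matrix protein-by-sample expression matrix (>= 3 proteins).
#' @param beta_grid candidate powers (default 1:20).
#' @param r2_target signed R^2 threshold (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return A list: `table` (beta, signed R^2, slope, mean/median/max
#'   connectivity), `suggested_beta`, `reliable`.
#' @export
pick_soft_threshold <- function(matrix, beta_grid = 1:20, r2_target = 0.8,
                                n_bins = 10) {
  assert_matrix(matrix, "matrix")
  assert_that(nrow(matrix) >= 3, "need at least 3 proteins")
  cm <- stats::cor(t(matrix))
  assert_that(any(cm[upper.tri(cm)] > 0),
              "all correlations non-positive: empty signed-hybrid network")
  rows <- lapply(beta_grid, function(b) {
    a <- signed_hybrid_adjacency(cm, b)
    k <- rowSums(a) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(beta = b, sft_r2 = fit$r2_signed, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # a near-empty network (mean connectivity << 1) cannot be called
  # scale-free however linear its log-log tail looks
  usable <- tab$mean_k >= 1
  ok <- which(tab$sft_r2 >= r2_target & usable)
  if (length(ok)) {
    list(table = tab, suggested_beta = tab$beta[ok[1]], reliable = TRUE)
  } else {
    warning("no power reaches signed R^2 >= ", r2_target,
            " at usable connectivity; suggestion unreliable")
    cand <- if (any(usable)) which(usable) else seq_len(nrow(tab))
    list(table = tab,
         suggested_beta = tab$beta[cand[which.max(tab$sft_r2[cand])]],
         reliable = FALSE)
  }
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2_signed = 0, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mid <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0 & mid > 0
  if (sum(keep) < 3) return(list(r2_signed = 0, slope = NA_real_))
  x <- log10(mid[keep]); y <- log10(freq[keep] / length(k))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2_signed = -sign(slope) * r2, slope = unname(slope))
}

#' Topological overlap dissimilarity
#'
#' Computes the topological overlap matrix
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{j != i} a_ij`,
#' `TOM_ii = 1`, and returns the dissimilarity `1 - TOM` used for module
#' detection.
#'
#' @param adjacency symmetric adjacency matrix, entries in \[0, 1\], unit
#'   diagonal.
#' @return `1 - TOM` matrix.
#' @export
tom_dissimilarity <- function(adjacency) {
  assert_that(is.matrix(adjacency), "adjacency must be a matrix")
  assert_that(isSymmetric(unname(adjacency), tol = 1e-10),
              "invalid input: adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                       # l_ij = sum_u a_iu a_uj (u != i,j holds: diag 0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  1 - tom
}

# first principal component of a module's expression, oriented so that it
# correlates positively with the mean member profile
module_eigengene <- function(matrix, members) {
  sub <- matrix[members, , drop = FALSE]
  if (length(members) == 1) return(as.numeric(scale(sub[1, ])))
  sub <- t(scale(t(sub)))
  sub[is.na(sub)] <- 0
  sv <- svd(sub, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  if (stats::cor(eg, colMeans(sub)) < 0) eg <- -eg
  eg
}

#' Detect co-expression modules by dynamic tree cutting
#'
#' Builds an average-linkage dendrogram of the dissimilarity, cuts it with
#' an adaptive-height dynamic cut (the cut height, searched over all merge
#' heights, that maximises the number of branches of at least
#' `min_module_size` proteins; `deep_split` >= 2 breaks ties toward the
#' lower, finer cut and < 2 toward the higher), labels undersized branches
#' ungrouped, and then iteratively merges modules whose summary profiles
#' (sign-oriented first principal component of member expression) have
#' Pearson dissimilarity `1 - cor` below `merge_cut_height`.
#'
#' @param dissimilarity square symmetric dissimilarity, typically
#'   `1 - TOM` from [tom_dissimilarity()].
#' @param matrix protein-by-sample expression matrix (for eigengene
#'   merging); rows must match the dissimilarity.
#' @param min_module_size minimum module size (default 30).
#' @param deep_split split aggressiveness 0-4 (default 2).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @return A `module_assignment`: `membership` (protein -> `"M1"`, `"M2"`,
#'   ... or `"ungrouped"`), `sizes`, `eigengenes` (module x sample),
#'   `merge_heights` of the dendrogram.
#' @export
detect_modules <- function(dissimilarity, matrix, min_module_size = 30,
                           deep_split = 2, merge_cut_height = 0.25) {
  assert_that(is.matrix(dissimilarity) &&
                nrow(dissimilarity) == ncol(dissimilarity),
              "dissimilarity must be square")
  assert_that(isSymmetric(unname(dissimilarity), tol = 1e-8),
              "invalid input: dissimilarity must be symmetric")
  ids <- rownames(dissimilarity) %||% rownames(matrix)
  p <- nrow(dissimilarity)
  if (p < min_module_size) {
    warning("fewer proteins than min_module_size: everything ungrouped")
    memb <- rep("ungrouped", p); names(memb) <- ids
    return(structure(list(membership = memb, sizes = integer(0),
                          eigengenes = NULL, merge_heights = numeric(0)),
                     class = "module_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(dissimilarity), method = "average")

  # static branch cut at a fraction of the dendrogram height; deeper split
  # presets cut lower, detaching more (smaller) branches before the noise
  # joins the tree near the top
  presets <- c(0.999, 0.995, 0.99, 0.985, 0.98)
  deep_split <- max(0L, min(4L, as.integer(deep_split)))
  cut_at <- presets[deep_split + 1L] * max(hc$height)
  lab0 <- stats::cutree(hc, h = cut_at)

  sizes0 <- table(lab0)
  module_ids <- names(sizes0)[sizes0 >= min_module_size]
  memb <- rep("ungrouped", p)
  for (j in seq_along(module_ids)) {
    memb[lab0 == as.integer(module_ids[j])] <- paste0("M", j)
  }
  names(memb) <- ids

  memb <- merge_close_modules(matrix, memb, merge_cut_height)
  mods <- setdiff(unique(memb), "ungrouped")
  eg <- if (length(mods)) {
    t(vapply(mods, function(m) module_eigengene(matrix, names(memb)[memb == m]),
             numeric(ncol(matrix))))
  } else NULL
  if (!is.null(eg)) dimnames(eg) <- list(mods, colnames(matrix))
  structure(list(membership = memb,
                 sizes = sort(table(memb[memb != "ungrouped"]),
                              decreasing = TRUE),
                 eigengenes = eg, merge_heights = hc$height,
                 cut_height = cut_at),
            class = "module_assignment")
}

# iterative eigengene merge; idempotent once no pair is closer than cut
merge_close_modules <- function(matrix, memb, merge_cut_height) {
  repeat {
    mods <- setdiff(unique(memb), "ungrouped")
    if (length(mods) < 2) break
    eg <- vapply(mods, function(m) module_eigengene(matrix, names(memb)[memb == m]),
                 numeric(ncol(matrix)))
    dd <- 1 - stats::cor(eg)
    diag(dd) <- Inf
    if (min(dd) >= merge_cut_height) break
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    keep <- mods[min(ij)]; drop <- mods[max(ij)]
    memb[memb == drop] <- keep
  }
  # relabel modules consecutively by size
  mods <- setdiff(unique(memb), "ungrouped")
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(memb == m), numeric(1))
    new <- paste0("M", seq_along(mods))
    names(new) <- mods[order(-sizes)]
    memb[memb != "ungrouped"] <- new[memb[memb != "ungrouped"]]
  }
  memb
}

#' Per-sample module score
#'
#' The module score of a sample is the median expression of the module's
#' member proteins in that sample (the summary used for tertile survival
#' stratification; the eigengene is used only for merging).
#'
#' @param matrix protein-by-sample matrix.
#' @param assignment a `module_assignment` (or named membership vector).
#' @param module_id module label, e.g. `"M1"`.
#' @return Named numeric vector of per-sample scores.
#' @export
module_score <- function(matrix, assignment, module_id) {
  assert_matrix(matrix, "matrix")
  memb <- if (inherits(assignment, "module_assignment")) {
    assignment$membership
  } else {
    assignment
  }
  members <- intersect(names(memb)[memb == module_id], rownames(matrix))
  assert_that(length(members) >= 1,
              paste("module", module_id, "absent from matrix"))
  apply(matrix[members, , drop = FALSE], 2, stats::median)
}

#' Tertile stratification of a module score
#'
#' Splits samples into `low` / `intermediate` / `high` strata at the
#' empirical tertiles of the score; samples on a boundary go to the lower
#' stratum. With distinct scores the strata sizes differ by at most one.
#'
#' @param score named numeric vector of per-sample scores.
#' @return Named factor with levels `low`, `intermediate`, `high`.
#' @export
tertile_stratify <- function(score) {
  assert_that(length(score) >= 3, "need at least 3 samples")
  qs <- stats::quantile(score, c(1, 2) / 3, names = FALSE)
  strata <- ifelse(score <= qs[1], "low",
                   ifelse(score <= qs[2], "intermediate", "high"))
  factor(stats::setNames(strata, names(score)),
         levels = c("low", "intermediate", "high"))
}

#' Export a thresholded network edge list
#'
#' Emits the undirected edges (i < j) whose similarity exceeds the
#' threshold, with weights, optionally annotated with module membership of
#' both endpoints. The default similarity in the pipeline is the TOM.
#'
#' @param similarity_matrix square symmetric similarity matrix.
#' @param threshold minimum similarity for an edge (default 0.05, strict).
#' @param assignment optional `module_assignment` for node annotation.
#' @return `data.frame` with columns source, target, weight (and
#'   source_module / target_module when an assignment is given).
#' @export
export_edge_list <- function(similarity_matrix, threshold = 0.05,
                             assignment = NULL) {
  assert_that(is.matrix(similarity_matrix) &&
                nrow(similarity_matrix) == ncol(similarity_matrix),
              "similarity_matrix must be square")
  assert_that(isSymmetric(unname(similarity_matrix), tol = 1e-8),
              "similarity_matrix must be symmetric")
  ids <- rownames(similarity_matrix) %||%
    as.character(seq_len(nrow(similarity_matrix)))
  ut <- which(upper.tri(similarity_matrix) & similarity_matrix > threshold,
              arr.ind = TRUE)
  edges <- data.frame(source = ids[ut[, 1]], target = ids[ut[, 2]],
                      weight = similarity_matrix[ut],
                      stringsAsFactors = FALSE)
  if (!is.null(assignment)) {
    memb <- if (inherits(assignment, "module_assignment")) {
      assignment$membership
    } else {
      assignment
    }
    edges$source_module <- unname(memb[edges$source])
    edges$target_module <- unname(memb[edges$target])
  }
  edges
}
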