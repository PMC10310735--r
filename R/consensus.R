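#' Resampling consensus clustering of samples
#'
#' Repeatedly subsamples samples (items) and proteins (features), clusters
#' each subsample, and tallies how often each sample pair co-clusters
#' relative to how often it is co-sampled. The defaults reproduce the
#' cohort pipeline's configuration: 80% item and feature resampling, 1000
#' repetitions, k from 2 to 10, agglomerative hierarchical clustering on
#' Spearman rank distance with average linkage.
#'
#' @param matrix protein-by-sample normalised matrix.
#' @param distance `"spearman"` (1 - rank correlation), `"pearson"`
#'   (1 - correlation) or `"euclidean"`, used by the hierarchical base
#'   method and for downstream silhouettes.
#' @param linkage `"average"` or `"complete"`.
#' @param base `"hierarchical"` or `"kmeans"` inner clustering.
#' @param k_range integer vector of cluster numbers to evaluate.
#' @param reps number of resampling repetitions.
#' @param p_item,p_feature fraction of samples / proteins drawn per rep.
#' @param seed RNG seed; runs are deterministic given the seed.
#' @return A `consensus_result`: `consensus` (list of sample-by-sample
#'   consensus matrices, entries in \[0,1\], diagonal 1, 0/0 defined as 0,
#'   one per k), `co_sampled` counts, `k_range`, `n_skipped` (reps skipped
#'   because a constant-feature subsample broke the correlation distance)
#'   and `params`.
#' @export
run_consensus <- function(matrix,
                          distance = c("spearman", "pearson", "euclidean"),
                          linkage = c("average", "complete"),
                          base = c("hierarchical", "kmeans"),
                          k_range = 2:10, reps = 1000,
                          p_item = 0.8, p_feature = 0.8, seed = 1L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  base <- match.arg(base)
  assert_matrix(matrix, "matrix")
  n <- ncol(matrix); p <- nrow(matrix)
  assert_that(n > max(k_range), "need more samples than max(k_range)")

  with_seed(seed, {
    n_item <- max(2L, floor(p_item * n))
    n_feat <- max(1L, floor(p_feature * p))
    co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
    names(co_cluster) <- as.character(k_range)
    co_sampled <- matrix(0, n, n)
    n_skipped <- 0L

    for (r in seq_len(reps)) {
      items <- sort(sample.int(n, n_item))
      feats <- sample.int(p, n_feat)
      sub <- matrix[feats, items, drop = FALSE]

      labels_by_k <- NULL
      if (base == "hierarchical") {
        d <- sample_distance(sub, distance)
        if (anyNA(as.vector(d))) { n_skipped <- n_skipped + 1L; next }
        hc <- stats::hclust(d, method = linkage)
        labels_by_k <- lapply(k_range, function(k) stats::cutree(hc, k))
      } else {
        labels_by_k <- lapply(k_range, function(k) {
          stats::kmeans(t(sub), centers = k, nstart = 1,
                        iter.max = 25)$cluster
        })
      }
      co_sampled[items, items] <- co_sampled[items, items] + 1
      for (j in seq_along(k_range)) {
        lab <- labels_by_k[[j]]
        same <- outer(lab, lab, "==") * 1
        co_cluster[[j]][items, items] <- co_cluster[[j]][items, items] + same
      }
    }

    consensus <- lapply(co_cluster, function(cc) {
      m <- ifelse(co_sampled > 0, cc / co_sampled, 0)
      diag(m) <- 1
      dimnames(m) <- list(colnames(matrix), colnames(matrix))
      m
    })
    structure(list(consensus = consensus, co_sampled = co_sampled,
                   k_range = k_range, n_skipped = n_skipped,
                   params = list(distance = distance, linkage = linkage,
                                 base = base, reps = reps, p_item = p_item,
                                 p_feature = p_feature, seed = seed)),
              class = "consensus_result")
  })
}

# distance between sample columns; correlation distances are 1 - cor
sample_distance <- function(matrix, distance) {
  switch(distance,
         euclidean = stats::dist(t(matrix)),
         pearson = stats::as.dist(1 - stats::cor(matrix, method = "pearson")),
         spearman = stats::as.dist(1 - suppressWarnings(
           stats::cor(matrix, method = "spearman"))))
}

# area under the empirical CDF of off-diagonal consensus entries:
# sum over sorted unique values of (x_i - x_{i-1}) * CDF(x_i)
consensus_cdf_area <- function(M) {
  e <- M[lower.tri(M)]
  xs <- sort(unique(e))
  cdf <- stats::ecdf(e)
  if (length(xs) < 2) return(list(area = 0, x = xs, cdf = cdf(xs)))
  list(area = sum(diff(xs) * cdf(xs)[-1]), x = xs, cdf = cdf(xs))
}

#' Select the number of clusters from a consensus result
#'
#' Computes, per k, the empirical CDF of consensus entries, its area, the
#' relative delta-area and the mean silhouette width of the consensus-derived
#' labels (on the configured sample distance). The chosen k is the smallest
#' k whose delta-area at k+1 falls below `delta_threshold` and whose mean
#' silhouette is a local maximum; when no k satisfies both, the k with the
#' best silhouette is used. Final labels come from average-linkage
#' hierarchical clustering of 1 - consensus at the chosen k.
#'
#' @param result a `consensus_result` from [run_consensus()].
#' @param matrix the matrix that was clustered (for silhouette distances);
#'   if `NULL`, silhouettes use 1 - consensus.
#' @param delta_threshold relative delta-area flattening threshold
#'   (default 0.025).
#' @return A `cluster_selection`: per-k `cdf`, `area`, `delta_area`,
#'   `silhouette`; `chosen_k`; `labels` (named integer vector).
#' @export
evaluate_k <- function(result, matrix = NULL, delta_threshold = 0.025) {
  assert_that(inherits(result, "consensus_result"),
              "result must come from run_consensus()")
  ks <- result$k_range
  assert_that(length(ks) >= 2, "need at least 2 values of k")

  cdfs <- lapply(result$consensus, consensus_cdf_area)
  area <- unname(vapply(cdfs, `[[`, numeric(1), "area"))
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  for (j in seq_along(ks)[-1]) {
    delta[j] <- if (area[j - 1] > 0) (area[j] - area[j - 1]) / area[j - 1] else 0
  }

  labels_k <- lapply(seq_along(ks), function(j) {
    hc <- stats::hclust(stats::as.dist(1 - result$consensus[[j]]),
                        method = "average")
    stats::cutree(hc, ks[j])
  })
  dmat <- if (!is.null(matrix)) {
    as.matrix(sample_distance(matrix, result$params$distance))
  } else {
    1 - result$consensus[[1]]
  }
  sil <- vapply(seq_along(ks), function(j) {
    s <- cluster::silhouette(labels_k[[j]], dmat = dmat)
    if (is.matrix(s)) mean(s[, "sil_width"]) else NA_real_
  }, numeric(1))

  chosen <- NA_integer_
  for (j in seq_along(ks)) {
    flat_next <- j == length(ks) || delta[j + 1] < delta_threshold
    left_ok <- j == 1 || sil[j] >= sil[j - 1]
    right_ok <- j == length(ks) || sil[j] >= sil[j + 1]
    if (flat_next && left_ok && right_ok) { chosen <- j; break }
  }
  if (is.na(chosen)) chosen <- which.max(sil)

  labels <- labels_k[[chosen]]
  names(labels) <- rownames(result$consensus[[1]])
  structure(list(k_range = ks, cdf = cdfs, area = area, delta_area = delta,
                 silhouette = sil, chosen_k = ks[chosen], labels = labels,
                 delta_threshold = delta_threshold),
            class = "cluster_selection")
}

#' SigClust: significance of a cluster split against a Gaussian null
#'
#' Tests whether a two-group split is stronger than expected from a single
#' multivariate Gaussian. The observed statistic is the cluster index
#' CI = within-cluster SS / total SS. The null is a zero-mean Gaussian with
#' diagonal covariance whose eigenvalues are estimated from the data by hard
#' thresholding: eigenvalues below the background noise variance
#' `sigma2 = (MAD of all matrix entries / 0.6745)^2` are replaced by
#' `sigma2`. Each of `n_sim` null datasets is split by 2-means and its CI
#' recorded; `p = (1 + #{null CI <= observed CI}) / (n_sim + 1)`. With more
#' than two observed clusters the test is applied to every cluster pair and
#' the maximum pairwise p is reported as the overall significance.
#'
#' @param matrix protein-by-sample matrix (samples are the observations).
#' @param labels cluster assignment for the samples (2 or more groups,
#'   each pair tested must have >= 2 samples).
#' @param n_sim number of null simulations (default 1000).
#' @param seed RNG seed.
#' @return A `sigclust_result`: `p` (overall), `pairs` (per-pair CI, p),
#'   `n_sim`, `sigma2`.
#' @export
sigclust <- function(matrix, labels, n_sim = 1000, seed = 1L) {
  assert_matrix(matrix, "matrix")
  labels <- as.factor(labels)
  assert_that(ncol(matrix) == length(labels),
              "one label per sample required")
  lv <- levels(labels)
  assert_that(length(lv) >= 2, "at least two groups required")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    sigclust_two(matrix[, sel, drop = FALSE], droplevels(labels[sel]),
                 n_sim = n_sim, seed = seed)
  })
  ps <- vapply(res, `[[`, numeric(1), "p")
  structure(list(p = max(ps),
                 pairs = data.frame(
                   group1 = vapply(pairs, `[`, character(1), 1),
                   group2 = vapply(pairs, `[`, character(1), 2),
                   ci = vapply(res, `[[`, numeric(1), "ci"),
                   p = ps),
                 n_sim = n_sim,
                 sigma2 = res[[1]]$sigma2),
            class = "sigclust_result")
}

sigclust_two <- function(matrix, labels, n_sim, seed) {
  X <- t(matrix)                       # n x d, samples as rows
  n <- nrow(X); d <- ncol(X)
  assert_that(n >= 3, "invalid input: need at least 3 samples")
  assert_that(all(table(labels) >= 2), "each group needs >= 2 samples")

  ci_of <- function(X, lab) {
    tot <- sum(sweep(X, 2, colMeans(X))^2)
    within <- sum(vapply(split(seq_len(nrow(X)), lab), function(ix) {
      sum(sweep(X[ix, , drop = FALSE], 2,
                colMeans(X[ix, , drop = FALSE]))^2)
    }, numeric(1)))
    if (tot == 0) 0 else within / tot
  }
  ci_obs <- ci_of(X, labels)

  # eigenvalues of the sample covariance with hard thresholding
  sigma2 <- stats::mad(as.vector(X))^2          # (MAD/0.6745)^2
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  ev <- numeric(d)
  ev[seq_along(sv)] <- sv^2 / (n - 1)
  ev[ev < sigma2] <- sigma2

  with_seed(seed, {
    ci_null <- vapply(seq_len(n_sim), function(i) {
      X0 <- matrix(stats::rnorm(n * d), n, d) %*% diag(sqrt(ev), d)
      km <- stats::kmeans(X0, centers = 2, nstart = 2, iter.max = 30)
      if (km$totss == 0) 0 else km$tot.withinss / km$totss
    }, numeric(1))
    list(ci = ci_obs, p = (1 + sum(ci_null <= ci_obs)) / (n_sim + 1),
         sigma2 = sigma2)
  })
}

# proportion of ambiguous consensus entries in the open window (x1, x2)
pac_score <- function(M, window = c(0.1, 0.9)) {
  e <- M[lower.tri(M)]
  mean(e > window[1] & e < window[2])
}

#' Monte-Carlo-null consensus clustering
#'
#' Compares the stability of consensus clustering on the real data against
#' null datasets simulated from a multivariate normal matched to the
#' observed principal-component eigenvalue spectrum. Stability is measured
#' by PAC (proportion of ambiguous consensus entries in the window
#' `(0.1, 0.9)`); for each k the relative cluster-stability score is
#' `ln(mean null PAC / real PAC)` and the empirical p-value is the fraction
#' of null datasets at least as stable as the real data.
#'
#' @param matrix protein-by-sample matrix.
#' @param base inner clustering method (default `"kmeans"`).
#' @param k_range cluster numbers to evaluate.
#' @param reps consensus repetitions per dataset.
#' @param n_null number of Monte-Carlo reference datasets (>= 20).
#' @param pac_window ambiguity window, default `c(0.1, 0.9)`.
#' @param p_item item-resampling fraction.
#' @param seed RNG seed.
#' @return An `m3c_result`: per-k `pac_real`, `pac_null` (matrix
#'   n_null x k), `rcsi`, `p`; `chosen_k` (k with the largest relative
#'   score among those with p < 0.05, `NA` if none).
#' @export
monte_carlo_consensus <- function(matrix, base = "kmeans", k_range = 2:10,
                                  reps = 100, n_null = 100,
                                  pac_window = c(0.1, 0.9),
                                  p_item = 0.8, seed = 1L) {
  assert_matrix(matrix, "matrix")
  assert_that(n_null >= 20, "n_null must be >= 20")
  n <- ncol(matrix)
  Xc <- sweep(t(matrix), 2, rowMeans(matrix))   # n x p, centred features
  sv <- svd(Xc)
  assert_that(sum(sv$d > 1e-12) >= 2, "invalid input: covariance rank < 2")

  run_pac <- function(mat, sd) {
    cr <- run_consensus(mat, distance = "euclidean", base = base,
                        k_range = k_range, reps = reps, p_item = p_item,
                        p_feature = 1, seed = sd)
    vapply(cr$consensus, pac_score, numeric(1), window = pac_window)
  }

  pac_real <- run_pac(matrix, seed)
  ev_sd <- sv$d / sqrt(max(1, n - 1))           # per-PC score sds

  pac_null <- with_seed(seed + 1L, {
    t(vapply(seq_len(n_null), function(b) {
      scores <- matrix(stats::rnorm(n * length(ev_sd)), n) %*% diag(ev_sd)
      X0 <- t(scores %*% t(sv$v))               # p x n null data
      dimnames(X0) <- dimnames(matrix)
      run_pac(X0, seed + 1L + b)
    }, numeric(length(k_range))))
  })

  n_pairs <- n * (n - 1) / 2
  pac_floor <- 1 / (n_pairs + 1)                # avoid log of zero PAC
  rcsi <- log(pmax(colMeans(pac_null), pac_floor) / pmax(pac_real, pac_floor))
  p <- vapply(seq_along(k_range), function(j) {
    (1 + sum(pac_null[, j] <= pac_real[j])) / (n_null + 1)
  }, numeric(1))

  ok <- which(p < 0.05)
  chosen <- if (length(ok)) k_range[ok[which.max(rcsi[ok])]] else NA_integer_
  structure(list(k_range = k_range, pac_real = pac_real,
                 pac_null = pac_null, rcsi = rcsi, p = p,
                 chosen_k = chosen, pac_window = pac_window),
            class = "m3c_result")
}
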