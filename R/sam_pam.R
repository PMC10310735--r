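#' Two-class significance analysis (SAM) of protein abundance
#'
#' Scores each protein for differential abundance between two groups with
#' either a Student t statistic (`"t_stat"`, the default used for two-class
#' marker calling) or the moderated SAM d statistic
#' `d_i = (mean2 - mean1) / (s_i + s0)` with exchangeability constant `s0`
#' (default: the median of all pooled standard errors). Permutation of the
#' group labels yields a pooled null distribution from which per-protein
#' p-values are computed and converted to q-values by Benjamini-Hochberg.
#' The significant set applies both the q-value threshold and a
#' linear-scale fold-change filter (defaults: FDR < 1%, fold change >= 1.5).
#'
#' @param matrix protein-by-sample matrix on the log2 scale.
#' @param labels two-level factor (or coercible) over samples; scores are
#'   oriented as level 2 minus level 1.
#' @param fdr q-value threshold for the significant set.
#' @param min_fc minimum linear fold change (applied two-sided:
#'   `max(fc, 1/fc) >= min_fc`).
#' @param n_perm number of label permutations.
#' @param statistic `"t_stat"` (s0 = 0) or `"d_stat"` (s0 = median s_i).
#' @param s0 override for the exchangeability constant.
#' @param seed RNG seed for the permutations.
#' @return A `sam_result` with `table` (per-protein mean1, mean2, s, d,
#'   log2 fold change, fold change, p, q), `s0`, `significant` (protein
#'   ids), `up`/`down` subsets, and parameters.
#' @export
sam_two_class <- function(matrix, labels, fdr = 0.01, min_fc = 1.5,
                          n_perm = 1000, statistic = c("t_stat", "d_stat"),
                          s0 = NULL, seed = 1L) {
  statistic <- match.arg(statistic)
  assert_matrix(matrix, "matrix")
  labels <- as.factor(labels)
  assert_that(nlevels(labels) == 2, "labels must have exactly two levels")
  assert_that(all(table(labels) >= 2), "both classes need >= 2 samples")

  stat_fun <- function(mat, lab) {
    g2 <- lab == levels(lab)[2]
    n1 <- sum(!g2); n2 <- sum(g2)
    m1 <- rowMeans(mat[, !g2, drop = FALSE])
    m2 <- rowMeans(mat[, g2, drop = FALSE])
    ss1 <- rowSums((mat[, !g2, drop = FALSE] - m1)^2)
    ss2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    list(m1 = m1, m2 = m2, s = s)
  }

  obs <- stat_fun(matrix, labels)
  s0_val <- if (!is.null(s0)) {
    s0
  } else if (statistic == "d_stat") {
    stats::median(obs$s)
  } else {
    0
  }
  denom <- obs$s + s0_val
  if (any(denom == 0)) {
    # zero-variance proteins: floor the denominator so scores stay finite
    floor_val <- min(denom[denom > 0], 1e-8)
    message(sum(denom == 0), " zero-variance proteins scored with floored s")
    denom[denom == 0] <- floor_val
  }
  d_obs <- (obs$m2 - obs$m1) / denom

  # exact enumeration of label assignments when feasible, else sampling
  n2 <- sum(labels == levels(labels)[2])
  n_all <- length(labels)
  perms <- if (choose(n_all, n2) <= n_perm) {
    utils::combn(n_all, n2, simplify = FALSE)
  } else {
    with_seed(seed, {
      lapply(seq_len(n_perm), function(i) sample.int(n_all, n2))
    })
  }
  null_d <- unlist(lapply(perms, function(ix) {
    lab <- factor(ifelse(seq_len(n_all) %in% ix,
                         levels(labels)[2], levels(labels)[1]),
                  levels = levels(labels))
    pm <- stat_fun(matrix, lab)
    dn <- pm$s + s0_val
    dn[dn == 0] <- min(dn[dn > 0], 1e-8)
    (pm$m2 - pm$m1) / dn
  }))
  abs_null <- sort(abs(null_d))
  # pooled permutation p: rank of |d| within the combined null
  exceed <- length(abs_null) -
    findInterval(abs(d_obs) - 1e-12, abs_null)
  p <- (1 + exceed) / (1 + length(abs_null))
  q <- stats::p.adjust(p, method = "BH")

  lfc <- obs$m2 - obs$m1
  fc <- 2^lfc
  sig <- q <= fdr & pmax(fc, 1 / fc) >= min_fc
  tab <- data.frame(protein = rownames(matrix),
                    mean1 = obs$m1, mean2 = obs$m2, s = obs$s,
                    d = d_obs, log2_fc = lfc, fold_change = fc,
                    p = p, q = q, significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = s0_val,
                 significant = tab$protein[sig],
                 up = tab$protein[sig & lfc > 0],
                 down = tab$protein[sig & lfc < 0],
                 params = list(fdr = fdr, min_fc = min_fc, n_perm = n_perm,
                               statistic = statistic, seed = seed,
                               levels = levels(labels))),
            class = "sam_result")
}

#' Subtype-unique upregulated markers
#'
#' For every subtype with more than `min_group - 1` cases, runs a two-class
#' SAM of that subtype against all other samples and collects the
#' upregulated significant proteins; a protein is a *unique* marker when it
#' is significant for exactly one subtype.
#'
#' @param matrix protein-by-sample matrix.
#' @param subtype_labels subtype assignment over samples.
#' @param min_group minimum subtype size to qualify (default 21, i.e.
#'   strictly more than 20 cases).
#' @param ... passed to [sam_two_class()] (fdr, min_fc, n_perm, seed, ...).
#' @return A list: `unique_markers` (subtype -> protein ids),
#'   `upregulated` (subtype -> all upregulated significant ids),
#'   `n_unique_total`, `qualifying_subtypes`.
#' @export
unique_subtype_markers <- function(matrix, subtype_labels, min_group = 21,
                                   ...) {
  assert_matrix(matrix, "matrix")
  subtype_labels <- as.factor(subtype_labels)
  sizes <- table(subtype_labels)
  qual <- names(sizes)[sizes >= min_group]
  assert_that(length(qual) >= 2,
              "invalid input: fewer than two subtypes meet min_group")
  up <- lapply(qual, function(st) {
    lab <- factor(ifelse(subtype_labels == st, "subtype", "rest"),
                  levels = c("rest", "subtype"))
    sam_two_class(matrix, lab, ...)$up
  })
  names(up) <- qual
  counts <- table(unlist(up))
  uniq <- lapply(up, function(u) u[counts[u] == 1])
  list(unique_markers = uniq, upregulated = up,
       n_unique_total = sum(lengths(uniq)),
       qualifying_subtypes = qual)
}

# pooled within-class sd and NSC ingredients
nsc_stats <- function(matrix, labels, s0 = NULL) {
  lv <- levels(labels)
  n <- ncol(matrix); K <- length(lv)
  nk <- table(labels)
  overall <- rowMeans(matrix)
  cent <- vapply(lv, function(g) rowMeans(matrix[, labels == g, drop = FALSE]),
                 numeric(nrow(matrix)))
  ssw <- rowSums(vapply(lv, function(g) {
    rowSums((matrix[, labels == g, drop = FALSE] - cent[, g])^2)
  }, numeric(nrow(matrix))))
  s <- sqrt(ssw / (n - K))
  s0_val <- s0 %||% stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  dik <- sweep(cent - overall, 1, s + s0_val, "/")
  dik <- sweep(dik, 2, mk[lv], "/")
  list(overall = overall, centroids = cent, s = s, s0 = s0_val,
       mk = mk, dik = dik, nk = nk, levels = lv)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

nsc_predict_delta <- function(st, priors, newx, delta) {
  dshr <- soft_threshold(st$dik, delta)
  retained <- rowSums(dshr != 0) > 0
  shrunken <- st$overall +
    sweep(sweep(dshr, 1, st$s + st$s0, "*"), 2, st$mk[st$levels], "*")
  if (!any(retained)) {
    # no informative proteins left: fall back to priors alone
    lab <- rep(st$levels[which.max(priors)], ncol(newx))
    return(list(labels = lab, retained = character(0),
                delta_scores = NULL))
  }
  x <- newx[retained, , drop = FALSE]
  ctr <- shrunken[retained, , drop = FALSE]
  w <- (st$s + st$s0)[retained]
  scores <- vapply(seq_along(st$levels), function(k) {
    colSums(((x - ctr[, k]) / w)^2) - 2 * log(priors[k])
  }, numeric(ncol(newx)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = ncol(newx))
  lab <- st$levels[apply(scores, 1, which.min)]
  list(labels = lab, retained = rownames(newx)[retained],
       delta_scores = scores)
}

#' Train a nearest-shrunken-centroid (PAM) classifier
#'
#' Computes standardised class-centroid differences
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, soft-thresholds them over a grid of shrinkage
#' values `delta`, and estimates the misclassification error of each grid
#' point by stratified cross-validation (default 10-fold). Expression rows
#' are z-scored first by default, matching the pipeline's use of z-scored
#' data for SAM-PAM panel reduction.
#'
#' @param matrix protein-by-sample matrix (typically pre-filtered by SAM).
#' @param labels class labels over samples (K >= 2 classes).
#' @param folds number of CV folds (reduced with a warning if a class is
#'   too small to stratify).
#' @param n_delta number of shrinkage grid points from 0 to `max|d_ik|`.
#' @param zscore_first z-score each protein row before training.
#' @param priors `"class"` (proportional to class size, default) or
#'   `"uniform"`.
#' @param seed RNG seed for fold assignment.
#' @return An `nsc_model` storing centroids, `s`, `s0`, priors, the delta
#'   grid with CV errors, `delta_star` (largest delta attaining the minimum
#'   CV error), and the retained panel at `delta_star`.
#' @export
pam_train <- function(matrix, labels, folds = 10, n_delta = 30,
                      zscore_first = TRUE, priors = c("class", "uniform"),
                      seed = 1L) {
  priors <- match.arg(priors)
  assert_matrix(matrix, "matrix")
  labels <- droplevels(as.factor(labels))
  assert_that(nlevels(labels) >= 2, "need at least two classes")
  nk <- table(labels)
  if (any(nk < folds)) {
    folds_new <- max(2L, min(nk))
    if (folds_new < folds) {
      warning("reducing folds from ", folds, " to ", folds_new,
              " so every fold keeps all classes")
      folds <- folds_new
    }
  }
  if (zscore_first) {
    matrix <- t(scale(t(matrix)))
    matrix[is.na(matrix)] <- 0           # constant rows carry no signal
  }
  st <- nsc_stats(matrix, labels)
  pri <- if (priors == "class") as.numeric(nk) / ncol(matrix)
         else rep(1 / nlevels(labels), nlevels(labels))
  names(pri) <- levels(labels)
  delta_grid <- seq(0, max(abs(st$dik)), length.out = n_delta)

  # stratified fold assignment
  fold_id <- with_seed(seed, {
    f <- integer(ncol(matrix))
    for (g in levels(labels)) {
      ix <- sample(which(labels == g))
      f[ix] <- rep_len(seq_len(folds), length(ix))
    }
    f
  })

  cv_err <- matrix(0, folds, n_delta)
  for (fd in seq_len(folds)) {
    test <- fold_id == fd
    st_tr <- nsc_stats(matrix[, !test, drop = FALSE],
                       droplevels(labels[!test]), s0 = NULL)
    pri_tr <- pri[st_tr$levels] / sum(pri[st_tr$levels])
    for (j in seq_len(n_delta)) {
      pred <- nsc_predict_delta(st_tr, pri_tr,
                                matrix[, test, drop = FALSE],
                                delta_grid[j])
      cv_err[fd, j] <- mean(pred$labels != as.character(labels[test]))
    }
  }
  # overall CV error weights folds by size
  fold_n <- tabulate(fold_id, folds)
  cv_curve <- colSums(cv_err * fold_n) / sum(fold_n)

  model <- structure(
    list(stats = st, priors = pri, delta_grid = delta_grid,
         cv_error = cv_curve, labels = labels, folds = folds, seed = seed,
         zscore_first = zscore_first),
    class = "nsc_model")
  sel <- select_min_error(model)
  model$delta_star <- sel$delta_star
  model$retained <- sel$retained
  model$cv_error_star <- sel$cv_error
  model
}

#' Pick the shrinkage that minimises cross-validated error
#'
#' Returns the largest `delta` attaining the minimum CV error (the
#' parsimony tie-break: equal error, smaller panel) along with the proteins
#' retained at that shrinkage and the error itself.
#'
#' @param model an `nsc_model` from [pam_train()].
#' @return A list: `delta_star`, `retained` (protein ids with a non-zero
#'   shrunken difference in any class), `cv_error`.
#' @export
select_min_error <- function(model) {
  assert_that(inherits(model, "nsc_model"), "model must be an nsc_model")
  err <- model$cv_error
  j <- max(which(err == min(err)))
  dshr <- soft_threshold(model$stats$dik, model$delta_grid[j])
  retained <- rownames(model$stats$dik)[rowSums(dshr != 0) > 0]
  list(delta_star = model$delta_grid[j], retained = retained,
       cv_error = err[j])
}

#' Predict class labels with a trained shrunken-centroid model
#'
#' Evaluates the discriminant
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`
#' over the retained proteins and assigns each sample to the class with the
#' smallest score; class probabilities are the softmin of the discriminants.
#' Retained proteins absent from the new matrix are dropped with a warning
#' as long as at least 80% remain; below that the prediction is refused.
#'
#' @param model an `nsc_model`.
#' @param new_matrix protein-by-sample matrix sharing protein identifiers
#'   with the training data (e.g. an external cohort).
#' @param delta shrinkage at which to predict (default `model$delta_star`).
#' @return A `data.frame`: sample, predicted label, one probability column
#'   per class, and `tie` (TRUE when two classes scored identically and the
#'   first in class order was taken).
#' @export
pam_predict <- function(model, new_matrix, delta = NULL) {
  assert_that(inherits(model, "nsc_model"), "model must be an nsc_model")
  assert_matrix(new_matrix, "new_matrix")
  delta <- delta %||% model$delta_star
  dshr <- soft_threshold(model$stats$dik, delta)
  retained <- rownames(model$stats$dik)[rowSums(dshr != 0) > 0]
  present <- intersect(retained, rownames(new_matrix))
  overlap <- length(present) / length(retained)
  assert_that(overlap >= 0.8,
              sprintf("only %.0f%% of retained proteins present; >= 80%% required",
                      100 * overlap))
  if (length(present) < length(retained)) {
    warning(length(retained) - length(present),
            " retained proteins missing from new matrix; dropped")
  }
  if (model$zscore_first) {
    new_matrix <- t(scale(t(new_matrix)))
    new_matrix[is.na(new_matrix)] <- 0
  }
  keep <- rownames(model$stats$dik) %in% present
  st <- model$stats
  st_sub <- st
  st_sub$overall <- st$overall[keep]
  st_sub$centroids <- st$centroids[keep, , drop = FALSE]
  st_sub$s <- st$s[keep]
  st_sub$dik <- st$dik[keep, , drop = FALSE]
  pred <- nsc_predict_delta(st_sub, model$priors,
                            new_matrix[present, , drop = FALSE][
                              rownames(st_sub$dik), , drop = FALSE],
                            delta)
  sc <- pred$delta_scores
  prob <- exp(-0.5 * (sc - apply(sc, 1, min)))
  prob <- prob / rowSums(prob)
  colnames(prob) <- st$levels
  tie <- apply(sc, 1, function(r) sum(r == min(r)) > 1)
  out <- data.frame(sample = colnames(new_matrix),
                    label = pred$labels, tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(prob))
}
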