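#' Remove proteins quantified in too few samples
#'
#' Retains exactly the proteins observed (non-missing) in at least
#' `min_frac` of samples; the default reproduces the pipeline's "identified
#' in < 75% of samples were removed" rule. The sample set is unchanged.
#'
#' @param matrix protein-by-sample numeric matrix, `NA` for missing.
#' @param min_frac minimum fraction of samples in which a protein must be
#'   observed, in (0, 1].
#' @return The filtered matrix. Warns (rather than silently failing) if no
#'   protein survives.
#' @export
filter_completeness <- function(matrix, min_frac = 0.75) {
  assert_matrix(matrix, "matrix")
  assert_that(min_frac > 0 && min_frac <= 1, "min_frac must lie in (0,1]")
  frac_obs <- rowMeans(!is.na(matrix))
  keep <- frac_obs >= min_frac
  if (!any(keep)) {
    warning("completeness filter removed every protein (min_frac = ",
            min_frac, ")")
  }
  matrix[keep, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing protein values
#'
#' Each missing cell is replaced by the unweighted mean, at that sample, of
#' the `k` nearest protein rows. Distances are Euclidean over co-observed
#' samples, rescaled by `sqrt(n_samples / n_shared)` to correct for unequal
#' overlap; only neighbours observed at the target sample are eligible.
#' Observed cells are never modified.
#'
#' @param matrix protein-by-sample matrix with `NA` for missing entries;
#'   every protein must have at least one observed value.
#' @param k number of neighbours (default 10, the conventional default of
#'   the originating algorithm). If fewer candidates exist, all available
#'   are used and a warning is issued.
#' @return The completed matrix.
#' @export
knn_impute <- function(matrix, k = 10) {
  assert_matrix(matrix, "matrix")
  assert_that(k >= 1, "k must be >= 1")
  assert_that(all(rowSums(!is.na(matrix)) >= 1),
              "every protein needs at least one observed value")
  miss_rows <- which(rowSums(is.na(matrix)) > 0)
  if (length(miss_rows) == 0) return(matrix)

  p <- nrow(matrix); n <- ncol(matrix)
  out <- matrix
  short_of_neighbours <- FALSE
  obs <- !is.na(matrix)
  for (i in miss_rows) {
    xi <- matrix[i, ]
    # overlap-rescaled Euclidean distance to every other row
    shared <- obs & rep(obs[i, ], each = p)       # p x n logical
    diffs <- sweep(matrix, 2, xi, "-")
    diffs[!shared] <- 0
    n_shared <- rowSums(shared)
    d2 <- rowSums(diffs^2, na.rm = TRUE)
    d <- ifelse(n_shared > 0, sqrt(d2 * n / n_shared), Inf)
    d[i] <- Inf
    for (s in which(is.na(xi))) {
      cand <- which(obs[, s] & is.finite(d))
      if (length(cand) == 0) next
      if (length(cand) < k) short_of_neighbours <- TRUE
      nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      out[i, s] <- mean(matrix[nb, s])
    }
  }
  if (short_of_neighbours) {
    warning("fewer than k candidate neighbours for some cells; ",
            "used all available")
  }
  out
}

#' Reference-channel ratio and log2 transform
#'
#' Step 1-2 of the normalisation pipeline: within each plex, every sample
#' channel is divided by the pooled-reference channel protein-wise, then
#' log2-transformed, and the per-batch results are assembled into one
#' protein-by-sample matrix. Proteins with a zero, negative or missing
#' reference intensity in a batch are flagged and excluded (set missing)
#' for that batch, with a message giving the count.
#'
#' @param raw a `raw_intensity_set` (see [generate_raw_plexes()]).
#' @return protein-by-sample matrix of log2 sample/reference ratios.
#' @export
ratio_log2 <- function(raw) {
  assert_that(inherits(raw, "raw_intensity_set"),
              "raw must be a raw_intensity_set")
  p <- length(raw$protein_ids)
  out <- matrix(NA_real_, p, length(raw$sample_ids),
                dimnames = list(raw$protein_ids, raw$sample_ids))
  n_flagged <- 0L
  for (b in raw$batches) {
    ref <- b$intensities[, b$reference_channel]
    bad <- !is.finite(ref) | ref <= 0
    n_flagged <- n_flagged + sum(bad)
    sample_cols <- names(b$channel_roles)[b$channel_roles == "sample"]
    ratio <- b$intensities[, sample_cols, drop = FALSE] / ref
    ratio[bad, ] <- NA_real_
    out[rownames(ratio), sample_cols] <- log2(ratio)
  }
  if (n_flagged > 0) {
    message(n_flagged,
            " protein-batch entries excluded: non-positive reference intensity")
  }
  out
}

#' Centre each protein across samples
#'
#' Step 3 of the normalisation pipeline: subtracts the per-protein median
#' (default) or mean, computed across all samples, from each row.
#'
#' @param matrix protein-by-sample matrix.
#' @param stat `"median"` (default) or `"mean"`.
#' @return The row-centred matrix.
#' @export
center_proteins <- function(matrix, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  assert_matrix(matrix, "matrix")
  ctr <- if (stat == "median") {
    apply(matrix, 1, stats::median, na.rm = TRUE)
  } else {
    rowMeans(matrix, na.rm = TRUE)
  }
  sweep(matrix, 1, ctr, "-")
}

#' Standardise each sample column
#'
#' Step 4 of the normalisation pipeline: z-scores every sample column to
#' mean 0 and standard deviation 1 (ignoring missing values).
#'
#' @param matrix protein-by-sample matrix.
#' @return The column-standardised matrix.
#' @export
standardize_samples <- function(matrix) {
  assert_matrix(matrix, "matrix")
  mu <- colMeans(matrix, na.rm = TRUE)
  sdv <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  sdv[sdv == 0] <- 1
  sweep(sweep(matrix, 2, mu, "-"), 2, sdv, "/")
}

#' Full pooled-reference normalisation pipeline
#'
#' Runs, in order: (1) per-batch sample/reference ratio, (2) log2,
#' (3) per-protein median centring across samples, (4) per-sample
#' standardisation. Optionally applies the completeness filter and kNN
#' imputation between steps 2 and 3, matching the order used for the
#' sarcoma cohort (filter, impute, then normalise).
#'
#' @param raw a `raw_intensity_set`.
#' @param min_frac completeness threshold passed to [filter_completeness()];
#'   `NULL` to skip filtering.
#' @param impute_k `k` for [knn_impute()]; `NULL` to skip imputation.
#' @return protein-by-sample normalised matrix (log2-ratio scale, centred,
#'   standardised), with attribute `provenance` recording the steps applied.
#' @export
reference_ratio_normalize <- function(raw, min_frac = 0.75, impute_k = 10) {
  m <- ratio_log2(raw)
  steps <- c("ratio", "log2")
  if (!is.null(min_frac)) {
    m <- filter_completeness(m, min_frac)
    steps <- c(steps, "filtered")
  }
  if (!is.null(impute_k) && any(is.na(m))) {
    m <- knn_impute(m, impute_k)
    steps <- c(steps, "imputed")
  }
  m <- center_proteins(m, "median")
  m <- standardize_samples(m)
  attr(m, "provenance") <- c(steps, "centred", "standardised")
  m
}

#' Tumour-infiltrating lymphocyte density from replicate core counts
#'
#' Converts raw lymphocyte counts from replicate tissue-microarray cores to
#' a cells-per-mm^2 density: cores with section preservation below 50% are
#' excluded; remaining counts are corrected to 100% area (divided by the
#' preservation fraction); replicates are averaged; and the mean is
#' multiplied by the fixed microscope-field factor 1.274.
#'
#' @param core_counts non-negative lymphocyte counts, one per core.
#' @param preservation_fraction per-core section preservation in \[0, 1\].
#' @param field_factor count-to-density conversion factor (default 1.274).
#' @return A list: `status` (`"ok"` or `"excluded"`), `density`
#'   (cells/mm^2, `NA` when excluded) and `n_cores_used`.
#' @export
til_density <- function(core_counts, preservation_fraction,
                        field_factor = 1.274) {
  assert_that(length(core_counts) >= 1, "at least one core required")
  assert_that(length(core_counts) == length(preservation_fraction),
              "one preservation fraction per core required")
  assert_that(all(core_counts >= 0), "invalid input: negative core counts")
  assert_that(all(preservation_fraction >= 0 & preservation_fraction <= 1),
              "preservation fractions must lie in [0,1]")
  keep <- preservation_fraction >= 0.5
  if (!any(keep)) {
    return(list(status = "excluded", density = NA_real_, n_cores_used = 0L))
  }
  corrected <- core_counts[keep] / preservation_fraction[keep]
  list(status = "ok",
       density = mean(corrected) * field_factor,
       n_cores_used = sum(keep))
}

#' Stratify samples as high/low around the cohort median
#'
#' A sample is `"high"` iff its value is greater than or equal to the cohort
#' median (ties at the median go high, for determinism).
#'
#' @param values named numeric vector (one value per sample).
#' @return A list: `strata` (named character vector, `"high"`/`"low"`) and
#'   `median` (the threshold used). Warns if all values are identical (all
#'   samples then go high).
#' @export
stratify_by_median <- function(values) {
  assert_that(length(values) >= 2, "at least 2 samples required")
  m <- stats::median(values, na.rm = TRUE)
  if (length(unique(values[!is.na(values)])) == 1) {
    warning("all values identical: every sample assigned 'high'")
  }
  strata <- ifelse(values >= m, "high", "low")
  names(strata) <- names(values)
  list(strata = strata, median = m)
}
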