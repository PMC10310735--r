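#' Configuration for a synthetic multi-plex proteomic cohort
#'
#' Describes the statistical structure of a simulated soft-tissue-sarcoma-like
#' cohort quantified in multiplexed batches (plexes) with a pooled reference
#' channel: subtype mean-shift markers, correlated co-expression modules,
#' batch effects, abundance-dependent missingness, proportional-hazards
#' survival tied to the planted structure, and a paired transcriptome with
#' controlled per-gene mRNA-protein Spearman correlation.
#'
#' @param n_samples number of tumour samples in the cohort.
#' @param n_proteins number of quantified proteins.
#' @param n_subtypes number of histological/molecular subtypes (>= 2).
#' @param subtype_proportions mixing weights over subtypes (sum to 1);
#'   defaults to equal proportions.
#' @param subtype_effect mean shift, in log2 units, applied to each subtype's
#'   marker proteins in samples of that subtype.
#' @param n_marker_proteins_per_subtype number of marker proteins planted per
#'   subtype (disjoint blocks).
#' @param module_sizes integer vector of planted co-expression module sizes.
#' @param module_within_correlation target within-module pairwise Pearson
#'   correlation of log2 abundances, in \[0, 1); scalar or one value per module.
#' @param plex_size samples per multiplexed batch (each batch additionally
#'   carries one pooled-reference channel).
#' @param plex_assignment `"randomised"` (default) or `"grouped"` (samples
#'   ordered by subtype before being chunked into plexes).
#' @param batch_sd standard deviation of the per-batch log2 offset.
#' @param noise_sd standard deviation of the per-measurement log2 noise.
#' @param base_log2_mean,base_log2_sd parameters of the log-normal base
#'   abundance distribution (log2 scale); sd 1.5 mimics the proteome's
#'   dynamic range.
#' @param missing_rate overall target fraction of missing sample-channel
#'   entries, in \[0, 1).
#' @param mnar_strength abundance dependence of missingness (probit link on
#'   negative standardised abundance); 0 gives purely random missingness.
#' @param survival_betas named numeric vector of log-hazard coefficients for
#'   planted features; names refer to `"subtype<k>"` indicators or
#'   `"module<m>"` latent factors (e.g. `c(module1 = 0.7)`).
#' @param censoring_rate target fraction of randomly censored records.
#' @param followup_cap administrative follow-up cap in years.
#' @param baseline_hazard event rate per year at linear predictor 0.
#' @param rho_mixture list describing the per-gene mRNA-protein Spearman
#'   correlation targets: `prop_correlated` (fraction of genes given
#'   `rho_correlated`), `rho_correlated`, and `rho_null` for the rest.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_samples = 321,
                          n_proteins = 2000,
                          n_subtypes = 3,
                          subtype_proportions = NULL,
                          subtype_effect = 1.0,
                          n_marker_proteins_per_subtype = 50,
                          module_sizes = c(50, 50, 50, 50),
                          module_within_correlation = 0.7,
                          plex_size = 10,
                          plex_assignment = c("randomised", "grouped"),
                          batch_sd = 0.3,
                          noise_sd = 0.5,
                          base_log2_mean = 20,
                          base_log2_sd = 1.5,
                          missing_rate = 0,
                          mnar_strength = 0,
                          survival_betas = c(module1 = 0.7),
                          censoring_rate = 0.3,
                          followup_cap = 5,
                          baseline_hazard = log(2) / 3,
                          rho_mixture = list(prop_correlated = 0.2,
                                             rho_correlated = 0.7,
                                             rho_null = 0),
                          seed = 1L) {
  plex_assignment <- match.arg(plex_assignment)
  if (is.null(subtype_proportions)) {
    subtype_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_proteins = as.integer(n_proteins),
    n_subtypes = as.integer(n_subtypes),
    subtype_proportions = subtype_proportions,
    subtype_effect = subtype_effect,
    n_marker_proteins_per_subtype = as.integer(n_marker_proteins_per_subtype),
    module_sizes = as.integer(module_sizes),
    module_within_correlation = module_within_correlation,
    plex_size = as.integer(plex_size), plex_assignment = plex_assignment,
    batch_sd = batch_sd, noise_sd = noise_sd,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    missing_rate = missing_rate, mnar_strength = mnar_strength,
    survival_betas = survival_betas,
    censoring_rate = censoring_rate, followup_cap = followup_cap,
    baseline_hazard = baseline_hazard,
    rho_mixture = rho_mixture, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  assert_that(cfg$n_subtypes >= 2, "invalid config: n_subtypes must be >= 2")
  assert_that(abs(sum(cfg$subtype_proportions) - 1) <= 1e-9,
              "invalid config: subtype_proportions must sum to 1")
  assert_that(length(cfg$subtype_proportions) == cfg$n_subtypes,
              "invalid config: one proportion per subtype required")
  assert_that(cfg$plex_size >= 2, "invalid config: plex_size must be >= 2")
  n_planted <- sum(cfg$module_sizes) +
    cfg$n_subtypes * cfg$n_marker_proteins_per_subtype
  assert_that(n_planted <= cfg$n_proteins,
              "invalid config: module_sizes and marker blocks exceed n_proteins")
  assert_that(all(cfg$module_within_correlation >= 0 &
                    cfg$module_within_correlation < 1),
              "invalid config: module_within_correlation must lie in [0,1)")
  assert_that(cfg$missing_rate >= 0 && cfg$missing_rate < 1,
              "invalid config: missing_rate must lie in [0,1)")
  assert_that(cfg$mnar_strength >= 0,
              "invalid config: mnar_strength must be >= 0")
  assert_that(cfg$followup_cap > 0,
              "invalid config: followup_cap must be positive")
  invisible(cfg)
}

#' Generate raw multi-plex intensities with known ground truth
#'
#' Simulates per-plex protein-by-channel intensity matrices. Each plex holds
#' `plex_size` sample channels (the last plex may be partial) plus one pooled
#' reference channel whose value per protein is the cohort-mean abundance,
#' sharing the plex's batch effect so that sample/reference ratios cancel it.
#' Sample intensities are
#' `2^(base + subtype shift + module latent factor + batch + noise)`;
#' missingness is a mixture of completely-at-random dropout and a probit
#' abundance-dependent (MNAR) component controlled by `mnar_strength`.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `raw` (a `raw_intensity_set`: `batches`, each
#'   with `intensities`, `channel_roles`, `reference_channel`; plus
#'   `protein_ids`, `sample_ids`, `batch_of_sample`) and `truth` (a
#'   `ground_truth`: `subtype_labels`, `module_membership`,
#'   `marker_membership`, `module_factors`, `true_rho`, `true_hazard_coefs`,
#'   `cohort_mean_abundance`, `seed`).
#' @export
generate_raw_plexes <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_proteins
    protein_ids <- sprintf("prot%04d", seq_len(p))
    sample_ids <- sprintf("S%03d", seq_len(n))

    subtype <- sample.int(config$n_subtypes, n, replace = TRUE,
                          prob = config$subtype_proportions)
    names(subtype) <- sample_ids

    # disjoint planted blocks: modules first, then subtype marker blocks
    n_mod <- length(config$module_sizes)
    module_membership <- rep(NA_integer_, p)
    idx <- 1L
    for (m in seq_len(n_mod)) {
      module_membership[idx:(idx + config$module_sizes[m] - 1L)] <- m
      idx <- idx + config$module_sizes[m]
    }
    marker_membership <- rep(NA_integer_, p)
    for (k in seq_len(config$n_subtypes)) {
      if (config$n_marker_proteins_per_subtype > 0) {
        marker_membership[idx:(idx + config$n_marker_proteins_per_subtype - 1L)] <- k
        idx <- idx + config$n_marker_proteins_per_subtype
      }
    }
    names(module_membership) <- names(marker_membership) <- protein_ids

    base <- stats::rnorm(p, config$base_log2_mean, config$base_log2_sd)

    # subtype mean shifts on marker proteins
    shift <- matrix(0, p, n)
    for (k in seq_len(config$n_subtypes)) {
      rows <- which(marker_membership == k)
      cols <- which(subtype == k)
      if (length(rows) && length(cols)) {
        shift[rows, cols] <- config$subtype_effect
      }
    }

    # module latent factors: cor = lambda^2 / (lambda^2 + noise_sd^2)
    rho <- rep_len(config$module_within_correlation, n_mod)
    factors <- matrix(stats::rnorm(n_mod * n), n_mod, n,
                      dimnames = list(NULL, sample_ids))
    latent <- matrix(0, p, n)
    for (m in seq_len(n_mod)) {
      lambda <- if (rho[m] > 0) config$noise_sd * sqrt(rho[m] / (1 - rho[m])) else 0
      rows <- which(module_membership == m)
      latent[rows, ] <- matrix(rep(lambda * factors[m, ], each = length(rows)),
                               nrow = length(rows))
    }

    signal_log2 <- base + shift + latent        # noise-free, batch-free
    cohort_mean_abundance <- rowMeans(2^signal_log2)
    names(cohort_mean_abundance) <- protein_ids

    # plex layout
    order_samples <- if (config$plex_assignment == "grouped") {
      order(subtype)
    } else {
      sample.int(n)
    }
    n_batches <- ceiling(n / config$plex_size)
    batch_of_sample <- integer(n)
    batch_of_sample[order_samples] <-
      rep(seq_len(n_batches), each = config$plex_size, length.out = n)
    names(batch_of_sample) <- sample_ids
    batch_offset <- stats::rnorm(n_batches, 0, config$batch_sd)

    noise <- matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
    log2_full <- signal_log2 + noise +
      matrix(rep(batch_offset[batch_of_sample], each = p), p, n)

    # missingness: MCAR/MNAR mixture on sample channels only
    miss <- matrix(FALSE, p, n)
    if (config$missing_rate > 0) {
      if (config$mnar_strength > 0) {
        z <- (log2_full - mean(log2_full)) / stats::sd(log2_full)
        w <- stats::pnorm(-config$mnar_strength * z)
        pr <- pmin(1, config$missing_rate * w / mean(w))
      } else {
        pr <- matrix(config$missing_rate, p, n)
      }
      miss <- matrix(stats::runif(p * n) < pr, p, n)
    }

    intensities <- 2^log2_full
    intensities[miss] <- NA_real_
    dimnames(intensities) <- list(protein_ids, sample_ids)

    batches <- vector("list", n_batches)
    for (b in seq_len(n_batches)) {
      cols <- sample_ids[batch_of_sample == b]
      ref <- cohort_mean_abundance * 2^batch_offset[b]
      mat <- cbind(intensities[, cols, drop = FALSE], ref)
      ref_id <- sprintf("ref_b%02d", b)
      colnames(mat) <- c(cols, ref_id)
      roles <- c(rep("sample", length(cols)), "reference")
      names(roles) <- colnames(mat)
      batches[[b]] <- list(intensities = mat, channel_roles = roles,
                           reference_channel = ref_id)
    }

    raw <- structure(
      list(batches = batches, protein_ids = protein_ids,
           sample_ids = sample_ids, batch_of_sample = batch_of_sample),
      class = "raw_intensity_set")

    # per-gene mRNA-protein correlation targets
    rm <- config$rho_mixture
    is_cor <- stats::runif(p) < rm$prop_correlated
    true_rho <- ifelse(is_cor, rm$rho_correlated, rm$rho_null)
    names(true_rho) <- protein_ids

    truth <- structure(
      list(subtype_labels = subtype,
           module_membership = module_membership,
           marker_membership = marker_membership,
           module_factors = factors,
           true_rho = true_rho,
           true_hazard_coefs = config$survival_betas,
           cohort_mean_abundance = cohort_mean_abundance,
           batch_offsets = batch_offset,
           seed = config$seed),
      class = "ground_truth")

    list(raw = raw, truth = truth)
  })
}

#' Generate a paired transcriptome with controlled Spearman concordance
#'
#' For each gene, emits an mRNA row whose Spearman correlation with the
#' corresponding protein row matches the planted target `truth$true_rho`
#' (within sampling error), via a Gaussian copula on ranks: the protein row's
#' normal scores are mixed with independent noise at the Pearson coefficient
#' `2*sin(pi*rho/6)` that yields the requested Spearman coefficient for a
#' bivariate Gaussian.
#'
#' @param protein_matrix normalised protein-by-sample matrix (genes to emit
#'   are its rows that appear in `truth$true_rho`).
#' @param truth a `ground_truth` from [generate_raw_plexes()], or any list
#'   with a named `true_rho` vector and a `seed`.
#' @param seed RNG seed; defaults to `truth$seed + 1`.
#' @return genes-by-samples mRNA matrix with the same dimnames subset.
#' @export
generate_paired_transcriptome <- function(protein_matrix, truth, seed = NULL) {
  assert_matrix(protein_matrix, "protein_matrix")
  genes <- intersect(rownames(protein_matrix), names(truth$true_rho))
  assert_that(length(genes) > 0, "no genes with a defined correlation target")
  rho <- truth$true_rho[genes]
  assert_that(all(abs(rho) <= 1),
              "invalid config: |true_rho| must not exceed 1")
  seed <- seed %||% (truth$seed + 1L)
  with_seed(seed, {
    n <- ncol(protein_matrix)
    out <- matrix(NA_real_, length(genes), n,
                  dimnames = list(genes, colnames(protein_matrix)))
    r <- 2 * sin(pi * rho / 6)    # Pearson on normal scores -> Spearman target
    for (i in seq_along(genes)) {
      x <- protein_matrix[genes[i], ]
      u <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
      out[i, ] <- r[i] * u + sqrt(max(0, 1 - r[i]^2)) * stats::rnorm(n)
    }
    out
  })
}

#' Simulate clinical covariates and survival endpoints
#'
#' Draws event times for local recurrence, metastasis and death from
#' independent exponential proportional-hazards models with linear predictor
#' `sum(beta * feature)` over the planted features named in
#' `config$survival_betas` (`"subtype<k>"` indicators or `"module<m>"` latent
#' factors). Random censoring is calibrated to `censoring_rate`; the
#' administrative 5-year-style cap is applied downstream by
#' [build_endpoints()]. Clinical covariates (grade, size, depth, margin, age,
#' sex, performance status) are generated independently of the planted risk.
#'
#' @param truth a `ground_truth` from [generate_raw_plexes()].
#' @param config the generating [cohort_config()].
#' @param seed RNG seed; defaults to `truth$seed + 2`.
#' @return A `data.frame` (clinical table): one row per sample with covariate
#'   columns, raw event times in years (`time_to_local_recurrence`,
#'   `time_to_metastasis`, `time_to_death`; `NA` when unobserved) and
#'   `last_followup`.
#' @export
simulate_survival <- function(truth, config, seed = NULL) {
  validate_cohort_config(config)
  betas <- config$survival_betas
  n <- length(truth$subtype_labels)
  samples <- names(truth$subtype_labels)

  feat <- function(name) {
    if (grepl("^subtype[0-9]+$", name)) {
      k <- as.integer(sub("subtype", "", name))
      assert_that(k <= config$n_subtypes,
                  paste("survival beta references unknown feature", name))
      as.numeric(truth$subtype_labels == k)
    } else if (grepl("^module[0-9]+$", name)) {
      m <- as.integer(sub("module", "", name))
      assert_that(m <= nrow(truth$module_factors),
                  paste("survival beta references unknown feature", name))
      truth$module_factors[m, ]
    } else {
      stop("survival beta references unknown feature ", name, call. = FALSE)
    }
  }
  lp <- rep(0, n)
  for (nm in names(betas)) lp <- lp + betas[[nm]] * feat(nm)

  seed <- seed %||% (truth$seed + 2L)
  with_seed(seed, {
    lambda <- config$baseline_hazard * exp(lp)
    draw <- function() stats::rexp(n, rate = lambda)
    t_death <- draw(); t_lr <- draw(); t_met <- draw()

    cens <- if (config$censoring_rate > 0) {
      rate_c <- config$baseline_hazard * config$censoring_rate /
        (1 - config$censoring_rate)
      stats::rexp(n, rate = rate_c)
    } else {
      rep(Inf, n)
    }
    # generous administrative horizon; endpoint construction applies the cap
    horizon <- pmin(cens, 4 * config$followup_cap)

    obs <- function(t) ifelse(t <= horizon, t, NA_real_)
    data.frame(
      sample = samples,
      subtype = as.integer(truth$subtype_labels),
      age = round(stats::rnorm(n, 60, 15)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.35, 0.45)),
      size_cm = round(exp(stats::rnorm(n, log(7), 0.6)), 1),
      depth = sample(c("deep", "superficial"), n, replace = TRUE,
                     prob = c(0.8, 0.2)),
      margin = sample(c("R0", "R1"), n, replace = TRUE, prob = c(0.75, 0.25)),
      performance_status = sample(0:2, n, replace = TRUE,
                                  prob = c(0.6, 0.3, 0.1)),
      time_to_local_recurrence = obs(t_lr),
      time_to_metastasis = obs(t_met),
      time_to_death = obs(t_death),
      last_followup = horizon,
      risk_score = lp,
      stringsAsFactors = FALSE)
  })
}
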