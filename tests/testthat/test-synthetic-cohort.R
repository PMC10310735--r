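test_that("config validation rejects impossible cohorts", {
  expect_error(cohort_config(n_subtypes = 1), "n_subtypes")
  expect_error(cohort_config(subtype_proportions = c(0.5, 0.4),
                             n_subtypes = 2), "sum to 1")
  expect_error(cohort_config(n_proteins = 50, module_sizes = c(40, 40)),
               "exceed")
  expect_error(cohort_config(plex_size = 1), "plex_size")
  expect_error(cohort_config(followup_cap = -1), "followup_cap")
})

test_that("identical config and seed give bit-identical output", {
  cfg <- cohort_config(n_samples = 25, n_proteins = 60, seed = 42,
                       module_sizes = c(20), missing_rate = 0.1,
                       n_marker_proteins_per_subtype = 10,
                       mnar_strength = 1)
  a <- generate_raw_plexes(cfg)
  b <- generate_raw_plexes(cfg)
  expect_identical(a, b)
  expect_identical(simulate_survival(a$truth, cfg),
                   simulate_survival(b$truth, cfg))
})

test_that("plex layout has one reference channel per batch and the right sizes", {
  cfg <- cohort_config(n_samples = 23, n_proteins = 40, plex_size = 10,
                       module_sizes = c(15),
                       n_marker_proteins_per_subtype = 5, seed = 3)
  sim <- generate_raw_plexes(cfg)
  expect_length(sim$raw$batches, 3)  # ceil(23/10)
  roles <- lapply(sim$raw$batches, function(b) table(b$channel_roles))
  expect_true(all(vapply(roles, function(r) r[["reference"]] == 1, logical(1))))
  expect_equal(sum(vapply(roles, function(r) r[["sample"]], numeric(1))), 23)
})

test_that("null-effect configuration gives sample/reference ratios of exactly 1", {
  cfg <- cohort_config(n_samples = 20, n_proteins = 30, subtype_effect = 0,
                       module_sizes = integer(0),
                       n_marker_proteins_per_subtype = 0,
                       module_within_correlation = 0, missing_rate = 0,
                       batch_sd = 0, noise_sd = 0, seed = 5)
  sim <- generate_raw_plexes(cfg)
  for (b in sim$raw$batches) {
    ref <- b$intensities[, b$reference_channel]
    smp <- b$intensities[, names(b$channel_roles)[b$channel_roles == "sample"],
                         drop = FALSE]
    expect_equal(as.vector(smp / ref), rep(1, length(smp)))
  }
})

test_that("reference channel equals the per-protein cohort-mean abundance", {
  cfg <- cohort_config(n_samples = 30, n_proteins = 50, batch_sd = 0,
                       module_sizes = c(20),
                       n_marker_proteins_per_subtype = 5,
                       missing_rate = 0, seed = 8)
  sim <- generate_raw_plexes(cfg)
  for (b in sim$raw$batches) {
    expect_identical(unname(b$intensities[, b$reference_channel]),
                     unname(sim$truth$cohort_mean_abundance))
  }
})

test_that("missingness is monotone in abundance when mnar_strength > 0", {
  cfg <- cohort_config(n_samples = 40, n_proteins = 400, module_sizes = c(50),
                       n_marker_proteins_per_subtype = 20,
                       missing_rate = 0.25, mnar_strength = 1.5, seed = 9)
  sim <- generate_raw_plexes(cfg)
  all_int <- do.call(cbind, lapply(sim$raw$batches, function(b) {
    b$intensities[, names(b$channel_roles)[b$channel_roles == "sample"],
                  drop = FALSE]
  }))
  base <- log2(sim$truth$cohort_mean_abundance)
  qs <- quantile(base, c(0.25, 0.75))
  low_miss <- mean(is.na(all_int[base <= qs[1], ]))
  high_miss <- mean(is.na(all_int[base >= qs[2], ]))
  expect_gt(low_miss, high_miss)
  # overall rate close to the configured target
  expect_lt(abs(mean(is.na(all_int)) - 0.25), 0.05)
})

test_that("planted module correlation matches the latent-factor closed form", {
  # cor = lambda^2 / (lambda^2 + sigma^2); average over seeds vs target 0.8
  cors <- vapply(1:12, function(sd) {
    cfg <- cohort_config(n_samples = 40, n_proteins = 80,
                         module_sizes = c(50),
                         module_within_correlation = 0.8,
                         n_marker_proteins_per_subtype = 5,
                         subtype_effect = 0, batch_sd = 0,
                         missing_rate = 0, seed = sd)
    sim <- generate_raw_plexes(cfg)
    log2_int <- log2(sim$raw$batches[[1]]$intensities)
    cols <- names(sim$raw$batches[[1]]$channel_roles)[
      sim$raw$batches[[1]]$channel_roles == "sample"]
    all_cols <- do.call(cbind, lapply(sim$raw$batches, function(b) {
      log2(b$intensities[, names(b$channel_roles)[b$channel_roles == "sample"],
                         drop = FALSE])
    }))
    members <- which(sim$truth$module_membership == 1)
    cm <- cor(t(all_cols[members, ]))
    mean(cm[lower.tri(cm)])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.8), 0.05)
})

test_that("paired transcriptome hits its Spearman targets", {
  sim <- small_cohort(seed = 21)
  truth <- sim$truth
  # rho = 1: monotone transform, sample Spearman exactly 1
  truth$true_rho[] <- 0
  truth$true_rho[1:5] <- 1
  mr <- generate_paired_transcriptome(sim$norm, truth)
  for (g in names(truth$true_rho)[1:5]) {
    expect_equal(cor(sim$norm[g, ], mr[g, ], method = "spearman"), 1)
  }
  # rho = 0 at n = 25: mean |rho| stays near the null sampling level
  rhos <- unlist(lapply(1:30, function(sd) {
    x <- matrix(rnorm(3 * 25), 3, 25,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:25)))
    tr <- list(true_rho = setNames(rep(0, 3), rownames(x)), seed = sd)
    y <- generate_paired_transcriptome(x, tr)
    vapply(1:3, function(i) cor(x[i, ], y[i, ], method = "spearman"),
           numeric(1))
  }))
  expect_lt(abs(mean(rhos)), 0.1)
  expect_lt(mean(abs(rhos)), 2.5 * 0.7979 / sqrt(24))  # null |rho| scale
  # rho > 1 rejected
  truth$true_rho[1] <- 1.2
  expect_error(generate_paired_transcriptome(sim$norm, truth), "true_rho")
})

test_that("planted rho mixture is recovered at the power of the Spearman test", {
  # n = 25 samples, 20% of genes at rho 0.7: the recovered positive-significant
  # fraction after BH should match the test's power within 5 points
  n <- 25; p <- 400
  hits <- numeric(10); planted <- numeric(10)
  for (sd in 1:10) {
    set.seed(sd)
    x <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("g%03d", 1:p), sprintf("s%02d", 1:n)))
    rho <- ifelse(runif(p) < 0.2, 0.7, 0)
    tr <- list(true_rho = setNames(rho, rownames(x)), seed = sd + 100)
    y <- generate_paired_transcriptome(x, tr)
    cc <- correlate_layers(pair_layers(x, y))
    hits[sd] <- mean(cc$class == "positive-significant")
    planted[sd] <- mean(rho > 0)
  }
  # independent power estimate for Spearman at n=25 under the same BH regime
  pow <- mean(vapply(1:10, function(sd) {
    set.seed(1000 + sd)
    ps <- vapply(1:400, function(i) {
      r <- 2 * sin(pi * 0.7 / 6)
      u <- rnorm(25); v <- r * u + sqrt(1 - r^2) * rnorm(25)
      suppressWarnings(cor.test(u, v, method = "spearman")$p.value)
    }, numeric(1))
    null_ps <- runif(1600)
    q <- p.adjust(c(ps, null_ps), "BH")[1:400]
    mean(q < 0.05)
  }, numeric(1)))
  expected <- mean(planted) * pow
  expect_lt(abs(mean(hits) - expected), 0.05)
})

test_that("survival generator respects caps, censoring and the planted hazard", {
  cfg <- cohort_config(n_samples = 200, n_proteins = 30, module_sizes = c(10),
                       n_marker_proteins_per_subtype = 5,
                       survival_betas = c(subtype2 = 0), censoring_rate = 0,
                       seed = 31)
  sim <- generate_raw_plexes(cfg)
  clin <- simulate_survival(sim$truth, cfg)
  rec <- build_endpoints(clin, cap = 5)
  expect_true(all(rec$time <= 5))
  expect_true(all(rec$time > 0))

  # event beyond the cap is returned censored at the cap
  clin2 <- clin[1, ]
  clin2$time_to_death <- 6.2
  clin2$last_followup <- 8
  clin2$time_to_local_recurrence <- NA
  clin2$time_to_metastasis <- NA
  r2 <- build_endpoints(clin2, cap = 5)
  os <- r2[r2$endpoint == "OS", ]
  expect_equal(os$time, 5)
  expect_equal(os$event, 0L)

  # null betas: log-rank p between planted subtypes is not systematically small
  ps <- vapply(1:15, function(sd) {
    cfgn <- cohort_config(n_samples = 120, n_proteins = 30,
                          module_sizes = c(10),
                          n_marker_proteins_per_subtype = 5,
                          survival_betas = c(subtype2 = 0), seed = sd)
    simn <- generate_raw_plexes(cfgn)
    cl <- simulate_survival(simn$truth, cfgn)
    r <- build_endpoints(cl)
    osr <- r[r$endpoint == "OS", ]
    km_fit(osr, simn$truth$subtype_labels[osr$sample])$logrank_p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), -1)        # computed without error
  expect_lt(mean(ps < 0.05), 0.35)      # far from systematic rejection

  # planted binary effect recovered within the fit's own 95% CI most of the time
  cover <- vapply(1:40, function(sd) {
    cfgb <- cohort_config(n_samples = 300, n_proteins = 30,
                          module_sizes = c(10),
                          n_marker_proteins_per_subtype = 5,
                          survival_betas = c(subtype2 = log(2)),
                          censoring_rate = 0, followup_cap = 50, seed = sd)
    simb <- generate_raw_plexes(cfgb)
    cl <- simulate_survival(simb$truth, cfgb)
    r <- build_endpoints(cl, cap = 50)
    osr <- r[r$endpoint == "OS", ]
    x <- as.numeric(simb$truth$subtype_labels[osr$sample] == 2)
    cf <- cox_fit(osr, data.frame(grp = x))
    cf$coefficients$lower95 <= 2 && cf$coefficients$upper95 >= 2
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})
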