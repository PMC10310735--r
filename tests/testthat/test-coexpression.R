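test_that("signed-hybrid adjacency matches elementwise brute force", {
  expect_equal(signed_hybrid_adjacency(matrix(-0.3, 1, 1), 5)[1, 1], 1)  # diag
  cm <- matrix(c(1, -0.3, -0.3, 1), 2, 2)
  expect_equal(signed_hybrid_adjacency(cm, 5)[1, 2], 0)
  cm2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(signed_hybrid_adjacency(cm2, 5)[1, 2], 0.03125)

  set.seed(5)
  r <- matrix(runif(100, -1, 1), 10, 10)
  r <- (r + t(r)) / 2; diag(r) <- 1
  a <- signed_hybrid_adjacency(r, 3)
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 1 else if (r[i, j] > 0) r[i, j]^3 else 0
    expect_equal(a[i, j], expected, tolerance = 1e-14)
  }
})

test_that("TOM dissimilarity matches hand and brute-force evaluation", {
  # 3-node toy: TOM12 = (0.2*0.4 + 0.5) / (min(0.7, 0.9) + 1 - 0.5)
  a <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.4,
                0.2, 0.4, 1), 3, 3)
  d <- tom_dissimilarity(a)
  expect_equal(1 - d[1, 2], 0.58 / 1.2, tolerance = 1e-12)

  # isolated nodes: TOM = 0, dissimilarity 1
  iso <- diag(2)
  expect_equal(tom_dissimilarity(iso)[1, 2], 1)

  # clique: TOM = 1, dissimilarity 0
  cl <- matrix(1, 4, 4)
  expect_equal(max(abs(tom_dissimilarity(cl))), 0)

  # brute force on a random 12-node adjacency, to 1e-12
  set.seed(6)
  r <- matrix(runif(144), 12, 12)
  r <- (r + t(r)) / 2; diag(r) <- 1
  d12 <- tom_dissimilarity(r)
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    l <- sum(vapply(setdiff(1:12, c(i, j)),
                    function(u) r[i, u] * r[u, j], numeric(1)))
    ki <- sum(r[i, -i]); kj <- sum(r[j, -j])
    tom <- (l + r[i, j]) / (min(ki, kj) + 1 - r[i, j])
    expect_equal(1 - d12[i, j], tom, tolerance = 1e-12)
  }
  expect_true(all(1 - d12 >= -1e-12 & 1 - d12 <= 1 + 1e-12))
  expect_error(tom_dissimilarity(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("soft-threshold selection flags structureless data", {
  set.seed(7)
  noise <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(paste0("p", 1:40), paste0("s", 1:30)))
  expect_warning(res <- pick_soft_threshold(noise, beta_grid = 1:8),
                 "unreliable")
  expect_false(res$reliable)

  # modular cohorts: the suggestion tracks the power with the best fit
  diffs <- vapply(c(31, 32, 33, 34, 35, 36), function(sd) {
    sim <- small_cohort(seed = sd)
    res2 <- suppressWarnings(pick_soft_threshold(sim$norm, beta_grid = 1:10))
    expect_true(res2$suggested_beta %in% 1:10)
    usable <- res2$table$mean_k >= 1
    best <- res2$table$beta[usable][which.max(res2$table$sft_r2[usable])]
    abs(res2$suggested_beta - best)
  }, numeric(1))
  expect_lte(median(diffs), 2)
})

test_that("module detection recovers planted blocks and leaves noise ungrouped", {
  cfg <- cohort_config(n_samples = 60, n_proteins = 750,
                       module_sizes = c(40, 45, 50, 55, 60),
                       module_within_correlation = 0.7,
                       n_marker_proteins_per_subtype = 0, subtype_effect = 0,
                       missing_rate = 0, seed = 13)
  sim <- generate_raw_plexes(cfg)
  norm <- reference_ratio_normalize(sim$raw)
  cm <- cor(t(norm))
  diss <- tom_dissimilarity(signed_hybrid_adjacency(cm, 5))
  asg <- detect_modules(diss, norm, min_module_size = 30)

  planted <- sim$truth$module_membership[rownames(norm)]
  jac_best <- vapply(1:5, function(m) {
    members <- names(planted)[which(planted == m)]
    max(vapply(setdiff(unique(asg$membership), "ungrouped"), function(md) {
      got <- names(asg$membership)[asg$membership == md]
      length(intersect(got, members)) / length(union(got, members))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(sum(jac_best >= 0.8), 4)
  noise_ids <- names(planted)[is.na(planted)]
  expect_gte(mean(asg$membership[noise_ids] == "ungrouped"), 0.5)
})

test_that("modules whose summary profiles are close get merged, idempotently", {
  # two blocks driven by the same latent factor: eigengene cor ~ 0.9+
  set.seed(14)
  n <- 50
  f <- rnorm(n)
  b1 <- t(sapply(1:35, function(i) 2 * f + rnorm(n, sd = 0.7)))
  b2 <- t(sapply(1:35, function(i) 2 * f + rnorm(n, sd = 0.7)))
  noise <- matrix(rnorm(60 * n), 60, n)
  m <- rbind(b1, b2, noise)
  dimnames(m) <- list(sprintf("p%03d", 1:130), sprintf("s%02d", 1:n))
  diss <- tom_dissimilarity(signed_hybrid_adjacency(cor(t(m)), 5))
  asg <- detect_modules(diss, m, min_module_size = 30)
  mods <- asg$membership[1:70]
  expect_equal(length(unique(mods)), 1)      # merged into one module

  # re-running the merge changes nothing
  memb2 <- sarcoproteo:::merge_close_modules(m, asg$membership, 0.25)
  expect_identical(memb2, asg$membership)
})

test_that("module detection is invariant to protein reordering", {
  sim <- small_cohort(seed = 15)
  norm <- sim$norm
  diss <- tom_dissimilarity(signed_hybrid_adjacency(cor(t(norm)), 5))
  asg <- detect_modules(diss, norm, min_module_size = 20)
  set.seed(16)
  perm <- sample(nrow(norm))
  normp <- norm[perm, ]
  dissp <- tom_dissimilarity(signed_hybrid_adjacency(cor(t(normp)), 5))
  asgp <- detect_modules(dissp, normp, min_module_size = 20)
  a <- asg$membership[rownames(norm)]
  b <- asgp$membership[rownames(norm)]
  grouped <- a != "ungrouped" | b != "ungrouped"
  expect_gte(adjusted_rand_index(a[grouped], b[grouped]), 0.99)
})

test_that("module scores and tertiles follow the median/tertile rules", {
  m <- toy_matrix(6, 9, seed = 17)
  memb <- setNames(c("M1", "M1", "M1", "ungrouped", "M2", "ungrouped"),
                   rownames(m))
  sc <- module_score(m, memb, "M1")
  expect_equal(sc, apply(m[1:3, ], 2, median))
  # single-protein module: the score is that protein's row
  expect_equal(module_score(m, memb, "M2"), m[5, ])
  expect_error(module_score(m, memb, "M9"), "absent")

  strata <- tertile_stratify(setNames(1:9, paste0("s", 1:9)))
  expect_equal(as.vector(table(strata)), c(3, 3, 3))
  # strata sizes differ by at most one for distinct scores
  for (n in c(10, 11, 14)) {
    st <- tertile_stratify(setNames(seq_len(n) + 0.1, seq_len(n)))
    expect_lte(diff(range(table(st))), 1)
  }
})

test_that("high-scoring module strata carry the planted hazard", {
  hr_ok <- vapply(1:8, function(sd) {
    cfg <- cohort_config(n_samples = 150, n_proteins = 120,
                         module_sizes = c(50), missing_rate = 0,
                         n_marker_proteins_per_subtype = 10,
                         survival_betas = c(module1 = 0.7),
                         censoring_rate = 0.2, seed = sd)
    sim <- generate_raw_plexes(cfg)
    norm <- reference_ratio_normalize(sim$raw)
    clin <- simulate_survival(sim$truth, cfg)
    rec <- build_endpoints(clin)
    os <- rec[rec$endpoint == "OS", ]
    memb <- setNames(ifelse(is.na(sim$truth$module_membership),
                            "ungrouped", "M1"),
                     names(sim$truth$module_membership))
    sc <- module_score(norm, memb, "M1")
    strata <- tertile_stratify(sc[os$sample])
    hl <- strata %in% c("high", "low")
    cf <- cox_fit(os[hl, ], data.frame(high = as.numeric(
      strata[hl] == "high")))
    cf$coefficients$hr > 1 && cf$coefficients$p < 0.1
  }, logical(1))
  expect_gte(mean(hr_ok), 0.7)
})

test_that("edge-list export matches a brute-force scan", {
  s <- matrix(c(1, 0.6, 0.02, 0.3,
                0.6, 1, 0.07, 0.01,
                0.02, 0.07, 1, 0.9,
                0.3, 0.01, 0.9, 1), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  e <- export_edge_list(s, 0.05)
  expect_equal(nrow(e), 4)   # (a,b) (a,d) (b,c) (c,d)
  expect_setequal(paste(e$source, e$target),
                  c("a b", "a d", "b c", "c d"))
  expect_equal(nrow(export_edge_list(s, 1.0)), 0)
  memb <- setNames(c("M1", "M1", "M2", "M2"), letters[1:4])
  ea <- export_edge_list(s, 0.5, memb)
  expect_identical(ea$source_module, c("M1", "M2"))
})
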