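make_clin <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("endpoint construction applies first-event and cap rules", {
  clin <- make_clin(
    sample = c("a", "b", "c", "d"),
    time_to_local_recurrence = c(NA, NA, 2.5, NA),
    time_to_metastasis = c(NA, 1.2, NA, NA),
    time_to_death = c(4.0, 3.0, NA, NA),
    last_followup = c(4.0, 3.0, 4.5, 6.2))
  rec <- build_endpoints(clin, cap = 5)
  # death without recurrence is an LRFS event at the death time
  lr_a <- rec[rec$endpoint == "LRFS" & rec$sample == "a", ]
  expect_equal(lr_a$time, 4.0); expect_equal(lr_a$event, 1L)
  # metastasis then death: MFS takes the first event
  mf_b <- rec[rec$endpoint == "MFS" & rec$sample == "b", ]
  expect_equal(mf_b$time, 1.2); expect_equal(mf_b$event, 1L)
  # event-free 6.2y of follow-up censors at the 5-year cap
  os_d <- rec[rec$endpoint == "OS" & rec$sample == "d", ]
  expect_equal(os_d$time, 5); expect_equal(os_d$event, 0L)
  expect_true(all(rec$time <= 5))
  # non-positive follow-up rejected with a reason
  bad <- make_clin(sample = "z", time_to_local_recurrence = NA,
                   time_to_metastasis = NA, time_to_death = NA,
                   last_followup = 0)
  r2 <- build_endpoints(bad)
  expect_equal(nrow(r2), 0)
  expect_identical(attr(r2, "rejected")$sample, "z")
})

test_that("Kaplan-Meier estimates equal the hand product-limit computation", {
  rec <- data.frame(sample = c("a", "b"), endpoint = "OS",
                    time = c(1, 2), event = c(1L, 1L))
  km <- km_fit(rec)
  expect_equal(km$curves$surv, c(0.5, 0))
  # no events: survival stays at 1
  rec0 <- data.frame(sample = letters[1:3], endpoint = "OS",
                     time = 1:3, event = 0L)
  expect_true(all(km_fit(rec0)$curves$surv == 1))
  # 5-record fixture with censoring, against the hand computation
  rec5 <- data.frame(sample = letters[1:5], endpoint = "OS",
                     time = c(1, 2, 2, 3, 4), event = c(1L, 0L, 1L, 1L, 0L))
  km5 <- km_fit(rec5)
  # events at t=1 (5 at risk), t=2 (4 at risk, 1 event), t=3 (2 at risk);
  # the censorings at t=2 and t=4 leave the curve unchanged
  expect_equal(km5$curves$time, c(1, 2, 3, 4))
  expect_equal(km5$curves$surv,
               c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2,
                 4 / 5 * 3 / 4 * 1 / 2),
               tolerance = 1e-12)
  # identical groups: log-rank p not extreme
  recg <- surv_records(60, seed = 2)
  kmg <- km_fit(recg, rep(c("x", "y"), 30))
  expect_gt(kmg$logrank_p, 0.001)
  expect_error(km_fit(recg, factor(rep("x", 60), levels = c("x", "y"))),
               "empty group")
})

test_that("Cox fits recover planted effects and reject bad inputs", {
  set.seed(3)
  lp <- log(2) * rbinom(300, 1, 0.5)
  rec <- surv_records(300, lp = lp, seed = 3)
  cf <- cox_fit(rec, data.frame(x = as.numeric(lp > 0)))
  expect_gt(cf$coefficients$hr, 1.4)
  expect_lt(cf$coefficients$hr, 2.9)
  expect_true(cf$coefficients$lower95 <= cf$coefficients$hr)
  expect_true(cf$coefficients$upper95 >= cf$coefficients$hr)
  expect_gte(cf$lr_chisq, 0)
  expect_error(cox_fit(rec, data.frame(x = rep(1, 300))), "constant")

  # LR chi-square invariant to affine rescaling of the covariate
  x <- rnorm(300)
  rec2 <- surv_records(300, lp = 0.5 * x, seed = 4)
  f1 <- cox_fit(rec2, data.frame(x = x))
  f2 <- cox_fit(rec2, data.frame(x = 10 * x + 3))
  expect_equal(f1$lr_chisq, f2$lr_chisq, tolerance = 1e-6)

  # complete separation flagged as unstable
  recs <- data.frame(sample = paste0("s", 1:20), endpoint = "OS",
                     time = c(seq(0.1, 1, length.out = 10),
                              seq(10, 20, length.out = 10)),
                     event = 1L)
  w <- testthat::capture_warnings(
    cfs <- cox_fit(recs, data.frame(g = rep(c(1, 0), each = 10))))
  expect_true(any(grepl("extreme hazard", w)))
  expect_true(cfs$unstable)
})

test_that("null Cox fits stay near hazard ratio 1", {
  hrs <- vapply(1:30, function(sd) {
    rec <- surv_records(400, seed = sd)
    cox_fit(rec, data.frame(g = rep(0:1, 200)))$coefficients$coef
  }, numeric(1))
  expect_gte(mean(abs(hrs) < 0.15), 0.9)
})

test_that("hazard screening applies the HR bound, alpha, and intersections", {
  set.seed(6)
  n <- 120
  risk <- rnorm(n)
  samples <- sprintf("S%03d", 1:n)
  rec <- do.call(rbind, lapply(c("OS", "LRFS", "MFS"), function(ep) {
    r <- surv_records(n, lp = log(2.8) * risk, seed = match(ep, c("OS", "LRFS", "MFS")))
    r$sample <- samples; r$endpoint <- ep; r
  }))
  m <- rbind(risk = risk, noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(m) <- samples
  rownames(m) <- c("risk", "noise1", "noise2")
  scr <- screen_features(m, rec)
  # the planted risk feature is significant for every endpoint
  expect_true("risk" %in% scr$all_endpoint_significant)
  # intersection excludes features missing any endpoint
  tab <- scr$table
  for (f in c("noise1", "noise2")) {
    eps_sig <- tab$significant[tab$feature == f]
    if (!all(eps_sig)) {
      expect_false(f %in% scr$all_endpoint_significant)
    }
  }
  # set algebra: the intersection is contained in each per-endpoint set
  for (ep in names(scr$significant)) {
    expect_true(all(scr$all_endpoint_significant %in% scr$significant[[ep]]))
  }
})

test_that("hazard screen is quiet on null cohorts", {
  frac <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 80
    m <- matrix(rnorm(50 * n), 50, n,
                dimnames = list(sprintf("f%02d", 1:50), sprintf("S%03d", 1:n)))
    rec <- surv_records(n, seed = sd)
    rec$sample <- colnames(m)
    mean(screen_features(m, rec)$table$significant)
  }, numeric(1))
  expect_lt(mean(frac), 0.02)
})

test_that("martingale cutpoint finds a planted hazard change point", {
  hits <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 400
    x <- exp(rnorm(n, log(5), 0.5))          # size-like covariate
    lp <- ifelse(x > 5, 1.2, 0)              # hazard jumps at x = 5
    rec <- surv_records(n, lp = lp, seed = sd + 50)
    mc <- martingale_cutpoint(rec, x, log_transform = TRUE)
    abs(mc$cutpoint - 5) / 5
  }, numeric(1))
  expect_lte(median(hits), 0.10)

  # covariate independent of hazard: median fallback may fire; when a
  # crossing exists the cutpoint still lies inside the covariate range
  set.seed(60)
  x <- runif(200, 1, 10)
  rec <- surv_records(200, seed = 61)
  res <- suppressWarnings(martingale_cutpoint(rec, x))
  expect_true(res$cutpoint >= min(x) && res$cutpoint <= max(x))
})

test_that("likelihood-ratio gain reproduces its defining arithmetic", {
  set.seed(8)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  rec <- surv_records(n, lp = 0.5 * x1 + 0.7 * x2, seed = 9)
  base <- cox_fit(rec, data.frame(x1 = x1))
  ext <- cox_fit(rec, data.frame(x1 = x1, x2 = x2))
  g <- lr_gain(base, ext)
  expect_equal(g$delta_chisq, ext$lr_chisq - base$lr_chisq)
  expect_equal(g$gain_pct, 100 * g$delta_chisq / base$lr_chisq)
  expect_gt(g$gain_pct, 0)
  # identical models: zero gain
  g0 <- lr_gain(base, base)
  expect_equal(g0$delta_chisq, 0)
  expect_equal(g0$gain_pct, 0)
  # non-nested models rejected
  other <- cox_fit(rec, data.frame(x2 = x2))
  expect_error(lr_gain(base, other), "nested")
})
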