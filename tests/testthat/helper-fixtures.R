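# Shared fixtures: all synthetic, built in code at test time.

# small named matrix filled from a fixed RNG
toy_matrix <- function(p = 10, n = 8, seed = 1, prefix = "P") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(p)),
                              sprintf("S%02d", seq_len(n))))
  m
}

# two (or more) well-separated spherical sample groups, proteins x samples
blob_matrix <- function(n_per_group = 15, d = 20, centers = c(-3, 3),
                        sd = 1, seed = 1) {
  set.seed(seed)
  cols <- lapply(seq_along(centers), function(g) {
    matrix(rnorm(d * n_per_group, centers[g], sd), d, n_per_group)
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(sprintf("P%03d", seq_len(d)),
                      sprintf("S%03d", seq_len(ncol(m))))
  attr(m, "groups") <- rep(seq_along(centers), each = n_per_group)
  m
}

# compact cohort used by several downstream tests
small_cohort <- function(seed = 11, ...) {
  cfg <- cohort_config(n_samples = 60, n_proteins = 250, n_subtypes = 3,
                       subtype_effect = 1.2, module_sizes = c(40, 40),
                       missing_rate = 0, batch_sd = 0.3, seed = seed, ...)
  sim <- generate_raw_plexes(cfg)
  sim$config <- cfg
  sim$norm <- reference_ratio_normalize(sim$raw)
  sim
}

# survival records with exponential times and a known linear predictor
surv_records <- function(n, lp = rep(0, n), base_rate = 0.2,
                         censor_time = Inf, endpoint = "OS", seed = 1) {
  set.seed(seed)
  t_evt <- rexp(n, rate = base_rate * exp(lp))
  time <- pmin(t_evt, censor_time)
  data.frame(sample = sprintf("S%03d", seq_len(n)), endpoint = endpoint,
             time = time, event = as.integer(t_evt <= censor_time),
             stringsAsFactors = FALSE)
}
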