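#' Build capped survival endpoints from a clinical table
#'
#' Constructs the three study endpoints from raw event times (years from
#' primary surgery): LRFS (local recurrence or death), MFS (metastasis or
#' death) and OS (death from any cause). Event-free samples are censored at
#' their last follow-up; every record is administratively capped at
#' `cap` years (events beyond the cap become censorings at the cap).
#' Records with non-positive follow-up are rejected with a reason.
#'
#' @param clinical `data.frame` with columns `sample`,
#'   `time_to_local_recurrence`, `time_to_metastasis`, `time_to_death`
#'   (`NA` when unobserved) and `last_followup`.
#' @param cap administrative cap in years (default 5).
#' @return A `data.frame` of survival records: sample, endpoint
#'   (`"LRFS"`/`"MFS"`/`"OS"`), time, event (1 event, 0 censored), plus a
#'   `rejected` attribute listing dropped samples and reasons.
#' @export
build_endpoints <- function(clinical, cap = 5) {
  need <- c("sample", "time_to_local_recurrence", "time_to_metastasis",
            "time_to_death", "last_followup")
  assert_that(all(need %in% names(clinical)),
              paste("clinical table must have columns:",
                    paste(need, collapse = ", ")))
  bad <- !is.na(clinical$last_followup) & clinical$last_followup <= 0
  rejected <- data.frame(sample = clinical$sample[bad],
                         reason = rep("non-positive follow-up", sum(bad)),
                         stringsAsFactors = FALSE)
  cl <- clinical[!bad, , drop = FALSE]

  one <- function(event_time, endpoint) {
    t_evt <- pmin(event_time, cl$time_to_death, na.rm = TRUE)
    t_evt[is.na(event_time) & is.na(cl$time_to_death)] <- NA
    has_evt <- !is.na(t_evt)
    time <- ifelse(has_evt, t_evt, cl$last_followup)
    event <- as.integer(has_evt)
    over <- time > cap
    event[over] <- 0L
    time[over] <- cap
    data.frame(sample = cl$sample, endpoint = rep(endpoint, nrow(cl)),
               time = time, event = event, stringsAsFactors = FALSE)
  }
  out <- rbind(one(cl$time_to_local_recurrence, "LRFS"),
               one(cl$time_to_metastasis, "MFS"),
               one(rep(NA_real_, nrow(cl)), "OS"))
  attr(out, "rejected") <- rejected
  out
}

records_surv <- function(records) {
  survival::Surv(records$time, records$event)
}

#' Fit a Cox proportional-hazards model
#'
#' Wraps [survival::coxph()] (Efron tie handling by default) and reports
#' hazard ratios with Wald confidence intervals and p-values, the model
#' log-likelihood and the likelihood-ratio chi-square against the null
#' model. Monotone-likelihood / complete-separation fits are flagged with
#' an infinite-HR warning rather than silently reported.
#'
#' @param records survival records for a single endpoint (columns sample,
#'   time, event).
#' @param covariates `data.frame` of covariate columns, rows aligned with
#'   `records` (or named by sample).
#' @param ties tie-handling method (default `"efron"`).
#' @return A `cox_fit`: `coefficients` table (coef, HR, lower/upper 95% CI,
#'   Wald p), `loglik`, `lr_chisq`, `df`, `n`, `events`,
#'   `unstable` flag, and the underlying `fit`.
#' @export
cox_fit <- function(records, covariates, ties = "efron") {
  assert_that(sum(records$event) >= 1, "need at least one event")
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) &&
      all(records$sample %in% rownames(covariates))) {
    covariates <- covariates[records$sample, , drop = FALSE]
  }
  assert_that(nrow(covariates) == nrow(records),
              "covariates must align with records")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    assert_that(length(unique(v[!is.na(v)])) > 1,
                paste("covariate", nm, "is constant"))
  }
  dat <- cbind(data.frame(.time = records$time, .event = records$event),
               covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  sm <- summary(fit)
  co <- sm$coefficients
  unstable <- any(!is.finite(co[, "coef"])) || any(abs(co[, "coef"]) > 15) ||
    any(!is.finite(sm$conf.int[, "upper .95"]))
  if (unstable) {
    warning("extreme hazard ratio: monotone likelihood / separation suspected")
  }
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(list(
    coefficients = data.frame(
      term = rownames(co), coef = co[, "coef"],
      hr = exp(co[, "coef"]),
      lower95 = sm$conf.int[, "lower .95"],
      upper95 = sm$conf.int[, "upper .95"],
      p = co[, "Pr(>|z|)"], row.names = NULL),
    loglik = fit$loglik[2], loglik_null = fit$loglik[1],
    lr_chisq = lr, df = sum(!is.na(stats::coef(fit))),
    n = fit$n, events = fit$nevent, unstable = unstable,
    terms = names(covariates), fit = fit),
    class = "cox_fit")
}

#' Kaplan-Meier estimates and log-rank test
#'
#' Product-limit survival curves per group plus, for two or more groups,
#' the log-rank chi-square and p-value.
#'
#' @param records survival records for a single endpoint.
#' @param groups group assignment aligned with the records (optional;
#'   single-group fit when omitted).
#' @return A list: `curves` (tidy data.frame of time, n.risk, n.event,
#'   surv, group), `logrank_chisq`, `logrank_p` (NULL for one group), and
#'   the `survfit` object.
#' @export
km_fit <- function(records, groups = NULL) {
  s <- records_surv(records)
  if (is.null(groups)) {
    fit <- survival::survfit(s ~ 1)
    grp <- rep("all", length(fit$time))
    lr_chi <- NULL; lr_p <- NULL
  } else {
    groups <- as.factor(groups)
    assert_that(length(groups) == nrow(records),
                "one group per record required")
    assert_that(all(table(groups) > 0), "empty group")
    dat <- data.frame(.time = records$time, .event = records$event,
                      .grp = groups)
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .grp, data = dat)
    sd <- survival::survdiff(survival::Surv(.time, .event) ~ .grp, data = dat)
    lr_chi <- sd$chisq
    lr_p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
    grp <- rep(sub("^\\.grp=", "", names(fit$strata)), fit$strata)
  }
  list(curves = data.frame(time = fit$time, n_risk = fit$n.risk,
                           n_event = fit$n.event, surv = fit$surv,
                           group = grp),
       logrank_chisq = lr_chi, logrank_p = lr_p, fit = fit)
}

#' Univariable Cox screening of expression features
#'
#' Fits a univariable Cox model per feature (on standardised expression by
#' default, so hazard ratios are per standard deviation) for each endpoint
#' present in the records. A feature is called significant when its Wald
#' p-value is below `alpha` *and* its hazard ratio lies outside
#' `hr_bounds` (default: HR > 2.0 or HR < 0.5). Non-converging features are
#' flagged and excluded from the significant sets.
#'
#' @param matrix feature-by-sample matrix.
#' @param records survival records (long format with an `endpoint`
#'   column, as from [build_endpoints()]).
#' @param hr_bounds `c(low, high)` hazard-ratio screen bounds.
#' @param alpha Wald significance level.
#' @param standardise z-score each feature before fitting.
#' @return A list: `table` (feature, endpoint, hr, p, significant,
#'   converged), `significant` (endpoint -> feature ids),
#'   `all_endpoint_significant` (intersection across endpoints).
#' @export
screen_features <- function(matrix, records, hr_bounds = c(0.5, 2.0),
                            alpha = 0.05, standardise = TRUE) {
  assert_matrix(matrix, "matrix")
  endpoints <- unique(records$endpoint)
  rows <- list()
  for (ep in endpoints) {
    rec <- records[records$endpoint == ep, , drop = FALSE]
    rec <- rec[rec$sample %in% colnames(matrix), , drop = FALSE]
    s <- survival::Surv(rec$time, rec$event)
    X <- matrix[, rec$sample, drop = FALSE]
    for (f in rownames(matrix)) {
      x <- X[f, ]
      if (standardise) {
        sdx <- stats::sd(x)
        if (is.na(sdx) || sdx == 0) {
          rows[[length(rows) + 1]] <- data.frame(
            feature = f, endpoint = ep, hr = NA_real_, p = NA_real_,
            significant = FALSE, converged = FALSE)
          next
        }
        x <- (x - mean(x)) / sdx
      }
      ft <- tryCatch(
        suppressWarnings(survival::coxph(s ~ x)),
        error = function(e) NULL)
      if (is.null(ft) || !is.finite(stats::coef(ft)) ||
          abs(stats::coef(ft)) > 15) {
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, endpoint = ep, hr = NA_real_, p = NA_real_,
          significant = FALSE, converged = FALSE)
        next
      }
      sm <- summary(ft)$coefficients
      hr <- exp(sm[1, "coef"]); p <- sm[1, "Pr(>|z|)"]
      sig <- isTRUE(p < alpha && (hr > hr_bounds[2] || hr < hr_bounds[1]))
      rows[[length(rows) + 1]] <- data.frame(
        feature = f, endpoint = ep, hr = hr, p = p,
        significant = sig, converged = TRUE)
    }
  }
  tab <- do.call(rbind, rows)
  sig <- lapply(split(tab, tab$endpoint),
                function(d) d$feature[d$significant])
  list(table = tab, significant = sig,
       all_endpoint_significant = Reduce(intersect, sig))
}

#' Martingale-residual cutpoint for a continuous covariate
#'
#' Computes martingale residuals of the null Cox model, smooths them
#' against the (log-transformed by default) covariate with a running-line
#' smoother (lowess, span 0.3), and returns the covariate value where the
#' smoothed residual crosses zero closest to the steepest slope. With no
#' zero crossing the cohort median is returned with a warning.
#'
#' @param records survival records for one endpoint.
#' @param covariate continuous values aligned with the records (>= 10
#'   distinct values).
#' @param log_transform log-transform before smoothing (default TRUE,
#'   matching the pipeline's treatment of tumour size).
#' @param span lowess span (default 0.3; wider spans oversmooth the
#'   crossing at a few hundred samples).
#' @return A list: `cutpoint` (original scale), `fallback` (TRUE when the
#'   median fallback fired), `diagnostics` (x, smoothed residual).
#' @export
martingale_cutpoint <- function(records, covariate, log_transform = TRUE,
                                span = 0.3) {
  assert_that(length(covariate) == nrow(records),
              "one covariate value per record required")
  assert_that(length(unique(covariate)) >= 10,
              "covariate needs >= 10 distinct values")
  x <- if (log_transform) log(covariate) else covariate
  null_fit <- survival::coxph(records_surv(records) ~ 1)
  res <- stats::residuals(null_fit, type = "martingale")
  sm <- stats::lowess(x, res, f = span)

  y <- sm$y
  cross <- which(y[-length(y)] * y[-1] <= 0 & (y[-length(y)] != 0 | y[-1] != 0))
  if (!length(cross)) {
    warning("no zero crossing in smoothed martingale residuals; ",
            "falling back to the median")
    return(list(cutpoint = stats::median(covariate), fallback = TRUE,
                diagnostics = data.frame(x = sm$x, residual = sm$y)))
  }
  slope <- abs((y[cross + 1] - y[cross]) / (sm$x[cross + 1] - sm$x[cross]))
  j <- cross[which.max(slope)]
  # linear interpolation of the crossing position
  x0 <- sm$x[j] - y[j] * (sm$x[j + 1] - sm$x[j]) / (y[j + 1] - y[j])
  cut <- if (log_transform) exp(x0) else x0
  list(cutpoint = cut, fallback = FALSE,
       diagnostics = data.frame(x = sm$x, residual = sm$y))
}

#' Likelihood-ratio prognostic gain of a nested Cox model
#'
#' Quantifies the prognostic information added by extending a baseline Cox
#' model: `delta_chisq = LR_ext - LR_base`, percentage gain
#' `100 * delta_chisq / LR_base`, and a chi-square p-value on the added
#' degrees of freedom. The models must be nested (the extended model's
#' covariates contain the base model's) and fitted on the same records.
#'
#' @param base,extended `cox_fit` objects.
#' @return An `lr_gain` list: `base_chisq`, `extended_chisq`,
#'   `delta_chisq`, `gain_pct`, `df`, `p`.
#' @export
lr_gain <- function(base, extended) {
  assert_that(inherits(base, "cox_fit") && inherits(extended, "cox_fit"),
              "base and extended must be cox_fit objects")
  assert_that(all(base$terms %in% extended$terms),
              "models are not nested: extended must contain base covariates")
  assert_that(base$n == extended$n && base$events == extended$events,
              "models must be fitted on the same records")
  d_chi <- extended$lr_chisq - base$lr_chisq
  d_df <- extended$df - base$df
  structure(list(
    base_chisq = base$lr_chisq, extended_chisq = extended$lr_chisq,
    delta_chisq = d_chi,
    gain_pct = 100 * d_chi / base$lr_chisq,
    df = d_df,
    p = if (d_df > 0) stats::pchisq(d_chi, d_df, lower.tail = FALSE) else NA_real_),
    class = "lr_gain")
}
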