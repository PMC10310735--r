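#' Run the end-to-end analysis pipeline from a configuration
#'
#' Orchestrates the stages in dependency order:
#' `simulate` (synthetic cohort, paired transcriptome, clinical table) ->
#' `preprocess` (reference-ratio normalisation with filtering/imputation) ->
#' `cluster` (consensus clustering + model selection + SigClust) /
#' `sam` (subtype-unique markers) / `pam` (marker-panel reduction) /
#' `modules` (co-expression modules + scores) ->
#' `survival` (endpoints, screens) / `concord` (layer concordance).
#' Every artefact is written under `out_dir` in plain-text formats, and a
#' JSON manifest records parameters, seeds, output hashes and summary
#' metrics, sufficient to reproduce the run exactly.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure: `stages` (character vector; default all), `seed`, `out_dir`,
#'   `cohort` (arguments to [cohort_config()]), and optional per-stage
#'   parameter lists `preprocess`, `cluster`, `sam`, `pam`, `modules`.
#' @return The manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "preprocess", "cluster",
                                 "sam", "pam", "modules", "survival",
                                 "concord")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(seed = seed, stages = stages, outputs = list(),
                   metrics = list())
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }
  need <- function(stage, wanted) {
    assert_that(!is.null(wanted),
                paste0("stage '", stage, "': missing upstream artefact"))
  }

  cohort <- NULL; truth <- NULL; norm <- NULL; clinical <- NULL
  mrna <- NULL; records <- NULL; labels <- NULL

  if ("simulate" %in% stages) {
    cfg <- do.call(cohort_config, c(config$cohort %||% list(),
                                    list(seed = seed)))
    sim <- generate_raw_plexes(cfg)
    cohort <- sim$raw; truth <- sim$truth
    clinical <- simulate_survival(truth, cfg)
    emit("clinical.csv", function(p) write_clinical(clinical, p))
    emit("ground_truth.json", function(p) {
      jsonlite::write_json(list(
        subtype_labels = as.list(truth$subtype_labels),
        module_membership = as.list(truth$module_membership),
        true_rho = as.list(truth$true_rho),
        true_hazard_coefs = as.list(truth$true_hazard_coefs),
        seed = truth$seed), p, auto_unbox = TRUE, digits = NA)
    })
    manifest$cohort_config <- cfg[setdiff(names(cfg), "survival_betas")]
    manifest$cohort_config$survival_betas <- as.list(cfg$survival_betas)
  }

  if ("preprocess" %in% stages) {
    need("preprocess", cohort)
    pp <- config$preprocess %||% list()
    norm <- reference_ratio_normalize(cohort,
                                      min_frac = pp$min_frac %||% 0.75,
                                      impute_k = pp$impute_k %||% 10)
    emit("normalized_matrix.tsv", function(p) write_matrix(norm, p, "protein"))
    if (!is.null(truth)) {
      mrna <- generate_paired_transcriptome(norm, truth)
      emit("mrna_matrix.tsv", function(p) write_matrix(mrna, p, "gene"))
    }
  }

  if ("cluster" %in% stages) {
    need("cluster", norm)
    cl <- config$cluster %||% list()
    cons <- run_consensus(norm,
                          distance = cl$distance %||% "spearman",
                          k_range = cl$k_range %||% 2:6,
                          reps = cl$reps %||% 250,
                          seed = seed)
    sel <- evaluate_k(cons, norm)
    labels <- sel$labels
    emit("cluster_labels.csv", function(p) {
      utils::write.csv(data.frame(sample = names(labels), cluster = labels),
                       p, row.names = FALSE, quote = FALSE)
    })
    sig <- sigclust(norm, labels, n_sim = cl$sigclust_sims %||% 200,
                    seed = seed)
    manifest$metrics$chosen_k <- sel$chosen_k
    manifest$metrics$sigclust_p <- sig$p
    if (!is.null(truth)) {
      manifest$metrics$cluster_ari <-
        adjusted_rand_index(labels, truth$subtype_labels[names(labels)])
    }
  }

  if ("sam" %in% stages) {
    need("sam", norm)
    sm <- config$sam %||% list()
    lab_src <- labels %||% truth$subtype_labels[colnames(norm)]
    need("sam", lab_src)
    um <- unique_subtype_markers(norm, lab_src,
                                 min_group = sm$min_group %||% 21,
                                 n_perm = sm$n_perm %||% 200, seed = seed)
    emit("unique_markers.tsv", function(p) {
      df <- data.frame(
        subtype = rep(names(um$unique_markers),
                      lengths(um$unique_markers)),
        protein = unlist(um$unique_markers, use.names = FALSE))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    manifest$metrics$n_unique_markers <- um$n_unique_total
  }

  if ("pam" %in% stages) {
    need("pam", norm)
    pm <- config$pam %||% list()
    lab_src <- labels %||% truth$subtype_labels[colnames(norm)]
    model <- pam_train(norm, lab_src, seed = seed,
                       folds = pm$folds %||% 10)
    emit("nsc_model.json", function(p) {
      jsonlite::write_json(list(
        delta_star = model$delta_star, cv_error = model$cv_error_star,
        retained = model$retained, s0 = model$stats$s0,
        priors = as.list(model$priors)), p, auto_unbox = TRUE, digits = NA)
    })
    manifest$metrics$panel_size <- length(model$retained)
    manifest$metrics$panel_cv_error <- model$cv_error_star
    if (!is.null(truth)) {
      informative <- names(truth$marker_membership)[
        !is.na(truth$marker_membership)]
      prec <- if (length(model$retained)) {
        mean(model$retained %in% informative)
      } else NA_real_
      manifest$metrics$panel_precision <- prec
    }
  }

  if ("modules" %in% stages) {
    need("modules", norm)
    md <- config$modules %||% list()
    cm <- stats::cor(t(norm))
    adj <- signed_hybrid_adjacency(cm, md$beta %||% 5)
    diss <- tom_dissimilarity(adj)
    assign <- detect_modules(diss, norm,
                             min_module_size = md$min_module_size %||% 30)
    emit("module_assignment.tsv", function(p) {
      utils::write.table(
        data.frame(protein = names(assign$membership),
                   module = assign$membership),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    edges <- export_edge_list(1 - diss, md$edge_threshold %||% 0.05, assign)
    emit("edge_list.tsv", function(p) {
      utils::write.table(edges, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    manifest$metrics$n_modules <-
      length(setdiff(unique(assign$membership), "ungrouped"))
  }

  if ("survival" %in% stages) {
    need("survival", clinical)
    records <- build_endpoints(clinical)
    emit("survival_records.csv", function(p) {
      utils::write.csv(records, p, row.names = FALSE, quote = FALSE)
    })
    if (!is.null(norm)) {
      scr <- screen_features(norm[seq_len(min(200, nrow(norm))), ,
                                  drop = FALSE], records)
      emit("hazard_screen.tsv", function(p) {
        utils::write.table(scr$table, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      })
      manifest$metrics$n_all_endpoint_significant <-
        length(scr$all_endpoint_significant)
    }
  }

  if ("concord" %in% stages) {
    need("concord", norm); need("concord", mrna)
    paired <- pair_layers(norm, mrna)
    conc <- correlate_layers(paired)
    emit("concordance.tsv", function(p) {
      utils::write.table(conc, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    manifest$metrics$n_positive_significant <-
      sum(conc$class == "positive-significant")
  }

  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
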