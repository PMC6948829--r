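#' Run the full analysis pipeline
#'
#' Orchestrates every stage from one configuration: cohort (synthetic
#' generation or CSV load), preprocessing and harmonization, pain
#' trajectories, factor reduction on the knee arm at baseline with
#' projection of the hip arm through the knee-arm weights, stepwise outcome
#' models (baseline pain, 6-month pain, 6-month residual pain, per scale)
#' with re-testing of knee-arm predictors in the hip arm, the six binarized
#' networks (two groups by three visits) with their metrics, and the
#' permutation comparisons.  One root seed drives deterministic sub-seeds
#' per stage, so identical configuration and seed reproduce identical
#' outputs.
#'
#' @param config an [analysis_config()], a path to a YAML configuration, or
#'   the list returned by [read_analysis_config()].
#' @param synthetic a [synthetic_spec()] (ignored when the configuration
#'   names a cohort CSV).
#' @param cohort optionally, an already-built [cohort_table()].
#' @param out_dir optional directory; when given, every stage output is
#'   serialized there along with a timestamped run log recording the
#'   configuration fingerprint and seed.
#' @param permutation_reps,louvain_reps optional overrides of the
#'   configuration values (the full 10,000/100 defaults are expensive;
#'   exploratory runs may use fewer).
#' @return A `run_report` list with elements `cohort`, `pain`,
#'   `pain_summary`, `factor_model`, `scores`, `models`, `networks`,
#'   `metrics`, `comparisons`, `config`, and `seed`.
#' @export
run_full_analysis <- function(config = analysis_config(), synthetic = NULL,
                              cohort = NULL, out_dir = NULL,
                              permutation_reps = NULL, louvain_reps = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (is.list(config) && !inherits(config, "analysis_config")) {
    synthetic <- synthetic %||% config$synthetic
    cohort_csv <- config$cohort_csv
    config <- config$config
    if (is.null(cohort) && !is.null(cohort_csv))
      cohort <- load_cohort(cohort_csv, default_registry())
  }
  stopifnot(inherits(config, "analysis_config"))
  perm_reps <- permutation_reps %||% config$permutation_reps
  louv_reps <- louvain_reps %||% config$louvain_reps
  log_file <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_file <- file.path(out_dir, "run.log")
  }
  cfg_hash <- fnv1a32(paste(deparse(unclass(config)), collapse = ""))
  pn_log("run_full_analysis start; config ", cfg_hash,
         "; rng_seed ", config$rng_seed, file = log_file)
  seeds <- derive_seeds(config$rng_seed, 40L)

  truth <- NULL
  if (is.null(cohort)) {
    if (is.null(synthetic))
      stop("no cohort source: supply a cohort, a cohort_csv, ",
           "or a synthetic spec before any computation")
    synthetic$rng_seed <- seeds[1]
    gen <- generate_cohort(synthetic)
    cohort <- gen$cohort; truth <- gen$truth
    pn_log("synthetic cohort generated; clipped fraction ",
           sprintf("%.4f", truth$clipped_fraction), file = log_file)
  }
  registry <- cohort$registry
  groups <- unique(cohort$records$group)
  visits <- c("baseline", "m3", "m6")

  # --- preprocessing ---------------------------------------------------
  harmonized <- list()
  for (g in groups) for (v in visits)
    harmonized[[g]][[v]] <- harmonize_visit(cohort, v, g, config = config)
  pain <- pain_trajectory(cohort, config)
  pain_summary <- summarize_pain(cohort, config)
  pn_log("preprocessing done", file = log_file)

  # --- factor reduction (fit on the larger knee arm at baseline) -------
  fit_group <- if ("KOA" %in% groups) "KOA" else groups[1]
  fm <- fit_factor_model(harmonized[[fit_group]]$baseline$matrix,
                         config, registry)
  scores <- list()
  for (g in groups) for (v in visits)
    scores[[g]][[v]] <- score_subjects(fm, harmonized[[g]][[v]]$matrix)
  communities <- stats::setNames(
    fm$component_labels[fm$membership$component], fm$membership$measure_id)
  pn_log("factor model: ", fm$retained_k, " components, KMO ",
         sprintf("%.3f", fm$kmo_overall), file = log_file)

  # --- outcome models --------------------------------------------------
  models <- fit_outcome_models(cohort, scores, pain, fit_group, groups, config)
  pn_log("outcome models fitted", file = log_file)

  # --- networks --------------------------------------------------------
  networks <- list(); metrics <- list(); corr <- list()
  si <- 2L
  for (g in groups) for (v in visits) {
    corr[[g]][[v]] <- correlation_matrix(harmonized[[g]][[v]]$matrix, g, v)
    networks[[g]][[v]] <- binarize_top(corr[[g]][[v]],
                                       config$binarize_fraction, communities)
    metrics[[g]][[v]] <- louvain_modularity(networks[[g]][[v]], louv_reps,
                                            seed = seeds[si])
    si <- si + 1L
  }
  pn_log("networks built", file = log_file)

  # --- permutation comparisons ----------------------------------------
  comparisons <- list()
  for (g in groups) {
    h <- harmonized[[g]]
    comparisons[[g]] <- list(
      delta_r_m3 = mean_delta_r(corr[[g]]$baseline, corr[[g]]$m3),
      delta_r_m6 = mean_delta_r(corr[[g]]$baseline, corr[[g]]$m6),
      p_delta_r_m3 = permute_compare(h$baseline$matrix, h$m3$matrix,
        "mean_delta_r", perm_reps, seeds[si], config$binarize_fraction),
      p_delta_r_m6 = permute_compare(h$baseline$matrix, h$m6$matrix,
        "mean_delta_r", perm_reps, seeds[si + 1], config$binarize_fraction),
      p_delta_r_m3_m6 = permute_compare(h$m3$matrix, h$m6$matrix,
        "mean_delta_r", perm_reps, seeds[si + 2], config$binarize_fraction),
      p_clustering_m3 = permute_compare(h$baseline$matrix, h$m3$matrix,
        "clustering", perm_reps, seeds[si + 3], config$binarize_fraction),
      p_modularity_m3 = permute_compare(h$baseline$matrix, h$m3$matrix,
        "modularity", perm_reps, seeds[si + 4], config$binarize_fraction,
        louvain_reps = max(5L, louv_reps %/% 10L)))
    si <- si + 5L
  }
  if (all(c("KOA", "HOA") %in% groups)) {
    comparisons$between_group <- list(
      p_delta_r_m3 = permute_compare_groups(
        harmonized$KOA$baseline$matrix, harmonized$KOA$m3$matrix,
        harmonized$HOA$baseline$matrix, harmonized$HOA$m3$matrix,
        "mean_delta_r", perm_reps, seeds[si]),
      p_delta_r_m6 = permute_compare_groups(
        harmonized$KOA$baseline$matrix, harmonized$KOA$m6$matrix,
        harmonized$HOA$baseline$matrix, harmonized$HOA$m6$matrix,
        "mean_delta_r", perm_reps, seeds[si + 1]))
  }
  pn_log("permutation comparisons done", file = log_file)

  report <- structure(list(
    cohort = cohort, truth = truth, harmonized = harmonized, pain = pain,
    pain_summary = pain_summary, factor_model = fm, scores = scores,
    models = models, networks = networks, metrics = metrics,
    comparisons = comparisons, config = config, config_hash = cfg_hash,
    seed = config$rng_seed), class = "run_report")

  if (!is.null(out_dir)) {
    write_results(cohort, file.path(out_dir, "cohort.csv"))
    write_results(fm, file.path(out_dir, "factor_model.json"))
    for (g in groups) for (v in visits) {
      write_results(networks[[g]][[v]],
                    file.path(out_dir, sprintf("network_%s_%s.graphml", g, v)))
      write_results(metrics[[g]][[v]],
                    file.path(out_dir, sprintf("metrics_%s_%s.json", g, v)))
    }
    for (g in groups) {
      utils::write.csv(comparisons[[g]]$delta_r_m3$delta,
                       file.path(out_dir, sprintf("delta_r_%s_m3.csv", g)))
      for (nm in grep("^p_", names(comparisons[[g]]), value = TRUE))
        write_results(comparisons[[g]][[nm]],
                      file.path(out_dir, sprintf("perm_%s_%s.json", g, nm)))
    }
    for (nm in names(models))
      write_results(models[[nm]], file.path(out_dir, sprintf("model_%s.csv", nm)))
    write_json_full(list(pain_summary = pain_summary,
                         config = unclass(config), seed = config$rng_seed,
                         config_hash = cfg_hash),
                    file.path(out_dir, "report.json"))
    pn_log("outputs written to ", out_dir, file = log_file)
  }
  report
}

# Table-2-style summary: mean, SD and inter-scale correlations of the four
# pain outcome scales per group and visit
summarize_pain <- function(cohort, config) {
  registry <- cohort$registry
  scales <- outcome_measures(registry)
  out <- list()
  for (g in unique(cohort$records$group)) for (v in c("baseline", "m3", "m6")) {
    h <- harmonize_visit(cohort, v, g, measures = scales, config = config)
    out[[g]][[v]] <- list(mean = colMeans(h$matrix),
                          sd = apply(h$matrix, 2, stats::sd),
                          correlations = stats::cor(h$matrix))
  }
  out
}

# stepwise models per outcome scale: baseline pain, m6 pain, m6 residual;
# knee-arm selection re-tested in the hip arm
fit_outcome_models <- function(cohort, scores, pain, fit_group, groups,
                               config) {
  covs <- cohort$covariates
  s_base <- scores[[fit_group]]$baseline
  subj <- rownames(s_base)
  x <- as.data.frame(s_base)
  if (!is.null(covs)) {
    ci <- match(subj, covs$subject_id)
    for (nm in c("age", "gender", "education", "bmi", "pain_duration",
                 "kl_grade"))
      if (!is.null(covs[[nm]])) x[[nm]] <- covs[[nm]][ci]
  }
  other <- setdiff(groups, fit_group)
  x_other <- NULL
  if (length(other)) {
    so <- scores[[other[1]]]$baseline
    x_other <- as.data.frame(so)
    if (!is.null(covs)) {
      ci <- match(rownames(so), covs$subject_id)
      for (nm in c("age", "gender", "education", "bmi", "pain_duration",
                   "kl_grade"))
        if (!is.null(covs[[nm]])) x_other[[nm]] <- covs[[nm]][ci]
    }
  }

  models <- list()
  ps <- pain$scales
  for (sc in unique(ps$measure_id)) {
    rows <- ps[ps$measure_id == sc & ps$group == fit_group, ]
    rows <- rows[match(subj, rows$subject_id), ]
    for (oc in c("pre", "m6", "residual_m6")) {
      yv <- rows[[oc]]
      ok <- !is.na(yv)
      fit <- stepwise_fit(x[ok, , drop = FALSE], yv[ok], config)
      fit$outcome <- paste0(sc, "_", oc)
      models[[paste0(fit_group, "_", sc, "_", oc)]] <- fit
      if (length(other) && length(fit$predictors)) {
        ro <- ps[ps$measure_id == sc & ps$group == other[1], ]
        ro <- ro[match(rownames(x_other), ro$subject_id), ]
        yo <- ro[[oc]]
        ok_o <- !is.na(yo)
        if (sum(ok_o) > length(fit$predictors) + 2) {
          mo <- apply_model(fit$predictors, x_other[ok_o, , drop = FALSE],
                            yo[ok_o])
          mo$outcome <- paste0(sc, "_", oc, "_", other[1])
          models[[paste0(other[1], "_", sc, "_", oc)]] <- mo
        }
      }
    }
  }
  models
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$seed, ", config", x$config_hash, ")\n")
  cat("  factor model:", x$factor_model$retained_k, "components\n")
  cat("  models:", length(x$models), "\n")
  for (g in names(x$comparisons)) {
    if (g == "between_group") next
    cmp <- x$comparisons[[g]]
    cat(sprintf("  %s: mean dR m3 %.3f (p=%.4g), m6 %.3f (p=%.4g)\n", g,
                cmp$delta_r_m3$mean_delta_r, cmp$p_delta_r_m3$probability,
                cmp$delta_r_m6$mean_delta_r, cmp$p_delta_r_m6$probability))
  }
  invisible(x)
}
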