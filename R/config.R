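#' Analysis configuration
#'
#' Collects the scalar constants used throughout the pipeline.  Defaults
#' mirror the analysis protocol: networks keep the strongest 25% of
#' correlations, Louvain modularity is averaged over 100 repetitions,
#' permutation probabilities use 10,000 resampling draws, stepwise selection
#' uses alpha-to-enter 0.05 and alpha-to-remove 0.10, factor loadings are
#' thresholded at |0.5|, components are retained at eigenvalue > 1, a
#' questionnaire with 30% or more of its items missing is excluded, and
#' studentized deleted residuals beyond +-3 SD are pruned (at most 3 cases).
#'
#' @param binarize_fraction fraction of measure pairs kept as network edges.
#' @param louvain_reps repetitions of Louvain community detection.
#' @param permutation_reps resampling draws for permutation probabilities.
#' @param alpha_enter significance level to enter stepwise selection.
#' @param alpha_remove significance level to remove.
#' @param loading_threshold absolute rotated-loading threshold for factor
#'   membership.
#' @param eigenvalue_cut component-retention cut (strictly greater than).
#' @param missing_threshold missing-item fraction at or above which an
#'   instrument score is excluded.
#' @param outlier_sd studentized-deleted-residual cut in SD units.
#' @param outlier_cap maximum number of cases removed per model.
#' @param rng_seed root seed for all stochastic stages.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(binarize_fraction = 0.25,
                            louvain_reps = 100L,
                            permutation_reps = 10000L,
                            alpha_enter = 0.05,
                            alpha_remove = 0.10,
                            loading_threshold = 0.5,
                            eigenvalue_cut = 1.0,
                            missing_threshold = 0.30,
                            outlier_sd = 3.0,
                            outlier_cap = 3L,
                            rng_seed = 1L) {
  cfg <- list(binarize_fraction = binarize_fraction,
              louvain_reps = as.integer(louvain_reps),
              permutation_reps = as.integer(permutation_reps),
              alpha_enter = alpha_enter,
              alpha_remove = alpha_remove,
              loading_threshold = loading_threshold,
              eigenvalue_cut = eigenvalue_cut,
              missing_threshold = missing_threshold,
              outlier_sd = outlier_sd,
              outlier_cap = as.integer(outlier_cap),
              rng_seed = as.integer(rng_seed))
  if (!(cfg$binarize_fraction > 0 && cfg$binarize_fraction < 1))
    stop("binarize_fraction must be in (0, 1)")
  if (cfg$louvain_reps < 1L || cfg$permutation_reps < 1L)
    stop("repetition counts must be >= 1")
  positive <- c("alpha_enter", "alpha_remove", "loading_threshold",
                "eigenvalue_cut", "missing_threshold", "outlier_sd")
  for (nm in positive)
    if (!(is.numeric(cfg[[nm]]) && cfg[[nm]] > 0))
      stop(nm, " must be a positive number")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration (and optional synthetic section) from YAML
#'
#' The YAML file mirrors [analysis_config()] field names at the top level; an
#' optional `synthetic` section mirrors [synthetic_spec()] fields and, when
#' present, is returned as a fully constructed spec.  A `cohort_csv` field
#' names a cohort file to load instead.
#'
#' @param path path to a YAML file.
#' @return A list with elements `config` (an `analysis_config`), `synthetic`
#'   (a `synthetic_spec` or `NULL`), and `cohort_csv` (a path or `NULL`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  cfg_args <- raw[intersect(names(raw), known)]
  cfg <- do.call(analysis_config, cfg_args)
  synth <- NULL
  if (!is.null(raw$synthetic)) {
    syn_known <- names(formals(synthetic_spec))
    syn_args <- raw$synthetic[intersect(names(raw$synthetic), syn_known)]
    synth <- do.call(synthetic_spec, syn_args)
  }
  list(config = cfg, synthetic = synth, cohort_csv = raw$cohort_csv %||% NULL)
}
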