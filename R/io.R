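#' Write a stage result to disk
#'
#' Dispatches on the result class: factor models, permutation results and
#' network metrics are serialized to JSON with full floating-point
#' precision; binarized networks are written as GraphML (with the community
#' attribute) plus a plain edge list; cohort tables and regression tables
#' as CSV.  Round-tripping a JSON result through the matching `read_*`
#' function reproduces all numbers exactly.
#'
#' @param results a stage output object.
#' @param path output path.  Networks write `<path>` (GraphML) and a
#'   sibling `<path>.edges.tsv`; cohorts write `<path>` and
#'   `<path>.covariates.csv` when covariates are present.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) UseMethod("write_results")

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  invisible(path)
}

# 17 significant digits: doubles survive the JSON round trip bit-exactly
write_json_full <- function(x, path) {
  check_writable(path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @export
write_results.default <- function(results, path) {
  write_json_full(unclass(results), path)
}

#' @export
write_results.factor_model <- function(results, path) {
  x <- results
  out <- list(
    type = "factor_model",
    eigenvalues = x$eigenvalues,
    variance_explained = x$variance_explained,
    loadings_unrotated = mat_to_list(x$loadings_unrotated),
    pattern = mat_to_list(x$pattern),
    phi = mat_to_list(x$phi),
    weights = mat_to_list(x$weights),
    kmo_overall = x$kmo_overall,
    kmo_per_measure = as.list(x$kmo_per_measure),
    retained_k = x$retained_k,
    scree_elbow = x$scree_elbow,
    component_labels = x$component_labels,
    membership = x$membership,
    center = as.list(x$center),
    scale = as.list(x$scale),
    measures = x$measures,
    n = x$n,
    loading_threshold = x$loading_threshold,
    eigenvalue_cut = x$eigenvalue_cut,
    kappa = x$kappa)
  write_json_full(out, path)
}

#' Read a factor model written by [write_results()]
#'
#' @param path path to the JSON file.
#' @return A `factor_model`.
#' @export
read_factor_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "factor_model")) stop("not a factor_model file")
  structure(list(
    eigenvalues = j$eigenvalues,
    variance_explained = j$variance_explained,
    loadings_unrotated = list_to_mat(j$loadings_unrotated),
    pattern = list_to_mat(j$pattern),
    phi = list_to_mat(j$phi),
    weights = list_to_mat(j$weights),
    kmo_overall = j$kmo_overall,
    kmo_per_measure = unlist(j$kmo_per_measure),
    retained_k = j$retained_k,
    scree_elbow = j$scree_elbow,
    component_labels = j$component_labels,
    membership = as.data.frame(j$membership),
    center = unlist(j$center),
    scale = unlist(j$scale),
    measures = j$measures,
    n = j$n,
    loading_threshold = j$loading_threshold,
    eigenvalue_cut = j$eigenvalue_cut,
    kappa = j$kappa), class = "factor_model")
}

#' @export
write_results.permutation_result <- function(results, path) {
  write_json_full(c(list(type = "permutation_result"), unclass(results)), path)
}

#' Read a permutation result written by [write_results()]
#'
#' @param path path to the JSON file.
#' @return A `permutation_result`.
#' @export
read_permutation_result <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$type, "permutation_result"))
    stop("not a permutation_result file")
  j$type <- NULL
  for (nm in c("observed", "draws", "probability"))
    j[[nm]] <- as.numeric(j[[nm]])
  structure(j, class = "permutation_result")
}

#' @export
write_results.binary_network <- function(results, path) {
  check_writable(path)
  igraph::write_graph(results$graph, path, format = "graphml")
  edge_path <- paste0(path, ".edges.tsv")
  utils::write.table(results$edges[, c("from", "to")], edge_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.cohort_table <- function(results, path) {
  check_writable(path)
  utils::write.csv(results$records, path, row.names = FALSE, na = "NA")
  if (!is.null(results$covariates))
    utils::write.csv(results$covariates, paste0(path, ".covariates.csv"),
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
write_results.regression_fit <- function(results, path) {
  check_writable(path)
  tab <- results$table
  if (!nrow(tab))
    tab <- data.frame(predictor = "(none entered)", b = NA_real_,
                      se = NA_real_, beta = NA_real_, t = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
  tab$adj_r_squared <- results$adj_r_squared
  tab$f_value <- results$f_value
  tab$df1 <- results$df[1]; tab$df2 <- results$df[2]
  tab$n <- results$n
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.network_metrics <- function(results, path) {
  x <- unclass(results)
  x$best_membership <- as.list(x$best_membership)
  write_json_full(c(list(type = "network_metrics"), x), path)
}
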