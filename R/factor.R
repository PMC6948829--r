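#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Compares the observed correlations with the anti-image partial
#' correlations obtained from the inverse correlation matrix.  The overall
#' statistic is `sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal pairs,
#' where `q` are the partial correlations with all other measures held
#' fixed; the per-measure statistic restricts the sums to one row.  Values
#' above 0.5 are conventionally taken as adequate for factor analysis.
#'
#' @param r a symmetric positive-definite correlation matrix.
#' @return A list with `overall` and `per_measure` (named by the matrix's
#'   column names), both in \[0, 1\].
#' @export
kmo <- function(r) {
  r <- as.matrix(r)
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  rinv <- tryCatch(solve(r), error = function(e)
    stop("correlation matrix is singular or near-singular; ",
         "consider removing collinear measures or adding a small ridge"))
  q <- -stats::cov2cor(rinv)
  diag(q) <- 0
  diag(r) <- 0
  r2 <- r^2; q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per) <- colnames(r)
  list(overall = overall, per_measure = per)
}

#' Component retention by the eigenvalue rule
#'
#' Retains components with eigenvalues strictly greater than `cut` (default
#' 1.0 for a correlation-matrix PCA).  The scree elbow (largest drop in the
#' eigenvalue sequence) is reported for visual inspection but never applied
#' automatically.
#'
#' @param eigenvalues eigenvalues in descending order.
#' @param cut retention threshold (strict inequality).
#' @return Integer count of retained components, with attribute
#'   `scree_elbow` (index of the largest eigenvalue drop).
#' @export
retain_components <- function(eigenvalues, cut = 1.0) {
  if (!length(eigenvalues)) stop("no eigenvalues supplied")
  k <- sum(eigenvalues > cut)
  elbow <- if (length(eigenvalues) > 1) which.max(-diff(eigenvalues)) else 1L
  structure(as.integer(k), scree_elbow = as.integer(elbow))
}

#' Promax oblique rotation
#'
#' Varimax pre-rotation followed by the power-target oblique transform:
#' the varimax loadings are raised elementwise to the `kappa`-th power
#' (preserving sign), the least-squares transform toward that target is
#' column-normalized so that the factor correlation matrix has unit
#' diagonal, and the pattern matrix and factor correlations are returned.
#' Columns are sign-fixed so the largest-magnitude loading of each column
#' is positive, and ordered by explained variance (column sum of squared
#' pattern loadings).
#'
#' @param loadings measures x k unrotated loading matrix, k >= 2 (k = 1
#'   returns the input with a warning).
#' @param kappa power of the target matrix (conventional default 4).
#' @return A list with `pattern` (rotated pattern matrix), `phi` (factor
#'   correlation matrix, symmetric with unit diagonal) and `rotmat` (the
#'   full transform such that `pattern = loadings %*% rotmat`).
#' @export
promax_rotate <- function(loadings, kappa = 4) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (k < 2) {
    warning("only one component retained; rotation is the identity")
    s <- if (max(abs(loadings)) == max(loadings)) 1 else -1
    return(list(pattern = s * loadings, phi = matrix(1, 1, 1),
                rotmat = matrix(s, 1, 1)))
  }
  vm <- stats::varimax(loadings, normalize = TRUE)
  a <- loadings %*% vm$rotmat
  target <- a * abs(a)^(kappa - 1)
  u <- solve(crossprod(a), crossprod(a, target))
  u <- u %*% diag(sqrt(diag(solve(crossprod(u)))))
  rotmat <- vm$rotmat %*% u
  pattern <- loadings %*% rotmat
  phi <- solve(crossprod(rotmat))

  # sign-fix: largest |loading| per column positive
  flip <- apply(pattern, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  pattern <- sweep(pattern, 2, flip, "*")
  rotmat <- sweep(rotmat, 2, flip, "*")
  phi <- diag(flip) %*% phi %*% diag(flip)

  # order by explained variance
  ord <- order(colSums(pattern^2), decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  phi <- (phi + t(phi)) / 2
  diag(phi) <- 1
  dimnames(phi) <- NULL
  rownames(pattern) <- rownames(loadings)
  list(pattern = pattern, phi = phi, rotmat = rotmat)
}

#' Fit the factor model of the measure battery
#'
#' Correlation-matrix PCA of the harmonized measures (pain intensity
#' outcomes excluded upstream), component retention by the eigenvalue rule,
#' Promax rotation, loading thresholding at `loading_threshold` for
#' community membership, and regression-method scoring weights rotated into
#' the oblique basis so that subjects of another group can be scored with
#' this group's weights.
#'
#' A measure whose pattern loadings exceed the threshold on several
#' components is assigned to the one with the largest absolute loading
#' (ties broken by component order) and flagged as multi-loading.  Component
#' labels are taken from the majority registry community of each
#' component's members when a registry is supplied.
#'
#' @param x subjects x measures numeric matrix (harmonized scale), with
#'   column names.
#' @param config an [analysis_config()].
#' @param registry optional [measure_registry()] used to label components
#'   and to drop pain outcome columns if present.
#' @param kappa Promax power, see [promax_rotate()].
#' @return An object of class `factor_model`.
#' @export
fit_factor_model <- function(x, config = analysis_config(),
                             registry = NULL, kappa = 4) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x needs measure ids as column names")
  if (!is.null(registry)) {
    keep <- setdiff(colnames(x), outcome_measures(registry))
    x <- x[, keep, drop = FALSE]
  }
  p <- ncol(x)
  if (p < 3) stop("need at least 3 measures")
  if (nrow(x) <= p)
    warning("fewer subjects than measures; loadings will be unstable")
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance measure(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  z <- scale(x, center = ctr, scale = scl)
  r <- stats::cor(x)

  adequacy <- kmo(r)
  if (adequacy$overall < 0.5)
    warning(sprintf("overall KMO %.3f is below 0.5; sampling adequacy is poor",
                    adequacy$overall))

  eig <- eigen(r, symmetric = TRUE)
  ev <- eig$values
  k <- retain_components(ev, config$eigenvalue_cut)
  if (k < 1) stop("no component exceeds the eigenvalue cut")
  loadings <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(loadings) <- colnames(x)

  rot <- if (k >= 2) promax_rotate(loadings, kappa = kappa) else {
    s <- sign(loadings[which.max(abs(loadings))])
    list(pattern = s * loadings, phi = matrix(1, 1, 1), rotmat = matrix(s, 1, 1))
  }

  # membership by thresholded pattern loadings
  thr <- config$loading_threshold
  hits <- abs(rot$pattern) >= thr
  assigned <- apply(rot$pattern, 1, function(row) {
    over <- which(abs(row) >= thr)
    if (!length(over)) return(NA_integer_)
    over[which.max(abs(row[over]))]
  })
  membership <- data.frame(
    measure_id = colnames(x),
    component = assigned,
    loading = rot$pattern[cbind(seq_len(p), ifelse(is.na(assigned), 1, assigned))],
    multi_loading = rowSums(hits) > 1,
    stringsAsFactors = FALSE)
  membership$loading[is.na(assigned)] <- NA_real_

  labels <- paste0("C", seq_len(k))
  if (!is.null(registry)) {
    comm <- registry$community[match(colnames(x), registry$measure_id)]
    for (j in seq_len(k)) {
      members <- comm[which(assigned == j)]
      if (length(members)) {
        tab <- sort(table(members), decreasing = TRUE)
        labels[j] <- names(tab)[1]
      }
    }
  }
  colnames(rot$pattern) <- labels

  # regression-method weights (unrotated), rotated into the Promax basis
  w0 <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(1 / sqrt(ev[seq_len(k)]), k)
  weights <- w0 %*% solve(t(rot$rotmat))
  dimnames(weights) <- list(colnames(x), labels)

  structure(list(
    eigenvalues = ev,
    variance_explained = 100 * ev / p,
    loadings_unrotated = loadings,
    pattern = rot$pattern,
    phi = rot$phi,
    weights = weights,
    kmo_overall = adequacy$overall,
    kmo_per_measure = adequacy$per_measure,
    retained_k = as.integer(k),
    scree_elbow = attr(k, "scree_elbow"),
    component_labels = labels,
    membership = membership,
    center = ctr, scale = scl,
    measures = colnames(x),
    n = nrow(x),
    loading_threshold = thr,
    eigenvalue_cut = config$eigenvalue_cut,
    kappa = kappa), class = "factor_model")
}

#' Score subjects with a fitted factor model
#'
#' Computes component scores as standardized measures times the model's
#' scoring weights.  Standardization always uses the fitting sample's means
#' and SDs, so subjects from another group (e.g. the hip arm scored with
#' knee-arm weights) are projected into the same component space.
#'
#' @param model a [fit_factor_model()] result.
#' @param x subjects x measures matrix containing at least the model's
#'   measures.
#' @return Subjects x components score matrix.
#' @export
score_subjects <- function(model, x) {
  x <- as.matrix(x)
  missing_cols <- setdiff(model$measures, colnames(x))
  if (length(missing_cols))
    stop("missing measure column(s): ", paste(missing_cols, collapse = ", "))
  z <- scale(x[, model$measures, drop = FALSE],
             center = model$center, scale = model$scale)
  scores <- z %*% model$weights
  rownames(scores) <- rownames(x)
  scores
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor_model:", x$retained_k, "components retained of",
      length(x$eigenvalues), "measures (eigenvalue >",
      format(x$eigenvalue_cut), ")\n")
  cat("  variance explained by retained components:",
      sprintf("%.1f%%", sum(x$variance_explained[seq_len(x$retained_k)])), "\n")
  cat("  overall KMO:", sprintf("%.3f", x$kmo_overall), "\n")
  cat("  components:", paste(x$component_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Scree plot of a factor model
#'
#' @param x a `factor_model`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.factor_model <- function(x, ...) {
  graphics::plot(x$eigenvalues, type = "b", xlab = "Component",
                 ylab = "Eigenvalue", ...)
  graphics::abline(h = x$eigenvalue_cut, lty = 2)
}
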