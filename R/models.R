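#' Stepwise forward/backward regression with alpha-to-enter and
#' alpha-to-remove
#'
#' Iterative model construction: at each step the candidate with the
#' smallest partial-F p-value enters if it is below `alpha_enter`, then
#' included predictors with the largest p-value above `alpha_remove` are
#' removed, until the model is stable ("only parameters that survived both
#' forward and backward elimination").  Selection is deterministic given the
#' data; ties in p-values are broken by candidate column order.
#'
#' After selection, cases with studentized deleted residuals beyond
#' `outlier_sd` standard deviations are pruned (largest first, at most
#' `outlier_cap` cases, see [remove_outliers()]) and the selection is re-run
#' once on the pruned data.  Set `outlier_handling = "none"` to skip, or
#' `"before_selection"` to prune on the full candidate model first.
#'
#' @param x data frame of candidate predictors (numeric columns).
#' @param y numeric outcome.
#' @param config an [analysis_config()] supplying `alpha_enter`,
#'   `alpha_remove`, `outlier_sd` and `outlier_cap`.
#' @param outlier_handling when to run the studentized-residual pass.
#' @return An object of class `regression_fit`; see [apply_model()] for the
#'   fixed-predictor variant.
#' @export
stepwise_fit <- function(x, y, config = analysis_config(),
                         outlier_handling = c("after_selection",
                                              "before_selection", "none")) {
  outlier_handling <- match.arg(outlier_handling)
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (nrow(x) <= ncol(x) + 2)
    warning("n is small relative to the number of candidates")
  keep <- vapply(x, function(col) stats::sd(col) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping zero-variance candidate(s): ",
            paste(names(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))

  removed <- character(0)
  if (outlier_handling == "before_selection") {
    pruned <- remove_outliers(x, y, names(x), config)
    x <- pruned$x; y <- pruned$y; removed <- pruned$removed
  }
  selected <- select_stepwise(x, y, config)
  if (outlier_handling == "after_selection" && length(selected)) {
    pruned <- remove_outliers(x, y, selected, config)
    if (length(pruned$removed)) {
      x <- pruned$x; y <- pruned$y; removed <- pruned$removed
      selected <- select_stepwise(x, y, config)
    }
  }
  make_regression_fit(x, y, selected, removed, outcome = "y")
}

# one full forward/backward alternation; returns the selected predictor names
select_stepwise <- function(x, y, config) {
  dat <- cbind(.y = y, x)
  selected <- character(0)
  candidates <- names(x)
  max_iter <- 2L * length(candidates) + 10L
  for (iter in seq_len(max_iter + 1L)) {
    if (iter > max_iter)
      stop("stepwise selection did not converge (cycling); ",
           "check alpha_enter < alpha_remove")
    changed <- FALSE
    # forward: smallest entry p-value below alpha_enter
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      fit <- stats::lm(step_formula(selected), data = dat)
      add <- stats::add1(fit, scope = step_formula(union(selected, remaining)),
                         test = "F")
      pvals <- add[["Pr(>F)"]][-1]
      names(pvals) <- gsub("`", "", rownames(add)[-1])
      pvals <- pvals[remaining]  # candidate order breaks ties
      best <- which.min(pvals)
      if (length(best) && is.finite(pvals[best]) &&
          pvals[best] < config$alpha_enter) {
        selected <- c(selected, remaining[best])
        changed <- TRUE
      } else if (length(best) && !is.na(pvals[best]) && pvals[best] == 0) {
        selected <- c(selected, remaining[best])
        changed <- TRUE
      }
    }
    # backward: largest included p-value above alpha_remove
    if (length(selected)) {
      fit <- stats::lm(step_formula(selected), data = dat)
      drop <- stats::drop1(fit, test = "F")
      pvals <- drop[["Pr(>F)"]][-1]
      names(pvals) <- gsub("`", "", rownames(drop)[-1])
      pvals <- pvals[selected]
      worst <- which.max(pvals)
      if (length(worst) && is.finite(pvals[worst]) &&
          pvals[worst] > config$alpha_remove) {
        selected <- setdiff(selected, selected[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  selected
}

# env must hold `dat`, so that add1/drop1 can refit from the stored call
step_formula <- function(terms, env = parent.frame()) {
  txt <- if (!length(terms)) ".y ~ 1"
         else paste(".y ~", paste(sprintf("`%s`", terms), collapse = " + "))
  stats::as.formula(txt, env = env)
}

#' Remove regression outliers by studentized deleted residuals
#'
#' Cases with absolute studentized deleted residuals above `outlier_sd`
#' (default 3) are removed one at a time, largest first, refitting after
#' each removal, up to `outlier_cap` cases (default 3).
#'
#' @param x data frame of predictors.
#' @param y outcome vector.
#' @param predictors names of the predictors of the current model.
#' @param config an [analysis_config()].
#' @return A list with pruned `x`, `y`, and `removed` (row names of removed
#'   cases).
#' @export
remove_outliers <- function(x, y, predictors, config = analysis_config()) {
  x <- as.data.frame(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  removed <- character(0)
  repeat {
    if (length(removed) >= config$outlier_cap) break
    if (nrow(x) <= length(predictors) + 3)
      stop("outlier removal would leave too few cases")
    dat <- cbind(.y = y, x)
    fit <- stats::lm(step_formula(predictors), data = dat)
    rs <- stats::rstudent(fit)
    worst <- which.max(abs(rs))
    if (!length(worst) || !is.finite(rs[worst]) ||
        abs(rs[worst]) <= config$outlier_sd) break
    removed <- c(removed, rownames(x)[worst])
    x <- x[-worst, , drop = FALSE]
    y <- y[-worst]
  }
  list(x = x, y = y, removed = removed)
}

#' Refit a fixed predictor set on another sample
#'
#' Plain multiple regression (no selection) of a predictor set discovered
#' elsewhere — e.g. re-testing the predictors selected in the knee arm on
#' the hip arm.
#'
#' @param predictors character vector of predictor names.
#' @param x data frame containing those columns.
#' @param y outcome vector.
#' @return A `regression_fit`.
#' @export
apply_model <- function(predictors, x, y) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(predictors, names(x))
  if (length(missing_cols))
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) <= length(predictors) + 2)
    stop("too few cases for this predictor set")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  make_regression_fit(x, y, predictors, character(0), outcome = "y")
}

# assemble the coefficient table and model statistics
make_regression_fit <- function(x, y, selected, removed, outcome) {
  dat <- cbind(.y = y, x)
  fit <- stats::lm(step_formula(selected), data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients
  table <- if (length(selected)) {
    idx <- match(sprintf("`%s`", selected), rownames(coefs))
    idx[is.na(idx)] <- match(selected, rownames(coefs))[is.na(idx)]
    data.frame(
      predictor = selected,
      b = coefs[idx, 1],
      se = coefs[idx, 2],
      beta = coefs[idx, 1] *
        vapply(x[selected], stats::sd, numeric(1)) / stats::sd(y),
      t = coefs[idx, 3],
      p = coefs[idx, 4],
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(predictor = character(0), b = numeric(0), se = numeric(0),
               beta = numeric(0), t = numeric(0), p = numeric(0))
  }
  fstat <- sm$fstatistic
  structure(list(
    outcome = outcome,
    predictors = selected,
    table = table,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_value = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    df = if (!is.null(fstat)) unname(fstat[2:3]) else c(NA_real_, NA_real_),
    f_p = if (!is.null(fstat))
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)[[1]]
      else NA_real_,
    n = nrow(x),
    removed_outliers = removed,
    fit = fit), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, digits = 3, ...) {
  cat("regression_fit (n =", x$n, ")\n")
  if (!nrow(x$table)) {
    cat("  no predictive model - no variables entered the equation\n")
  } else {
    print(format(x$table, digits = digits), row.names = FALSE)
    cat(sprintf("  adjusted R^2 = %.3f, F(%d, %d) = %.3f, p = %.4g\n",
                x$adj_r_squared, x$df[1], x$df[2], x$f_value, x$f_p))
  }
  if (length(x$removed_outliers))
    cat("  removed outliers:", paste(x$removed_outliers, collapse = ", "), "\n")
  invisible(x)
}
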