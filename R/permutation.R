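# permutation-resampling inference for network statistics

# statistic evaluators: each takes two aligned subjects-x-measures matrices
# (pre, post) and returns a non-negative magnitude statistic
network_statistic <- function(statistic, fraction, louvain_reps) {
  switch(statistic,
    mean_delta_r = function(a, b)
      mean(abs(stats::cor(b) - stats::cor(a))[upper.tri(diag(ncol(a)))]),
    clustering = function(a, b) {
      ga <- binarize_top(stats::cor(a), fraction)
      gb <- binarize_top(stats::cor(b), fraction)
      abs(mean_clustering(gb) - mean_clustering(ga))
    },
    modularity = function(a, b) {
      ga <- binarize_top(stats::cor(a), fraction)
      gb <- binarize_top(stats::cor(b), fraction)
      pa <- graph_precompute(ga$graph)
      pb <- graph_precompute(gb$graph)
      qa <- mean(vapply(seq_len(louvain_reps), function(i)
        louvain_once(ga$graph, pa)$q, numeric(1)))
      qb <- mean(vapply(seq_len(louvain_reps), function(i)
        louvain_once(gb$graph, pb)$q, numeric(1)))
      abs(qb - qa)
    },
    stop("unknown statistic: ", statistic))
}

has_zero_variance <- function(m) {
  rng <- matrixStats_range(m)
  any(rng[1, ] == rng[2, ])
}

# column ranges without matrixStats: apply is fine at this scale
matrixStats_range <- function(m) apply(m, 2, range)

#' Permutation-resampling comparison of two visits
#'
#' Tests whether the network structure of a group changed between two
#' visits, using the within-subject visit-swap null: for each subject
#' independently, the pre- and post-surgery measure vectors are swapped
#' with probability one half, and the full statistic pipeline (correlation,
#' binarization where applicable, graph metric, delta) is recomputed on
#' each draw.  Under no surgery effect the two visits are exchangeable
#' within subject, so the observed statistic is calibrated against this
#' null.  The resampling probability is one-sided on the magnitude
#' statistic with the add-one correction,
#' `(1 + #(null >= observed)) / (1 + reps)`, and so never returns 0.
#'
#' @param pre,post aligned subjects x measures matrices (same subjects,
#'   same row order; same measures).
#' @param statistic `"mean_delta_r"`, `"clustering"`, or `"modularity"`.
#' @param reps number of resampling draws.
#' @param seed integer seed; the probability is deterministic given it.
#' @param fraction binarization fraction for the graph statistics.
#' @param louvain_reps Louvain repetitions inside each modularity
#'   evaluation (applied identically to the observed statistic and every
#'   draw).
#' @return A `permutation_result`: statistic name, observed value, all null
#'   draws, the resampling probability, seed, and scheme.
#' @export
permute_compare <- function(pre, post,
                            statistic = c("mean_delta_r", "clustering",
                                          "modularity"),
                            reps = 10000L, seed = NULL,
                            fraction = 0.25, louvain_reps = 20L) {
  statistic <- match.arg(statistic)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post)))
    stop("pre and post matrices must be aligned")
  if (reps < 100) warning("fewer than 100 resampling draws")
  n <- nrow(pre)
  stat_fun <- network_statistic(statistic, fraction, louvain_reps)
  with_seed(seed, {
    observed <- stat_fun(pre, post)
    draws <- numeric(reps)
    n_redrawn <- 0L
    for (i in seq_len(reps)) {
      repeat {
        swap <- stats::runif(n) < 0.5
        a <- pre; b <- post
        a[swap, ] <- post[swap, , drop = FALSE]
        b[swap, ] <- pre[swap, , drop = FALSE]
        if (!has_zero_variance(a) && !has_zero_variance(b)) break
        n_redrawn <- n_redrawn + 1L
      }
      draws[i] <- stat_fun(a, b)
    }
    structure(list(statistic = statistic, observed = observed,
                   draws = draws,
                   probability = (1 + sum(draws >= observed)) / (1 + reps),
                   reps = reps, seed = seed,
                   scheme = "within_subject_visit",
                   n_redrawn = n_redrawn),
              class = "permutation_result")
  })
}

#' Permutation comparison of a change statistic between two groups
#'
#' Tests whether the magnitude of a change statistic (e.g. mean delta-r
#' from baseline to 3 months) differs between two groups, by reshuffling
#' subjects between the groups while preserving group sizes; each subject
#' carries its (pre, post) pair of measure vectors through the shuffle.
#'
#' @param pre1,post1 aligned matrices of group 1.
#' @param pre2,post2 aligned matrices of group 2.
#' @param statistic,reps,seed,fraction,louvain_reps see [permute_compare()].
#' @return A `permutation_result` with scheme `"between_group"`; the
#'   observed value is `|stat(group1) - stat(group2)|`.
#' @export
permute_compare_groups <- function(pre1, post1, pre2, post2,
                                   statistic = c("mean_delta_r", "clustering",
                                                 "modularity"),
                                   reps = 10000L, seed = NULL,
                                   fraction = 0.25, louvain_reps = 20L) {
  statistic <- match.arg(statistic)
  pre <- rbind(as.matrix(pre1), as.matrix(pre2))
  post <- rbind(as.matrix(post1), as.matrix(post2))
  n1 <- nrow(pre1); n <- nrow(pre)
  if (reps < 100) warning("fewer than 100 resampling draws")
  stat_fun <- network_statistic(statistic, fraction, louvain_reps)
  grp_stat <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    abs(stat_fun(pre[idx1, , drop = FALSE], post[idx1, , drop = FALSE]) -
        stat_fun(pre[idx2, , drop = FALSE], post[idx2, , drop = FALSE]))
  }
  with_seed(seed, {
    observed <- grp_stat(seq_len(n1))
    draws <- numeric(reps)
    for (i in seq_len(reps)) draws[i] <- grp_stat(sample.int(n, n1))
    structure(list(statistic = statistic, observed = observed,
                   draws = draws,
                   probability = (1 + sum(draws >= observed)) / (1 + reps),
                   reps = reps, seed = seed, scheme = "between_group",
                   n_redrawn = 0L),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %s (%s)\n", x$statistic, x$scheme))
  cat(sprintf("  observed = %.4f, p = %.4g (%d draws)\n",
              x$observed, x$probability, x$reps))
  invisible(x)
}
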