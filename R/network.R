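#' Pearson correlation matrix of a harmonized measure matrix
#'
#' @param x subjects x measures matrix with no missing cells (preprocessing
#'   is upstream), n >= 4.
#' @param group,visit optional labels carried as attributes.
#' @return A `correlation_matrix`: the symmetric Pearson matrix with
#'   attributes `n`, `group`, `visit`.
#' @export
correlation_matrix <- function(x, group = NULL, visit = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("need at least 4 subjects")
  if (anyNA(x)) stop("missing cells; run preprocessing first")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance measure(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  structure(r, n = nrow(x), group = group, visit = visit,
            class = c("correlation_matrix", "matrix"))
}

#' Fisher z comparison of two correlation coefficients
#'
#' Tests the difference of two independent-sample correlations:
#' `z = (atanh(r2) - atanh(r1)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value.
#'
#' @param r1,r2 correlation coefficients, |r| < 1.
#' @param n1,n2 sample sizes, each > 3.
#' @return A list with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1))
    stop("|r| = 1 has an infinite z transform")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples")
  z <- (atanh(r2) - atanh(r1)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Binarize a correlation matrix at its strongest fraction of pairs
#'
#' Ranks the `choose(p, 2)` measure pairs by absolute correlation
#' (configurable to positive-only) and keeps the top
#' `round(fraction * choose(p, 2))` (half-up) as unweighted undirected
#' edges.  Ties are broken deterministically: higher |r| first, then
#' lexicographic pair order.  Community labels (typically the factor-model
#' membership) are attached to the nodes.
#'
#' @param corr a [correlation_matrix()] (or plain symmetric matrix with
#'   column names).
#' @param fraction fraction of pairs kept, in (0, 1\].
#' @param communities named vector of community labels per measure, or
#'   `NULL` for `"unassigned"`.
#' @param rank_by `"absolute"` (default; both signs can form edges) or
#'   `"positive"`.
#' @return A `binary_network`: list with the `igraph` graph, `edges` data
#'   frame, `fraction`, and node metadata.
#' @export
binarize_top <- function(corr, fraction = 0.25, communities = NULL,
                         rank_by = c("absolute", "positive")) {
  rank_by <- match.arg(rank_by)
  r <- as.matrix(corr)
  p <- ncol(r)
  if (p < 3) stop("need at least 3 nodes")
  ids <- colnames(r) %||% paste0("V", seq_len(p))
  n_pairs <- choose(p, 2)
  m <- round_half_up(fraction * n_pairs)
  if (m < 1) stop("fraction ", fraction, " yields zero edges")

  ut <- which(upper.tri(r), arr.ind = TRUE)
  strength <- if (rank_by == "absolute") abs(r[ut]) else r[ut]
  ord <- order(-strength, ut[, 1], ut[, 2])
  keep <- ut[ord[seq_len(m)], , drop = FALSE]

  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, t(keep))
  comm <- if (is.null(communities)) rep("unassigned", p)
          else unname(communities[ids])
  comm[is.na(comm)] <- "unassigned"
  igraph::V(g)$community <- comm

  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      r = r[keep], stringsAsFactors = FALSE)
  structure(list(graph = g, edges = edges, fraction = fraction,
                 nodes = ids, communities = stats::setNames(comm, ids),
                 n_subjects = attr(corr, "n", exact = TRUE),
                 group = attr(corr, "group", exact = TRUE),
                 visit = attr(corr, "visit", exact = TRUE)),
            class = "binary_network")
}

#' Mean local clustering coefficient
#'
#' The local coefficient of node i is `2 * triangles(i) / (k_i (k_i - 1))`;
#' nodes of degree below 2 contribute 0.  The network-level value is the
#' mean over all nodes, ranging from 0 (no clustering) to 1 (maximal
#' clustering).
#'
#' @param net a [binarize_top()] network (or an `igraph` graph).
#' @return The mean local clustering coefficient.
#' @export
mean_clustering <- function(net) {
  g <- if (inherits(net, "binary_network")) net$graph else net
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  local[is.na(local)] <- 0  # degree-1 nodes
  mean(local)
}

# neighbor lists, degrees and edge count reused across Louvain repetitions
graph_precompute <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  list(n = n, m = nrow(el), edges = el, adj = adj,
       deg = vapply(adj, length, integer(1)))
}

# Newman-Girvan Q of a partition, from precomputed structures
partition_q <- function(pre, mem) {
  same <- mem[pre$edges[, 1]] == mem[pre$edges[, 2]]
  e_c <- sum(same) / pre$m
  d_c <- tapply(pre$deg, mem, sum) / (2 * pre$m)
  e_c - sum(d_c^2)
}

# single-node refinement: greedily move nodes between communities while Q
# improves; escapes the local optima the aggregated Louvain phase leaves
# behind on small graphs
refine_partition <- function(pre, mem) {
  m <- pre$m; s2 <- (2 * m)^2
  comm_deg <- numeric(max(mem))
  for (v in seq_len(pre$n)) comm_deg[mem[v]] <- comm_deg[mem[v]] + pre$deg[v]
  next_label <- length(comm_deg) + 1L
  repeat {
    improved <- FALSE
    for (v in sample.int(pre$n)) {
      kv <- pre$deg[v]
      if (kv == 0) next
      cv <- mem[v]
      nb_comm <- mem[pre$adj[[v]]]
      l_to <- table(nb_comm)
      l_vc <- if (as.character(cv) %in% names(l_to))
        l_to[[as.character(cv)]] else 0
      cand <- unique(c(as.integer(names(l_to)), 0L))  # 0 = fresh singleton
      best_dq <- 1e-12; best_d <- NA_integer_
      for (d in cand) {
        if (d == cv) next
        l_vd <- if (d > 0 && as.character(d) %in% names(l_to))
          l_to[[as.character(d)]] else 0
        dd <- if (d > 0) comm_deg[d] else 0
        dq <- (l_vd - l_vc) / m - 2 * kv * (dd - comm_deg[cv] + kv) / s2
        if (dq > best_dq) { best_dq <- dq; best_d <- d }
      }
      if (!is.na(best_d)) {
        comm_deg[cv] <- comm_deg[cv] - kv
        if (best_d == 0L) {
          mem[v] <- next_label
          comm_deg[next_label] <- kv
          next_label <- next_label + 1L
        } else {
          mem[v] <- best_d
          comm_deg[best_d] <- comm_deg[best_d] + kv
        }
        improved <- TRUE
      }
    }
    # merge pass: joining two communities can escape optima that
    # single-node moves cannot
    repeat {
      labs <- sort(unique(mem))
      if (length(labs) < 2) break
      cd <- comm_deg[labs]
      between <- matrix(0, length(labs), length(labs))
      li <- match(mem[pre$edges[, 1]], labs)
      lj <- match(mem[pre$edges[, 2]], labs)
      for (e in seq_along(li)) if (li[e] != lj[e]) {
        between[li[e], lj[e]] <- between[li[e], lj[e]] + 1
        between[lj[e], li[e]] <- between[lj[e], li[e]] + 1
      }
      dq_merge <- between / m - 2 * outer(cd, cd) / s2
      diag(dq_merge) <- -Inf
      if (max(dq_merge) <= 1e-12) break
      pick <- which(dq_merge == max(dq_merge), arr.ind = TRUE)[1, ]
      keep <- labs[pick[1]]; gone <- labs[pick[2]]
      mem[mem == gone] <- keep
      comm_deg[keep] <- comm_deg[keep] + comm_deg[gone]
      comm_deg[gone] <- 0
      improved <- TRUE
    }
    if (!improved) break
  }
  mem
}

# one Louvain repetition on a random node order, with refinement; each
# restart refines an additional random coarse partition and the best
# result is kept (escapes local optima on weakly modular graphs)
louvain_once <- function(g, pre, restarts = 0L) {
  perm <- sample.int(pre$n)
  gp <- igraph::permute(g, perm)
  mem <- igraph::membership(igraph::cluster_louvain(gp))[perm]
  mem <- refine_partition(pre, as.integer(mem))
  q <- partition_q(pre, mem)
  for (r in seq_len(restarts)) {
    k <- max(2L, ceiling(pre$n / 4))
    mem2 <- refine_partition(pre, sample.int(k, pre$n, replace = TRUE))
    q2 <- partition_q(pre, mem2)
    if (q2 > q) { q <- q2; mem <- mem2 }
  }
  list(q = q, membership = mem)
}

#' Louvain modularity averaged over repetitions
#'
#' Runs Louvain community detection `reps` times, each on an independently
#' randomized node order followed by a single-node refinement sweep, and
#' reports the mean and SD of the Newman-Girvan modularity Q (resolution 1)
#' together with the best partition found.
#'
#' @param net a [binarize_top()] network or `igraph` graph with at least
#'   one edge.
#' @param reps number of repetitions.
#' @param seed integer seed; results are deterministic given the seed.
#' @param restarts additional random-restart refinements per repetition
#'   (default 1; the permutation machinery uses 0 for speed, identically
#'   on observed and resampled networks).
#' @return A `network_metrics` object with `q_mean`, `q_sd`, `q_values`,
#'   `best_membership`, `reps`, and `mean_clustering` of the same network.
#' @export
louvain_modularity <- function(net, reps = 100L, seed = NULL,
                               restarts = 1L) {
  g <- if (inherits(net, "binary_network")) net$graph else net
  if (igraph::ecount(g) < 1) stop("graph has no edges")
  pre <- graph_precompute(g)
  with_seed(seed, {
    best_q <- -Inf; best_membership <- NULL
    q <- numeric(reps)
    for (i in seq_len(reps)) {
      rep_i <- louvain_once(g, pre, restarts)
      q[i] <- rep_i$q
      if (q[i] > best_q) {
        best_q <- q[i]
        best_membership <- rep_i$membership
      }
    }
    names(best_membership) <- igraph::V(g)$name
    structure(list(q_mean = mean(q), q_sd = stats::sd(q), q_values = q,
                   best_membership = best_membership, reps = reps,
                   mean_clustering = mean_clustering(g)),
              class = "network_metrics")
  })
}

#' Change in pairwise correlations between two timepoints
#'
#' Computes the per-pair change `r_b - r_a` and its network-level summary,
#' the mean over all `choose(p, 2)` pairs of the absolute change (mean
#' delta-r).  The signed mean is reported alongside, since correlations can
#' both strengthen and weaken.
#'
#' @param corr_a,corr_b two [correlation_matrix()] objects over the same
#'   measures in the same order.
#' @return A `network_comparison`: list with `mean_delta_r` (mean absolute
#'   change), `mean_delta_r_signed`, and the per-pair `delta` matrix.
#' @export
mean_delta_r <- function(corr_a, corr_b) {
  a <- as.matrix(corr_a); b <- as.matrix(corr_b)
  if (!identical(dim(a), dim(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("correlation matrices cover different measures")
  delta <- b - a
  ut <- upper.tri(delta)
  structure(list(mean_delta_r = mean(abs(delta[ut])),
                 mean_delta_r_signed = mean(delta[ut]),
                 delta = delta, n_pairs = sum(ut)),
            class = "network_comparison")
}
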