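# Independent brute-force oracles: these never call the package's own graph
# code paths, only plain adjacency-matrix arithmetic.

# adjacency matrix of a binary_network / igraph graph
adjacency_of <- function(net) {
  g <- if (inherits(net, "binary_network")) net$graph else net
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# mean local clustering coefficient by exhaustive triangle counting
brute_mean_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) { vals[i] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
    vals[i] <- 2 * tri / (k * (k - 1))
  }
  mean(vals)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1
    if (i > n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# Newman-Girvan modularity of a partition, from the adjacency matrix
modularity_of_partition <- function(adj, membership) {
  m2 <- sum(adj)  # 2m for a symmetric 0/1 matrix
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(adj[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

# globally optimal modularity by exhaustive search over all partitions
brute_optimal_modularity <- function(adj) {
  parts <- all_partitions(nrow(adj))
  max(vapply(parts, function(p) modularity_of_partition(adj, p), numeric(1)))
}

# random connected-ish undirected graph as an adjacency matrix
random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  on <- ut[stats::runif(length(ut)) < p_edge]
  if (!length(on)) on <- ut[1]
  adj[on] <- 1L
  adj + t(adj)
}

graph_from_adjacency <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# greedy best one-to-one map from model components to planted communities;
# returns the number of measures whose assigned component maps to their
# planted community
community_recovery_count <- function(model, planted) {
  comp <- model$membership$component
  names(comp) <- model$membership$measure_id
  planted <- planted[names(comp)]
  k <- model$retained_k
  labels <- unique(planted)
  tab <- matrix(0, k, length(labels), dimnames = list(NULL, labels))
  for (j in seq_len(k)) {
    members <- planted[which(comp == j)]
    if (length(members))
      for (lb in members) tab[j, lb] <- tab[j, lb] + 1
  }
  total <- 0
  used_j <- integer(0); used_l <- character(0)
  for (step in seq_len(min(k, length(labels)))) {
    cand <- tab
    if (length(used_j)) cand[used_j, ] <- -1
    if (length(used_l)) cand[, used_l] <- -1
    best <- which(cand == max(cand), arr.ind = TRUE)[1, , drop = FALSE]
    if (cand[best] <= 0) break
    total <- total + tab[best]
    used_j <- c(used_j, best[1])
    used_l <- c(used_l, colnames(tab)[best[2]])
  }
  total
}

# synthetic spec with no surgery effect (exchangeable visits)
null_synthetic_spec <- function(n_koa = 84L, n_hoa = 0L, rng_seed = 1L) {
  scales <- c("BPI-PS", "NRS", "KOOS-P", "SF36-BP")
  synthetic_spec(
    n_koa = n_koa, n_hoa = n_hoa,
    retention = matrix(1, 4, 2, dimnames = list(scales, c("KOA", "HOA"))),
    rewire_strength = c(KOA = 0, HOA = 0),
    rng_seed = rng_seed)
}

# harmonized baseline/m3 matrices of one arm of a generated cohort
arm_matrices <- function(spec, group = "KOA", visits = c("baseline", "m3")) {
  gen <- generate_cohort(spec)
  lapply(visits, function(v)
    harmonize_visit(gen$cohort, v, group)$matrix)
}
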