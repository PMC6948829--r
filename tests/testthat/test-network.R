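test_that("correlation matrices satisfy their contract", {
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  x[, 2] <- x[, 1]            # identical columns
  x[, 3] <- -x[, 1]           # anti-correlated
  r <- correlation_matrix(x)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(unclass(r), t(unclass(r)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(r, "n"), 10)

  big <- matrix(rnorm(10000), 5000, 2, dimnames = list(NULL, c("u", "v")))
  expect_lt(abs(correlation_matrix(big)["u", "v"]), 0.05)

  x[, 4] <- 7
  expect_error(correlation_matrix(x), "d")
  expect_error(correlation_matrix(x[1:3, ]), "4 subjects")
})

test_that("Fisher z comparison matches the closed form", {
  res0 <- fisher_z_compare(0.4, 50, 0.4, 60)
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # Table-2-sized example: KOA BPI-KOOS r at baseline vs 3 months
  res <- fisher_z_compare(0.266, 84, 0.837, 84)
  expect_equal(res$z, 5.972674, tolerance = 1e-5)
  expect_lt(res$p, 1e-8)
  # p decreases monotonically in |r2 - r1|
  ps <- sapply(seq(0.3, 0.8, by = 0.1),
               function(r2) fisher_z_compare(0.3, 84, r2, 84)$p)
  expect_true(all(diff(ps) <= 0))
  expect_error(fisher_z_compare(1, 50, 0.5, 50), "infinite")
  expect_error(fisher_z_compare(0.2, 3, 0.5, 50), "n > 3")
})

test_that("binarization keeps the strongest fraction with deterministic ties", {
  # 4 nodes, |r| = AB .9, BD .8, BC .3, AD .2, AC .1, CD .05; 25% of 6 -> 2
  r <- diag(4)
  dimnames(r) <- list(LETTERS[1:4], LETTERS[1:4])
  set_r <- function(i, j, v) { r[i, j] <<- v; r[j, i] <<- v }
  set_r("A", "B", 0.9); set_r("B", "D", -0.8); set_r("B", "C", 0.3)
  set_r("A", "D", 0.2); set_r("A", "C", 0.1); set_r("C", "D", 0.05)
  net <- binarize_top(r, 0.25)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$from, net$edges$to), c("A B", "B D"))
  # positive-only ranking drops the negative edge
  net_pos <- binarize_top(r, 0.25, rank_by = "positive")
  expect_setequal(paste(net_pos$edges$from, net_pos$edges$to),
                  c("A B", "B C"))

  # the study's network size: 21 nodes, 25% of 210 pairs -> 53 edges
  set.seed(3)
  x <- matrix(rnorm(21 * 50), 50, 21,
              dimnames = list(NULL, paste0("m", 1:21)))
  net21 <- binarize_top(correlation_matrix(x), 0.25)
  expect_equal(nrow(net21$edges), 53)
  expect_equal(igraph::ecount(net21$graph), 53)

  full <- binarize_top(r, 1.0)
  expect_equal(nrow(full$edges), 6)
  expect_error(binarize_top(r, 0.01), "zero edges")
})

test_that("edge counts and edge sets obey the binarization invariants", {
  set.seed(9)
  for (i in 1:10) {
    p <- sample(5:15, 1)
    frac <- runif(1, 0.1, 0.9)
    x <- matrix(rnorm(p * 40), 40, p, dimnames = list(NULL, paste0("v", 1:p)))
    r <- correlation_matrix(x)
    net <- binarize_top(r, frac)
    expect_equal(nrow(net$edges), floor(frac * choose(p, 2) + 0.5))
    # invariance to a monotone transform of |r|
    r3 <- unclass(r); r3 <- sign(r3) * abs(r3)^3; diag(r3) <- 1
    net3 <- binarize_top(r3, frac)
    expect_setequal(paste(net$edges$from, net$edges$to),
                    paste(net3$edges$from, net3$edges$to))
  }
})

test_that("mean clustering matches hand-enumerated triangle counts", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(mean_clustering(tri), 1)
  path <- igraph::make_graph(~ a - b, b - d)
  expect_equal(mean_clustering(path), 0)
  g <- igraph::make_graph(~ n1 - n2, n1 - n3, n2 - n3, n3 - n4)
  expect_equal(mean_clustering(g), 7 / 12)
})

test_that("mean clustering equals the brute-force oracle on random graphs", {
  set.seed(42)
  for (i in 1:40) {
    adj <- random_adjacency(sample(3:7, 1), runif(1, 0.2, 0.8))
    g <- graph_from_adjacency(adj)
    expect_equal(mean_clustering(g), brute_mean_clustering(adj))
  }
})

test_that("Louvain modularity is exact on analysable graphs", {
  two_tri <- igraph::make_graph(~ a - b, b - c, a - c, d - e, e - f, d - f)
  m <- louvain_modularity(two_tri, reps = 25, seed = 1)
  expect_equal(m$q_values, rep(0.5, 25))
  expect_equal(m$q_sd, 0)

  clique <- igraph::make_full_graph(5)
  mc <- louvain_modularity(clique, reps = 10, seed = 2)
  expect_equal(mc$q_mean, 0)

  expect_error(louvain_modularity(igraph::make_empty_graph(3, FALSE), 10, 1),
               "no edges")
  # determinism
  g <- graph_from_adjacency(random_adjacency(8, 0.4))
  m1 <- louvain_modularity(g, reps = 20, seed = 5)
  m2 <- louvain_modularity(g, reps = 20, seed = 5)
  expect_identical(m1$q_values, m2$q_values)
  expect_identical(m1$best_membership, m2$best_membership)
})

test_that("Louvain never beats, and nearly reaches, the exhaustive optimum", {
  set.seed(7)
  for (i in 1:6) {
    adj <- random_adjacency(sample(5:8, 1), runif(1, 0.25, 0.6))
    opt <- brute_optimal_modularity(adj)
    m <- louvain_modularity(graph_from_adjacency(adj), reps = 30, seed = i)
    expect_lte(max(m$q_values), opt + 1e-12)
    expect_gte(m$q_mean, opt - 0.02)
  }
})

test_that("mean delta-r is the average absolute pairwise change", {
  set.seed(4)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r <- correlation_matrix(x)
  expect_equal(mean_delta_r(r, r)$mean_delta_r, 0)

  mk <- function(ab, ac, bc) {
    m <- diag(3); dimnames(m) <- list(c("a","b","c"), c("a","b","c"))
    m["a","b"] <- m["b","a"] <- ab
    m["a","c"] <- m["c","a"] <- ac
    m["b","c"] <- m["c","b"] <- bc
    m
  }
  d <- mean_delta_r(mk(0.2, 0.4, -0.1), mk(0.5, 0.4, 0.3))
  expect_equal(d$mean_delta_r, (0.3 + 0 + 0.4) / 3)
  expect_equal(d$n_pairs, 3)
  expect_lte(d$mean_delta_r, 2)
  expect_error(mean_delta_r(r, correlation_matrix(x[, c(2, 1, 3)])),
               "different measures")
})

test_that("permutation probabilities are deterministic and well-formed", {
  set.seed(10)
  pre <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("m", 1:10)))
  post <- pre + matrix(rnorm(200, sd = 0.5), 20, 10)
  p1 <- permute_compare(pre, post, "mean_delta_r", reps = 200, seed = 6)
  p2 <- permute_compare(pre, post, "mean_delta_r", reps = 200, seed = 6)
  expect_identical(p1$probability, p2$probability)
  expect_identical(p1$draws, p2$draws)
  expect_gt(p1$probability, 0)
  expect_lte(p1$probability, 1)
  expect_length(p1$draws, 200)
  expect_warning(permute_compare(pre, post, "mean_delta_r", reps = 50,
                                 seed = 1), "100")
  # invariance to measure ordering (same seed, permuted columns)
  perm <- sample(10)
  p3 <- permute_compare(pre[, perm], post[, perm], "mean_delta_r",
                        reps = 200, seed = 6)
  expect_identical(p3$probability, p1$probability)
})

test_that("graph-statistic permutation tests run the full pipeline per draw", {
  set.seed(12)
  pre <- matrix(rnorm(22 * 10), 22, 10, dimnames = list(NULL, paste0("m", 1:10)))
  post <- matrix(rnorm(22 * 10), 22, 10, dimnames = list(NULL, paste0("m", 1:10)))
  pc <- permute_compare(pre, post, "clustering", reps = 120, seed = 2)
  expect_equal(pc$statistic, "clustering")
  expect_true(all(pc$draws >= 0 & pc$draws <= 1))
  pm <- permute_compare(pre, post, "modularity", reps = 120, seed = 3,
                        louvain_reps = 5)
  expect_true(all(is.finite(pm$draws)))
})

test_that("between-group resampling preserves group sizes", {
  set.seed(13)
  mk <- function(n) matrix(rnorm(n * 8), n, 8,
                           dimnames = list(NULL, paste0("m", 1:8)))
  pre1 <- mk(30); post1 <- mk(30); pre2 <- mk(10); post2 <- mk(10)
  res <- permute_compare_groups(pre1, post1, pre2, post2,
                                "mean_delta_r", reps = 150, seed = 4)
  expect_equal(res$scheme, "between_group")
  expect_gte(res$observed, 0)
  expect_gt(res$probability, 0)
  expect_lte(res$probability, 1)
  res2 <- permute_compare_groups(pre1, post1, pre2, post2,
                                 "mean_delta_r", reps = 150, seed = 4)
  expect_identical(res2$draws, res$draws)
})
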