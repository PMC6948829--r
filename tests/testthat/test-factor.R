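test_that("KMO matches hand-computed anti-image values", {
  # equicorrelated 3x3 at r = 0.5: partial correlations are all 1/3,
  # overall = 6*0.25 / (6*0.25 + 6*(1/9)) = 0.6923...
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  res <- kmo(r)
  expect_equal(res$overall, 0.6923076923, tolerance = 1e-9)
  expect_equal(unname(res$per_measure), rep(0.6923076923, 3),
               tolerance = 1e-9)

  # near-identity: r and partial r agree at first order -> overall ~ 0.5
  r2 <- diag(4); r2[upper.tri(r2)] <- r2[lower.tri(r2)] <- 1e-6
  expect_equal(kmo(r2)$overall, 0.5, tolerance = 1e-3)

  # block structure: per-measure values equal within a block
  rb <- diag(4)
  rb[1, 2] <- rb[2, 1] <- 0.8
  rb[3, 4] <- rb[4, 3] <- 0.8
  per <- kmo(rb)$per_measure
  expect_equal(per[1], per[2])
  expect_equal(per[3], per[4])

  singular <- matrix(1, 3, 3)
  expect_error(kmo(singular), "singular")
})

test_that("component retention uses a strict eigenvalue cut", {
  expect_equal(as.integer(retain_components(c(3.2, 2.1, 1.4, 1.01, 0.99))), 4L)
  expect_equal(as.integer(retain_components(rep(1.0, 5))), 0L)
  expect_error(retain_components(numeric(0)), "eigenvalues")
  k <- retain_components(c(5, 4, 1.2, 0.3, 0.2))
  expect_equal(attr(k, "scree_elbow"), 2L)  # largest drop after component 2
})

test_that("promax rotation leaves perfect simple structure alone", {
  L <- rbind(matrix(c(0.8, 0), 4, 2, byrow = TRUE),
             matrix(c(0, 0.8), 4, 2, byrow = TRUE))
  res <- promax_rotate(L)
  perm_ok <- FALSE
  for (perm in list(1:2, 2:1)) {
    if (max(abs(abs(res$pattern[, perm]) - abs(L))) < 0.05) perm_ok <- TRUE
  }
  expect_true(perm_ok)
  expect_lt(max(abs(res$phi[upper.tri(res$phi)])), 0.05)
})

test_that("promax agrees with the reference implementation in stats", {
  set.seed(99)
  for (case in 1:5) {
    L <- matrix(rnorm(16), 8, 2)
    mine <- promax_rotate(L)
    oracle <- unclass(stats::promax(L, m = 4)$loadings)
    matched <- FALSE
    for (perm in list(1:2, 2:1)) {
      o <- oracle[, perm, drop = FALSE]
      s <- sign(colSums(mine$pattern * o)); s[s == 0] <- 1
      o <- sweep(o, 2, s, "*")
      if (max(abs(mine$pattern - o)) < 1e-8) matched <- TRUE
    }
    expect_true(matched)
    expect_equal(mine$phi, t(mine$phi))
    expect_equal(diag(mine$phi), rep(1, 2))
  }
  expect_warning(promax_rotate(matrix(rnorm(8), 8, 1)), "identity")
})

test_that("factor model recovers planted structure on one default cohort", {
  gen <- generate_cohort(synthetic_spec(n_hoa = 0L, rng_seed = 13))
  h <- harmonize_visit(gen$cohort, "baseline", "KOA")
  fm <- fit_factor_model(h$matrix, registry = default_registry())
  expect_equal(fm$retained_k, 5L)
  expect_equal(sum(fm$eigenvalues), 21, tolerance = 1e-8)
  expect_gt(fm$kmo_overall, 0.5)
  expect_gte(community_recovery_count(fm, gen$truth$communities), 19)
  # rotated and unrotated models span the same column space
  qr_u <- qr(fm$loadings_unrotated)
  resid <- fm$pattern - qr.fitted(qr_u, fm$pattern)
  expect_lt(max(abs(resid)), 1e-8)
  # component labels match the planted community names
  expect_setequal(fm$component_labels,
                  c("Affect", "Pain Catastrophizing", "Pain Quality",
                    "Health", "Physical Performance"))
})

test_that("single-factor data retains one component", {
  set.seed(5)
  x <- sample_measure_matrix(matrix(0.9, 6, 1), 0.3, 200, seed = 5)
  colnames(x) <- paste0("m", 1:6)
  fm <- suppressWarnings(fit_factor_model(x))
  expect_equal(fm$retained_k, 1L)
})

test_that("scoring is centered on the fitting sample and transfers", {
  gen <- generate_cohort(synthetic_spec(rng_seed = 21))
  h_koa <- harmonize_visit(gen$cohort, "baseline", "KOA")
  fm <- fit_factor_model(h_koa$matrix, registry = default_registry())
  sc <- score_subjects(fm, h_koa$matrix)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  # an all-mean subject scores zero on every component
  mid <- matrix(fm$center, 1, dimnames = list("mid", fm$measures))
  expect_lt(max(abs(score_subjects(fm, mid))), 1e-10)
  # hip-arm subjects projected through knee-arm weights recover their
  # planted factor scores
  h_hoa <- harmonize_visit(gen$cohort, "baseline", "HOA")
  sc_hoa <- score_subjects(fm, h_hoa$matrix)
  cc <- abs(cor(sc_hoa, gen$truth$factor_scores$HOA$baseline))
  expect_true(all(apply(cc, 2, max) > 0.8))
  expect_error(score_subjects(fm, h_hoa$matrix[, 1:10]), "missing measure")
})

test_that("promax factor correlations vanish for orthogonal planted factors", {
  L <- default_loading_matrix()
  x <- sample_measure_matrix(L, 0.15, 2000, seed = 17)
  fm <- fit_factor_model(x)
  off <- fm$phi[upper.tri(fm$phi)]
  expect_lt(max(abs(off)), 0.15)
})

test_that("pain outcome columns are excluded from the factor stage", {
  gen <- generate_cohort(synthetic_spec(n_koa = 60L, n_hoa = 0L, rng_seed = 2))
  reg <- default_registry()
  h_all <- harmonize_visit(gen$cohort, "baseline", "KOA",
                           measures = reg$measure_id)
  fm <- fit_factor_model(h_all$matrix, registry = reg)
  expect_equal(sort(fm$measures),
               sort(reg$measure_id[!reg$is_pain_outcome]))
})
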