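#' Default latent-factor loading matrix
#'
#' Simple-structure loadings for the 21 non-outcome measures on the five
#' latent dimensions (Affect, Pain Catastrophizing, Pain Quality, Health,
#' Physical Performance), taken from the community labels of the registry.
#' Each measure loads `loading` (default 0.75) on its own factor and 0
#' elsewhere.  Loadings are expressed in native orientation: measures scored
#' higher-is-better (KOOS, SF-36 subscales, 6MWT) load negatively on their
#' burden factor, so that e.g. walking distance falls as physical-performance
#' burden rises.
#'
#' @param registry a [measure_registry()].
#' @param loading absolute loading on the own factor.
#' @return A 21 x 5 matrix with measure ids as row names and factor labels
#'   as column names.
#' @export
default_loading_matrix <- function(registry = default_registry(),
                                   loading = 0.75) {
  reg <- registry[!registry$is_pain_outcome, , drop = FALSE]
  factors <- unique(reg$community)
  L <- matrix(0, nrow(reg), length(factors),
              dimnames = list(reg$measure_id, factors))
  sgn <- ifelse(reg$orientation == "higher_is_better", -1, 1)
  L[cbind(seq_len(nrow(reg)), match(reg$community, factors))] <- sgn * loading
  L
}

#' Anchored baseline pain-scale parameters
#'
#' Baseline means and SDs of the four pain outcome scales per group on the
#' harmonized 0-10 scale, anchored to the observed cohort values.
#'
#' @return A list of `mean` and `sd` matrices (scale x group).
#' @export
default_pain_baseline <- function() {
  list(
    mean = cbind(KOA = c(`BPI-PS` = 4.79, NRS = 6.53, `KOOS-P` = 6.49,
                         `SF36-BP` = 7.04),
                 HOA = c(`BPI-PS` = 4.38, NRS = 6.09, `KOOS-P` = 5.86,
                         `SF36-BP` = 6.49)),
    sd   = cbind(KOA = c(`BPI-PS` = 1.50, NRS = 1.67, `KOOS-P` = 1.49,
                         `SF36-BP` = 1.82),
                 HOA = c(`BPI-PS` = 1.52, NRS = 1.66, `KOOS-P` = 1.63,
                         `SF36-BP` = 1.55)))
}

#' Default post-surgical pain retention fractions
#'
#' Fraction of baseline pain remaining post-surgery per scale and group,
#' fitted as the ratio of the anchored 3-month means to the baseline means
#' (hip replacement relieves a larger share of pain than knee replacement).
#'
#' @return A scale x group matrix of retention fractions.
#' @export
default_retention <- function() {
  pb <- default_pain_baseline()$mean
  m3 <- cbind(KOA = c(`BPI-PS` = 1.69, NRS = 1.89, `KOOS-P` = 2.45,
                      `SF36-BP` = 3.39),
              HOA = c(`BPI-PS` = 0.54, NRS = 0.55, `KOOS-P` = 0.79,
                      `SF36-BP` = 1.95))
  m3 / pb
}

#' Specification of a synthetic surgical cohort
#'
#' Defines the generative model for cohorts emulating the study design: two
#' unbalanced arms (84 knee OA, 22 hip OA), 21 measures driven by 5
#' orthogonal latent factors, four pain outcome scales tied to the Pain
#' Quality factor with baseline means and SDs anchored to the observed
#' cohort, a surgery effect that multiplies pain by a per-scale retention
#' fraction and rewires the inter-measure correlation structure (more
#' strongly in the hip arm), 3-to-6-month stability, and completely random
#' item missingness.
#'
#' `rewire_strength` is defined operationally: 0 leaves the correlation
#' structure unchanged after surgery, 1 replaces it entirely.  The
#' post-surgery structure blends the baseline loadings toward a shared
#' global recovery dimension whose row norm moves toward
#' `rewire_target_norm`, so that surgery both reorganizes and strengthens
#' inter-measure correlations, collapsing the modular baseline topology.
#'
#' @param n_koa,n_hoa arm sizes (an arm may be 0 to generate one group only).
#' @param registry a [measure_registry()].
#' @param loadings 21 x 5 loading matrix in native orientation.
#' @param uniqueness unique variance per measure (scalar or vector).  The
#'   default 0.15 implies within-factor correlations near 0.79, in line with
#'   observed within-construct correlations of the instruments.
#' @param pain_baseline list of `mean` and `sd` matrices (scale x group) on
#'   the 0-10 scale.
#' @param retention matrix (scale x group) of post/pre pain mean ratios.
#' @param rewire_strength named vector, rewiring in \[0, 1\] per group.
#' @param rewire_target_norm loading row norm of the fully rewired structure.
#' @param factor_persistence correlation of factor scores between 3 and 6
#'   months (pain levels are stable from 3 months onward).
#' @param noise_persistence correlation of scale-specific pain noise between
#'   3 and 6 months.
#' @param pain_factor_loading standardized loading of each pain scale on the
#'   Pain Quality factor.
#' @param missing_rate completely-at-random missingness per record.
#' @param rng_seed integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_koa = 84L, n_hoa = 22L,
                           registry = default_registry(),
                           loadings = default_loading_matrix(registry),
                           uniqueness = 0.15,
                           pain_baseline = default_pain_baseline(),
                           retention = default_retention(),
                           rewire_strength = c(KOA = 0.2, HOA = 0.9),
                           rewire_target_norm = 0.95,
                           factor_persistence = 0.9,
                           noise_persistence = 0.8,
                           pain_factor_loading = 0.5,
                           missing_rate = 0.02,
                           rng_seed = 1L) {
  loadings <- as.matrix(loadings)
  if (!all(is.finite(loadings))) stop("loadings must be finite")
  p <- nrow(loadings)
  if (length(uniqueness) == 1) uniqueness <- rep(uniqueness, p)
  if (length(uniqueness) != p)
    stop("uniqueness must be scalar or one value per measure")
  if (any(uniqueness <= 0)) stop("uniqueness must be > 0")
  if (any(retention < 0)) stop("retention must be >= 0")
  if (any(rewire_strength < 0 | rewire_strength > 1))
    stop("rewire_strength must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate out of range")
  nm <- registry$measure_id[!registry$is_pain_outcome]
  if (!identical(sort(rownames(loadings)), sort(nm)))
    stop("loading matrix rows must match the registry's non-outcome measures")
  structure(list(n_koa = as.integer(n_koa), n_hoa = as.integer(n_hoa),
                 registry = registry, loadings = loadings,
                 uniqueness = uniqueness, pain_baseline = pain_baseline,
                 retention = as.matrix(retention),
                 rewire_strength = rewire_strength,
                 rewire_target_norm = rewire_target_norm,
                 factor_persistence = factor_persistence,
                 noise_persistence = noise_persistence,
                 pain_factor_loading = pain_factor_loading,
                 missing_rate = missing_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# post-surgery loading matrix: blend toward a shared global recovery dimension
rewire_loadings <- function(L0, strength, target_norm) {
  if (strength == 0) return(L0)
  rn0 <- sqrt(rowSums(L0^2))
  rn1 <- (1 - strength) * rn0 + strength * target_norm
  dominant <- apply(L0, 1, function(r) r[which.max(abs(r))])
  tgt <- outer(sign(dominant), rep(1 / sqrt(ncol(L0)), ncol(L0)))
  tgt <- tgt * (rn0 / sqrt(rowSums(tgt^2)))
  Lraw <- (1 - strength) * L0 + strength * tgt
  Lraw * (rn1 / sqrt(rowSums(Lraw^2)))
}

#' Sample a subject-by-measure matrix from a loading model
#'
#' Draws `n` subjects as `F L' + E diag(sqrt(u))` with standard-normal,
#' mutually independent factor scores `F` and unique noise `E`.  The implied
#' correlation of measures i and j is
#' `sum_k L_ik L_jk / sqrt((sum L_i^2 + u_i)(sum L_j^2 + u_j))`.
#'
#' @param loadings measures x factors loading matrix.
#' @param uniqueness unique variance per measure (scalar or vector), > 0.
#' @param n number of subjects (>= 2).
#' @param seed integer seed; same seed gives an identical matrix.
#' @return An `n` x measures numeric matrix (unstandardized: the variance of
#'   measure j is `sum(L_j^2) + u_j`).
#' @export
sample_measure_matrix <- function(loadings, uniqueness, n, seed = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings); k <- ncol(loadings)
  if (n < 2) stop("n must be >= 2")
  if (length(uniqueness) == 1) uniqueness <- rep(uniqueness, p)
  if (any(uniqueness <= 0)) stop("uniqueness must be > 0")
  with_seed(seed, {
    f <- matrix(stats::rnorm(n * k), n, k)
    e <- matrix(stats::rnorm(n * p), n, p)
    x <- f %*% t(loadings) + e %*% diag(sqrt(uniqueness), p)
    colnames(x) <- rownames(loadings)
    x
  })
}

# implied correlation matrix of a loading model
implied_correlation <- function(loadings, uniqueness) {
  v <- loadings %*% t(loadings) + diag(uniqueness, nrow(loadings))
  stats::cov2cor(v)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces a long-format [cohort_table()] (values in native instrument
#' units, completely-at-random missingness injected) together with the
#' generative ground truth used by recovery tests: per-visit factor scores,
#' per-visit loading matrices and implied correlation matrices, planted
#' community labels, and the planted pain-outcome coefficients.
#'
#' At baseline, measures are driven by independent standard-normal factor
#' scores through the spec's loading matrix.  At 3 months the factor scores
#' are remixed with freshly drawn scores and the loadings blend toward a
#' global recovery dimension, both governed by the group's
#' `rewire_strength`; at 6 months the structure is held fixed and factor
#' scores persist with correlation `factor_persistence`, reflecting the
#' stability of outcomes from 3 months onward.  Pain scales follow the Pain
#' Quality factor with baseline means and SDs from the spec and post-surgery
#' means equal to baseline times the per-scale retention fraction.  Values
#' are clipped to the registry's native ranges; the clipped fraction is
#' reported in the ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `cohort` (a [cohort_table()]) and `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  registry <- spec$registry
  nm <- rownames(spec$loadings)
  pain_ids <- rownames(spec$pain_baseline$mean)
  groups <- c(KOA = spec$n_koa, HOA = spec$n_hoa)
  groups <- groups[groups > 0]
  seeds <- derive_seeds(spec$rng_seed, length(groups))

  all_records <- NULL
  all_covs <- NULL
  truth <- list(communities = apply(spec$loadings, 1, function(r)
                  colnames(spec$loadings)[which.max(abs(r))]),
                loadings = list(), factor_scores = list(),
                implied_correlation = list(), pain_coefficients = list(),
                clipped_fraction = NULL)
  n_clipped <- 0; n_cells <- 0

  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]; n <- groups[[gi]]
    w <- unname(spec$rewire_strength[g])
    if (is.na(w)) stop("no rewire_strength for group ", g)
    L0 <- spec$loadings
    L3 <- rewire_loadings(L0, w, spec$rewire_target_norm)
    Lv <- list(baseline = L0, m3 = L3, m6 = L3)
    gen <- with_seed(seeds[gi], {
      k <- ncol(L0)
      F0 <- matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, colnames(L0)))
      Gn <- matrix(stats::rnorm(n * k), n, k)
      F3 <- if (w > 0) ((1 - w) * F0 + w * Gn) / sqrt((1 - w)^2 + w^2) else F0
      rho <- spec$factor_persistence
      F6 <- rho * F3 + sqrt(1 - rho^2) * matrix(stats::rnorm(n * k), n, k)
      colnames(F3) <- colnames(F6) <- colnames(L0)
      Fv <- list(baseline = F0, m3 = F3, m6 = F6)

      # measures per visit, native units
      meas <- lapply(names(Fv), function(v) {
        L <- Lv[[v]]
        z <- Fv[[v]] %*% t(L) +
          matrix(stats::rnorm(n * nrow(L)), n) %*% diag(sqrt(spec$uniqueness))
        z <- sweep(z, 2, sqrt(rowSums(L^2) + spec$uniqueness), "/")
        colnames(z) <- nm
        z
      })
      names(meas) <- names(Fv)

      # pain scales on 0-10, then native
      lam <- spec$pain_factor_loading
      rho_e <- spec$noise_persistence
      eps <- list(baseline = matrix(stats::rnorm(n * 4), n, 4),
                  m3 = matrix(stats::rnorm(n * 4), n, 4))
      eps$m6 <- rho_e * eps$m3 + sqrt(1 - rho_e^2) * matrix(stats::rnorm(n * 4), n, 4)
      pain <- lapply(names(Fv), function(v) {
        fq <- Fv[[v]][, "Pain Quality"]
        mret <- if (v == "baseline") rep(1, 4) else spec$retention[pain_ids, g]
        p <- sapply(seq_along(pain_ids), function(s) {
          mu <- spec$pain_baseline$mean[pain_ids[s], g] * mret[s]
          sdv <- spec$pain_baseline$sd[pain_ids[s], g]
          mu + sdv * (lam * fq + sqrt(1 - lam^2) * eps[[v]][, s])
        })
        colnames(p) <- pain_ids
        p
      })
      names(pain) <- names(Fv)

      covs <- if (g == "KOA") data.frame(
        age = stats::rnorm(n, 65.6, 6.4),
        gender = stats::rbinom(n, 1, 0.80),
        education = sample(0:2, n, TRUE, c(0.78, 0.16, 0.06)),
        bmi = stats::rnorm(n, 30.3, 4.6),
        pain_duration = round(stats::rlnorm(n, log(48), 0.6)),
        kl_grade = sample(2:4, n, TRUE, c(0.25, 0.5, 0.25))
      ) else data.frame(
        age = stats::rnorm(n, 60, 7.5),
        gender = stats::rbinom(n, 1, 0.32),
        education = sample(0:2, n, TRUE, c(0.68, 0.20, 0.12)),
        bmi = stats::rnorm(n, 28.2, 3.3),
        pain_duration = round(stats::rlnorm(n, log(48), 0.6)),
        kl_grade = sample(2:4, n, TRUE, c(0.25, 0.5, 0.25))
      )
      miss <- stats::runif(n * 25 * 3) < spec$missing_rate
      list(Fv = Fv, meas = meas, pain = pain, covs = covs, miss = miss)
    })

    subj <- sprintf("%s-%03d", g, seq_len(n))
    gen$covs <- cbind(subject_id = subj, gen$covs)

    # assemble native-unit long records for this group
    rec_g <- NULL
    mi <- 0
    for (v in c("baseline", "m3", "m6")) {
      # non-outcome measures: z-scores -> native mid-range +- range/6
      native <- gen$meas[[v]]
      for (j in seq_along(nm)) {
        entry <- registry_entry(registry, nm[j])
        mid <- (entry$native_min + entry$native_max) / 2
        scale <- (entry$native_max - entry$native_min) / 6
        x <- mid + native[, j] * scale
        n_clipped <- n_clipped + sum(x < entry$native_min | x > entry$native_max)
        native[, j] <- pmin(pmax(x, entry$native_min), entry$native_max)
      }
      # pain scales: harmonized 0-10 -> native
      pnat <- gen$pain[[v]]
      for (s in seq_along(pain_ids)) {
        entry <- registry_entry(registry, pain_ids[s])
        h <- pnat[, s]
        n_clipped <- n_clipped + sum(h < 0 | h > 10)
        pnat[, s] <- native_from_harmonized(pmin(pmax(h, 0), 10), entry)
      }
      vals <- cbind(native, pnat)
      n_cells <- n_cells + length(vals)
      rec_g <- rbind(rec_g, data.frame(
        subject_id = rep(subj, times = ncol(vals)),
        group = g, visit = v,
        measure_id = rep(colnames(vals), each = n),
        value = as.vector(vals), stringsAsFactors = FALSE))
    }
    rec_g$missing_flag <- gen$miss[seq_len(nrow(rec_g))]
    rec_g$value[rec_g$missing_flag] <- NA_real_

    all_records <- rbind(all_records, rec_g)
    all_covs <- rbind(all_covs, gen$covs)
    truth$loadings[[g]] <- Lv
    truth$factor_scores[[g]] <- gen$Fv
    truth$implied_correlation[[g]] <- lapply(Lv, implied_correlation,
                                             uniqueness = spec$uniqueness)
    truth$pain_coefficients[[g]] <- spec$pain_factor_loading *
      spec$pain_baseline$sd[pain_ids, g]
  }
  truth$clipped_fraction <- n_clipped / n_cells

  list(cohort = cohort_table(all_records, registry, all_covs), truth = truth)
}
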