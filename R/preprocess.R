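#' Impute or exclude missing items of one instrument score
#'
#' Applies the missing-data rule for one subject-visit's items of a single
#' score or sub-score: if the missing fraction is at or above `threshold`
#' (default 30%, boundary inclusive) the score is excluded; otherwise missing
#' items are replaced by the mean of the observed items of the same score.
#'
#' @param items numeric vector of item responses, `NA` for missing.
#' @param threshold missing fraction at or above which the score is excluded.
#' @return A list with elements `items` (imputed vector, or `NULL` if
#'   excluded), `excluded` (logical), `missing_fraction`, and `imputed_idx`
#'   (indices that were filled in).
#' @export
handle_missing <- function(items, threshold = 0.30) {
  if (!length(items)) stop("no items supplied")
  frac <- mean(is.na(items))
  if (frac >= threshold) {
    return(list(items = NULL, excluded = TRUE, missing_fraction = frac,
                imputed_idx = integer(0)))
  }
  idx <- which(is.na(items))
  if (length(idx)) items[idx] <- mean(items, na.rm = TRUE)
  list(items = items, excluded = FALSE, missing_fraction = frac,
       imputed_idx = idx)
}

#' Rescale a native measure value to the common 0-10 worse-is-higher scale
#'
#' Affine map from the measure's native range to \[0, 10\], reversing
#' higher-is-better measures so that 10 always means worst status.  The map
#' is a bijection; [native_from_harmonized()] inverts it.
#'
#' @param value numeric vector in native units.
#' @param entry one registry row (see [registry_entry()]).
#' @return Values on the 0-10 harmonized scale.
#' @export
rescale_measure <- function(value, entry) {
  lo <- entry$native_min; hi <- entry$native_max
  out_of_range <- !is.na(value) & (value < lo | value > hi)
  if (any(out_of_range))
    stop("value outside native range [", lo, ", ", hi, "] for measure ",
         entry$measure_id)
  h <- (value - lo) / (hi - lo) * 10
  if (entry$orientation == "higher_is_better") h <- 10 - h
  h
}

#' Invert [rescale_measure()]
#'
#' @param h numeric vector on the harmonized 0-10 scale.
#' @param entry one registry row.
#' @return Values in native units.
#' @export
native_from_harmonized <- function(h, entry) {
  if (entry$orientation == "higher_is_better") h <- 10 - h
  entry$native_min + h / 10 * (entry$native_max - entry$native_min)
}

#' Percent residual pain
#'
#' Post-surgical pain expressed as a percentage of pre-surgical pain:
#' `100 * post / pre`.  100% means no change, 0% complete relief, and values
#' above 100% indicate worsening.  The statistic is undefined (returned as
#' `NA`) when pre-surgical pain is zero; such subjects are excluded from
#' aggregates.
#'
#' @param pre pre-surgery pain on the 0-10 scale.
#' @param post post-surgery pain on the 0-10 scale.
#' @return Percent residual pain, `NA` where `pre == 0`.
#' @export
residual_pain <- function(pre, post) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE))
    stop("pain values must be non-negative")
  out <- 100 * post / pre
  out[!is.na(pre) & pre == 0] <- NA_real_
  out
}

#' Aggregate pain across the four outcome scales
#'
#' Arithmetic mean of the four pain intensity scales for one subject-visit,
#' on the 0-10 scale.  Undefined (`NA`) if any scale is unavailable after
#' preprocessing.
#'
#' @param values numeric vector of length 4, or a matrix with 4 columns
#'   (one row per subject-visit).
#' @return The mean, or row means for a matrix input; `NA` where any scale
#'   is missing.
#' @export
aggregate_pain <- function(values) {
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (ncol(values) != 4) stop("expected 4 pain scales")
    return(rowMeans(values))
  }
  if (length(values) != 4) stop("expected 4 pain scales")
  mean(values)
}

#' Harmonize one group-visit slice of a cohort to a complete 0-10 matrix
#'
#' Pivots the long cohort records of one group and visit into a
#' subjects-by-measures matrix on the harmonized 0-10 scale, applying the
#' missing-data rule at the level available in a subscale-scored table:
#' a subject-visit with `missing_threshold` or more of an instrument's
#' subscales missing yields an exclusion record for that instrument; all
#' missing cells are then filled with the group-visit mean of the affected
#' measure (the documented subscale-level fallback of the item-mean rule,
#' see [handle_missing()] for the item-level form).  Imputed cells are
#' flagged in the provenance matrix.
#'
#' @param cohort a [cohort_table()].
#' @param visit one of `"baseline"`, `"m3"`, `"m6"`.
#' @param group group label, e.g. `"KOA"`.
#' @param measures measure ids to include (default: the 21 non-outcome
#'   measures).
#' @param config an [analysis_config()].
#' @return An object of class `harmonized_matrix`: list with `matrix`
#'   (subjects x measures, no missing cells), `imputed` (logical matrix),
#'   and `exclusions` (data frame of subject, instrument, visit, reason).
#' @export
harmonize_visit <- function(cohort, visit, group,
                            measures = NULL,
                            config = analysis_config()) {
  registry <- cohort$registry
  if (is.null(measures)) measures <- network_measures(registry)
  rec <- cohort$records
  rec <- rec[rec$visit == visit & rec$group == group &
               rec$measure_id %in% measures, , drop = FALSE]
  if (!nrow(rec)) stop("no records for group ", group, " at visit ", visit)
  subjects <- unique(rec$subject_id)
  m <- matrix(NA_real_, length(subjects), length(measures),
              dimnames = list(subjects, measures))
  m[cbind(match(rec$subject_id, subjects), match(rec$measure_id, measures))] <-
    ifelse(rec$missing_flag, NA_real_, rec$value)

  # native -> harmonized 0-10, worse-is-higher
  for (j in seq_along(measures)) {
    entry <- registry_entry(registry, measures[j])
    m[, j] <- rescale_measure(m[, j], entry)
  }

  # instrument-level exclusion rule
  exclusions <- data.frame(subject_id = character(0), instrument = character(0),
                           visit = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  instr <- registry$instrument[match(measures, registry$measure_id)]
  for (ins in unique(instr)) {
    cols <- which(instr == ins)
    frac <- rowMeans(is.na(m[, cols, drop = FALSE]))
    hit <- which(frac >= config$missing_threshold)
    for (i in hit) {
      exclusions <- rbind(exclusions, data.frame(
        subject_id = subjects[i], instrument = ins, visit = visit,
        reason = sprintf("%.0f%% of subscales missing", 100 * frac[i]),
        stringsAsFactors = FALSE))
    }
  }

  imputed <- is.na(m)
  if (any(imputed)) {
    mu <- colMeans(m, na.rm = TRUE)
    for (j in which(colSums(imputed) > 0)) m[imputed[, j], j] <- mu[j]
  }
  structure(list(matrix = m, imputed = imputed, exclusions = exclusions,
                 group = group, visit = visit),
            class = "harmonized_matrix")
}

#' Per-subject pain trajectories and residual pain
#'
#' Extracts the four pain outcome scales at each visit on the 0-10 scale and
#' computes percent residual pain at 3 and 6 months, plus the aggregate pain
#' (mean of the four scales) per subject-visit.
#'
#' @param cohort a [cohort_table()].
#' @param config an [analysis_config()].
#' @return An object of class `pain_trajectory`: list with `scales` (data
#'   frame: subject, group, measure, pre, m3, m6, residual_m3, residual_m6)
#'   and `aggregate` (data frame: subject, group, visit, aggregate_pain).
#' @export
pain_trajectory <- function(cohort, config = analysis_config()) {
  registry <- cohort$registry
  scales <- outcome_measures(registry)
  per_visit <- lapply(c("baseline", "m3", "m6"), function(v) {
    out <- NULL
    for (g in unique(cohort$records$group)) {
      h <- harmonize_visit(cohort, v, g, measures = scales, config = config)
      df <- data.frame(subject_id = rownames(h$matrix), group = g,
                       stringsAsFactors = FALSE)
      out <- rbind(out, cbind(df, as.data.frame(h$matrix)))
    }
    out
  })
  names(per_visit) <- c("baseline", "m3", "m6")

  long <- NULL
  for (sc in scales) {
    base <- per_visit$baseline[, c("subject_id", "group", sc)]
    names(base)[3] <- "pre"
    m3 <- per_visit$m3[match(base$subject_id, per_visit$m3$subject_id), sc]
    m6 <- per_visit$m6[match(base$subject_id, per_visit$m6$subject_id), sc]
    long <- rbind(long, data.frame(
      base[, c("subject_id", "group")], measure_id = sc, pre = base$pre,
      m3 = m3, m6 = m6,
      residual_m3 = residual_pain(base$pre, m3),
      residual_m6 = residual_pain(base$pre, m6),
      stringsAsFactors = FALSE))
  }

  agg <- NULL
  for (v in names(per_visit)) {
    pv <- per_visit[[v]]
    agg <- rbind(agg, data.frame(
      subject_id = pv$subject_id, group = pv$group, visit = v,
      aggregate_pain = aggregate_pain(pv[, scales]),
      stringsAsFactors = FALSE))
  }
  structure(list(scales = long, aggregate = agg), class = "pain_trajectory")
}
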