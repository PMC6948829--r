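#' Cohort table
#'
#' The pipeline's universal input: long-format records of one value per
#' (subject, visit, measure), with group labels and optional per-subject
#' covariates.  Visits are fixed to `baseline`, `m3` (3 months post-surgery)
#' and `m6` (6 months).
#'
#' @param records a `data.frame` with columns `subject_id`, `group`, `visit`,
#'   `measure_id`, `value`, and optionally `missing_flag`.
#' @param registry the [measure_registry()] the records must resolve against.
#' @param covariates optional per-subject `data.frame` with column
#'   `subject_id` and any of `age`, `gender`, `education`, `bmi`,
#'   `pain_duration`, `kl_grade`.
#' @return An object of class `cohort_table`: a list with elements `records`,
#'   `covariates` and `registry`.
#' @export
cohort_table <- function(records, registry, covariates = NULL) {
  required <- c("subject_id", "group", "visit", "measure_id", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("cohort records are missing columns: ",
         paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  records$visit <- as.character(records$visit)
  records$measure_id <- as.character(records$measure_id)
  if (is.null(records$missing_flag)) records$missing_flag <- is.na(records$value)
  records$missing_flag <- records$missing_flag | is.na(records$value)

  bad_visit <- setdiff(unique(records$visit), c("baseline", "m3", "m6"))
  if (length(bad_visit))
    stop("unknown visit label(s): ", paste(bad_visit, collapse = ", "),
         " (allowed: baseline, m3, m6)")
  unknown <- setdiff(unique(records$measure_id), registry$measure_id)
  if (length(unknown))
    stop("measure_id(s) not in registry: ", paste(unknown, collapse = ", "))
  key <- paste(records$subject_id, records$visit, records$measure_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (subject, visit, measure) record: subject ",
         dup$subject_id, ", visit ", dup$visit, ", measure ", dup$measure_id)
  }
  grp_per_subj <- tapply(records$group, records$subject_id,
                         function(g) length(unique(g)))
  if (any(grp_per_subj > 1))
    stop("group label differs within subject(s): ",
         paste(names(grp_per_subj)[grp_per_subj > 1], collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (is.null(covariates$subject_id))
      stop("covariates need a subject_id column")
    covariates$subject_id <- as.character(covariates$subject_id)
  }
  structure(list(records = records, covariates = covariates,
                 registry = registry),
            class = "cohort_table")
}

#' Load a cohort from a long-format CSV file
#'
#' The canonical input is a UTF-8 CSV with header row and columns
#' `subject_id`, `group`, `visit`, `measure_id`, `value`.  Cells whose value
#' does not parse as a number (e.g. `"NA"`, empty, free text) become records
#' with `missing_flag` set rather than being dropped.  Unknown measure ids
#' and duplicated (subject, visit, measure) keys are hard errors.
#'
#' @param path path to the CSV file.
#' @param registry a [measure_registry()].
#' @param covariates optional path to a per-subject covariate CSV, or a
#'   `data.frame`.
#' @return A [cohort_table()].
#' @export
load_cohort <- function(path, registry, covariates = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("subject_id", "group", "visit", "measure_id", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  val <- suppressWarnings(as.numeric(raw$value))
  raw$missing_flag <- is.na(val)
  raw$value <- val
  if (is.character(covariates)) {
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  cohort_table(raw, registry, covariates)
}

#' @export
print.cohort_table <- function(x, ...) {
  rec <- x$records
  cat("cohort_table:", length(unique(rec$subject_id)), "subjects,",
      nrow(rec), "records\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table_g <- table(
    tapply(rec$group, rec$subject_id, `[`, 1))), table_g), collapse = ", "), "\n")
  cat("  visits:", paste(unique(rec$visit), collapse = ", "), "\n")
  cat("  measures:", length(unique(rec$measure_id)),
      " missing cells:", sum(rec$missing_flag), "\n")
  invisible(x)
}

# subjects of one group, in first-appearance order
cohort_subjects <- function(cohort, group = NULL) {
  rec <- cohort$records
  if (!is.null(group)) rec <- rec[rec$group == group, , drop = FALSE]
  unique(rec$subject_id)
}
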