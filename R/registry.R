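#' Measure registry
#'
#' A measure registry is the catalogue of every instrument subscale and
#' performance score handled by the pipeline: its native scoring range, its
#' orientation (whether higher native values mean worse status), the latent
#' community it is assigned to, and whether it is one of the four pain
#' intensity outcome scales.
#'
#' @param entries a `data.frame` with columns `measure_id`, `instrument`,
#'   `subscale`, `native_min`, `native_max`, `orientation`
#'   (`"higher_is_worse"` or `"higher_is_better"`), `community`, and
#'   `is_pain_outcome` (logical).
#' @return An object of class `measure_registry` (a validated `data.frame`).
#' @seealso [default_registry()]
#' @export
measure_registry <- function(entries) {
  required <- c("measure_id", "instrument", "subscale", "native_min",
                "native_max", "orientation", "community", "is_pain_outcome")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols))
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (anyDuplicated(entries$measure_id))
    stop("duplicate measure_id in registry: ",
         paste(unique(entries$measure_id[duplicated(entries$measure_id)]),
               collapse = ", "))
  if (any(entries$native_min >= entries$native_max))
    stop("native_min must be < native_max for every measure")
  bad_orient <- setdiff(entries$orientation,
                        c("higher_is_worse", "higher_is_better"))
  if (length(bad_orient))
    stop("unknown orientation value(s): ", paste(bad_orient, collapse = ", "))
  if (!is.logical(entries$is_pain_outcome))
    stop("is_pain_outcome must be logical")
  rownames(entries) <- NULL
  class(entries) <- c("measure_registry", "data.frame")
  entries
}

#' Default registry of 21 biopsychosocial measures and 4 pain outcomes
#'
#' The battery covers seven questionnaires (HADS, PCS, MPQ, DN4, KOOS/HOOS,
#' SF-36, BPI) and two physical-performance tests (timed up-and-go, six-minute
#' walk).  The 21 non-outcome measures carry default community labels for the
#' five latent dimensions of osteoarthritis pain: Affect, Pain
#' Catastrophizing, Pain Quality, Health, and Physical Performance.  The four
#' pain intensity outcome scales (NRS, BPI severity, KOOS/HOOS pain, SF-36
#' bodily pain) are flagged with `is_pain_outcome` and excluded from factor
#' reduction and network stages.
#'
#' Native ranges follow the standard published scorings; versions of an
#' instrument with a different range (e.g. the 7-item DN4 interview form) can
#' be accommodated by editing the returned data frame and passing it back
#' through [measure_registry()].
#'
#' @return A [measure_registry()] with 25 entries.
#' @export
default_registry <- function() {
  e <- function(id, instrument, subscale, lo, hi, orient, community,
                outcome = FALSE)
    data.frame(measure_id = id, instrument = instrument, subscale = subscale,
               native_min = lo, native_max = hi, orientation = orient,
               community = community, is_pain_outcome = outcome,
               stringsAsFactors = FALSE)
  worse <- "higher_is_worse"; better <- "higher_is_better"
  entries <- rbind(
    e("HADS-A",  "HADS", "anxiety",                    0,  21, worse,  "Affect"),
    e("HADS-D",  "HADS", "depression",                 0,  21, worse,  "Affect"),
    e("MPQ-A",   "MPQ",  "affective",                  0,  12, worse,  "Affect"),
    e("PCS-R",   "PCS",  "rumination",                 0,  16, worse,  "Pain Catastrophizing"),
    e("PCS-M",   "PCS",  "magnification",              0,  12, worse,  "Pain Catastrophizing"),
    e("PCS-H",   "PCS",  "helplessness",               0,  24, worse,  "Pain Catastrophizing"),
    e("MPQ-S",   "MPQ",  "sensory",                    0,  33, worse,  "Pain Quality"),
    e("DN4",     "DN4",  "total",                      0,  10, worse,  "Pain Quality"),
    e("KOOS-S",  "KOOS", "symptoms",                   0, 100, better, "Pain Quality"),
    e("KOOS-SR", "KOOS", "sport_recreation",           0, 100, better, "Pain Quality"),
    e("KOOS-QOL","KOOS", "quality_of_life",            0, 100, better, "Pain Quality"),
    e("KOOS-ADL","KOOS", "activities_of_daily_living", 0, 100, better, "Pain Quality"),
    e("SF36-PF", "SF36", "physical_functioning",       0, 100, better, "Health"),
    e("SF36-PH", "SF36", "role_physical",              0, 100, better, "Health"),
    e("SF36-EP", "SF36", "role_emotional",             0, 100, better, "Health"),
    e("SF36-EF", "SF36", "energy_fatigue",             0, 100, better, "Health"),
    e("SF36-E",  "SF36", "emotional_wellbeing",        0, 100, better, "Health"),
    e("SF36-SF", "SF36", "social_functioning",         0, 100, better, "Health"),
    e("SF36-GH", "SF36", "general_health",             0, 100, better, "Health"),
    e("TUG",     "TUG",  "time_seconds",               0,  60, worse,  "Physical Performance"),
    e("6MWT",    "6MWT", "distance_metres",            0, 800, better, "Physical Performance"),
    e("NRS",     "NRS",  "pain_intensity",             0,  10, worse,  "unassigned", TRUE),
    e("BPI-PS",  "BPI",  "pain_severity",              0,  10, worse,  "unassigned", TRUE),
    e("KOOS-P",  "KOOS", "pain",                       0, 100, better, "unassigned", TRUE),
    e("SF36-BP", "SF36", "bodily_pain",                0, 100, better, "unassigned", TRUE)
  )
  measure_registry(entries)
}

#' Look up one registry entry
#'
#' @param registry a [measure_registry()].
#' @param measure_id a single measure id.
#' @return A one-row data frame.
#' @keywords internal
registry_entry <- function(registry, measure_id) {
  i <- match(measure_id, registry$measure_id)
  if (is.na(i)) stop("measure_id not in registry: ", measure_id)
  registry[i, , drop = FALSE]
}

# ids of the measures entering factor reduction and networks (non-outcomes)
network_measures <- function(registry) {
  registry$measure_id[!registry$is_pain_outcome]
}

# ids of the four pain outcome scales
outcome_measures <- function(registry) {
  registry$measure_id[registry$is_pain_outcome]
}
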