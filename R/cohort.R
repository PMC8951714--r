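#' Apply the ICU eligibility cascade
#'
#' Screens a patient table against the standard eligibility criteria for a
#' serial-lactate analysis, applied sequentially so each patient is counted
#' at the first criterion it fails:
#' \enumerate{
#'   \item age < 18 years;
#'   \item not the first ICU admission;
#'   \item fewer than two lactate measurements within the observation
#'     window (this covers patients with zero measurements);
#'   \item ICU length of stay < 24 h.
#' }
#'
#' @param patients Patient data.frame (see [read_patients()]).
#' @param measurements Measurement data.frame (see [read_measurements()]).
#'   Measurements for patient ids absent from `patients` raise a warning
#'   and are ignored.
#' @param window An [observation_window()] used to count in-window
#'   measurements; default first 24 h.
#' @param min_los_hours Minimum ICU length of stay in hours (default 24).
#'
#' @return A list with elements `included` (character vector of included
#'   patient ids, in input order) and `report` (a `filter_report`
#'   data.frame of per-criterion exclusion counts with attributes
#'   `n_screened` and `n_included`).
#' @examples
#' pts <- data.frame(patient_id = c("a", "b"), age_years = c(17, 50),
#'                   first_icu_stay = c(TRUE, TRUE),
#'                   icu_los_hours = c(48, 48),
#'                   sepsis = c(FALSE, TRUE), death_28d = c(FALSE, FALSE))
#' mes <- data.frame(patient_id = rep(c("a", "b"), each = 2),
#'                   time_hours = c(1, 5, 2, 6),
#'                   lactate_mmol_l = c(2, 2, 3, 1))
#' apply_exclusions(pts, mes)$included   # "b"
#' @export
apply_exclusions <- function(patients, measurements,
                             window = observation_window(),
                             min_los_hours = 24) {
  window <- as_window(window)
  stopifnot(is.data.frame(patients))
  n_screened <- nrow(patients)

  unknown <- setdiff(unique(measurements$patient_id), patients$patient_id)
  if (length(unknown)) {
    warning(sprintf(
      "%d measurement patient id(s) not present in the patient table; their series are ignored",
      length(unknown)), call. = FALSE)
    measurements <-
      measurements[!(measurements$patient_id %in% unknown), , drop = FALSE]
  }

  counts <- measurement_counts(measurements, window)
  n_meas <- counts[match(patients$patient_id, names(counts))]
  n_meas[is.na(n_meas)] <- 0L

  criteria <- list(
    "age < 18 years"                 = patients$age_years < 18,
    "not first ICU admission"        = !patients$first_icu_stay,
    "< 2 lactate measurements in window" = n_meas < 2L,
    "ICU length of stay < 24 h"      = patients$icu_los_hours < min_los_hours
  )

  excluded <- rep(FALSE, n_screened)
  n_excluded <- integer(length(criteria))
  for (i in seq_along(criteria)) {
    fails <- criteria[[i]] & !excluded
    n_excluded[i] <- sum(fails)
    excluded <- excluded | fails
  }

  report <- data.frame(criterion = names(criteria),
                       n_excluded = n_excluded,
                       stringsAsFactors = FALSE)
  attr(report, "n_screened") <- n_screened
  attr(report, "n_included") <- n_screened - sum(n_excluded)
  class(report) <- c("filter_report", "data.frame")

  list(included = patients$patient_id[!excluded], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Eligibility cascade: %d screened, %d included\n",
              attr(x, "n_screened"), attr(x, "n_included")))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Split an included cohort by sepsis status
#'
#' Partitions patients into sepsis and non-sepsis cohorts according to the
#' supplied (Sepsis-3 adjudicated) flag, preserving input order within each
#' cohort.
#'
#' @param patients Patient data.frame with a logical `sepsis` column and no
#'   missing flags.
#' @return A list with data.frames `sepsis` and `non_sepsis`.
#' @export
split_by_sepsis <- function(patients) {
  stopifnot(is.data.frame(patients))
  if (!"sepsis" %in% names(patients) || anyNA(patients$sepsis))
    stop("every patient must carry a non-missing `sepsis` flag",
         call. = FALSE)
  list(sepsis = patients[patients$sepsis, , drop = FALSE],
       non_sepsis = patients[!patients$sepsis, , drop = FALSE])
}

#' Stratify a cohort by in-window measurement count
#'
#' Selects the patients whose number of in-window lactate measurements
#' satisfies a count rule — either exactly `k` or at least `k` — as used in
#' the measurement-count sensitivity analysis (strata with 2, >=3, >=4 or
#' >=5 measurements). Counts are of observed points before boundary
#' extension.
#'
#' @param patients Patient data.frame.
#' @param measurements Measurement data.frame.
#' @param k Count threshold (>= 2).
#' @param rule `"at_least"` (default) or `"exactly"`.
#' @param window An [observation_window()]; default first 24 h.
#' @return The subset of `patients` satisfying the rule, in input order.
#' @export
stratify_by_measurement_count <- function(patients, measurements, k,
                                          rule = c("at_least", "exactly"),
                                          window = observation_window()) {
  rule <- match.arg(rule)
  window <- as_window(window)
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("`k` must be a single count >= 2", call. = FALSE)
  counts <- measurement_counts(measurements, window)
  n_meas <- counts[match(patients$patient_id, names(counts))]
  n_meas[is.na(n_meas)] <- 0L
  keep <- if (rule == "at_least") n_meas >= k else n_meas == k
  patients[keep, , drop = FALSE]
}
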