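#' One patient's timed lactate measurements
#'
#' Constructs a normalized measurement series from raw (time, value) pairs.
#' Ingest normalization applies, in order:
#' \enumerate{
#'   \item measurements outside the observation window are dropped
#'     (pre-admission draws at negative times, and draws after the window
#'     end); the number dropped is kept in the `n_dropped` attribute;
#'   \item duplicate timestamps are collapsed by averaging their values,
#'     so the series defines a function of time;
#'   \item measurements are sorted by time.
#' }
#'
#' @param patient_id Opaque patient identifier (length 1).
#' @param times Numeric vector of measurement times, hours since ICU
#'   admission.
#' @param values Numeric vector of lactate concentrations in mmol/L
#'   (strictly positive), same length as `times`.
#' @param window An [observation_window()] (or `c(start, end)`) used for
#'   clipping. Default: first 24 h.
#'
#' @return An object of class `measurement_series`: a list with elements
#'   `patient_id`, `times`, `values`, and attribute `n_dropped` (count of
#'   out-of-window measurements removed at ingest).
#' @examples
#' s <- measurement_series("p1", times = c(6, 18), values = c(2, 4))
#' s$times
#' @seealso [extend_to_window()], [burden_metrics()]
#' @export
measurement_series <- function(patient_id, times, values,
                               window = observation_window()) {
  window <- as_window(window)
  if (length(patient_id) != 1L)
    stop("`patient_id` must have length 1", call. = FALSE)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (anyNA(times) || anyNA(values) || !all(is.finite(times)) ||
      !all(is.finite(values)))
    stop("`times` and `values` must be finite and non-missing",
         call. = FALSE)
  if (any(values <= 0))
    stop("lactate values must be strictly positive (mmol/L)", call. = FALSE)

  keep <- times >= window$start & times <= window$end
  n_dropped <- sum(!keep)
  times <- times[keep]
  values <- values[keep]
  if (length(times) == 0L)
    stop(sprintf("patient %s has no measurements within the [%g, %g] h window",
                 as.character(patient_id), window$start, window$end),
         call. = FALSE)

  if (anyDuplicated(times)) {
    values <- as.numeric(tapply(values, factor(times, levels = unique(sort(times))),
                                mean))
    times <- unique(sort(times))
  } else {
    ord <- order(times)
    times <- times[ord]
    values <- values[ord]
  }

  structure(list(patient_id = patient_id, times = times, values = values),
            class = "measurement_series", n_dropped = n_dropped)
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("<measurement_series: patient %s, %d measurement%s>\n",
              as.character(x$patient_id), length(x$times),
              if (length(x$times) == 1L) "" else "s"))
  print(data.frame(time_hours = x$times, lactate_mmol_l = x$values),
        row.names = FALSE)
  invisible(x)
}

#' @export
length.measurement_series <- function(x) length(x$times)

#' Carry boundary lactate values to the window edges
#'
#' Extends a measurement series so that the lactate curve is defined on the
#' whole observation window: the value at the window start is taken to equal
#' the first observed value, and the value at the window end to equal the
#' last observed value. If a measurement already sits exactly on a boundary,
#' no duplicate point is added. Interior points are unchanged.
#'
#' @param series A [measurement_series()] whose times all lie inside
#'   `window`.
#' @param window An [observation_window()]; default first 24 h.
#'
#' @return A `measurement_series` spanning `[window$start, window$end]`.
#' @examples
#' s <- measurement_series("p1", c(6, 18), c(2, 4))
#' extend_to_window(s)$times    # 0  6 18 24
#' @export
extend_to_window <- function(series, window = observation_window()) {
  window <- as_window(window)
  stopifnot(inherits(series, "measurement_series"))
  n <- length(series$times)
  if (n == 0L)
    stop("cannot extend an empty measurement series", call. = FALSE)
  if (series$times[1L] < window$start || series$times[n] > window$end)
    stop("series has measurements outside the observation window",
         call. = FALSE)
  times <- series$times
  values <- series$values
  if (times[1L] > window$start) {
    times <- c(window$start, times)
    values <- c(values[1L], values)
  }
  n <- length(times)
  if (times[n] < window$end) {
    times <- c(times, window$end)
    values <- c(values, values[n])
  }
  structure(list(patient_id = series$patient_id, times = times,
                 values = values),
            class = "measurement_series",
            n_dropped = attr(series, "n_dropped"))
}

#' Read a lactate measurement table
#'
#' Reads a CSV with the columns `patient_id, time_hours, lactate_mmol_l`
#' (header required, UTF-8, decimal point).
#'
#' @param path Path to the CSV file.
#' @return A data.frame with character `patient_id` and numeric
#'   `time_hours`, `lactate_mmol_l`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("patient_id", "time_hours", "lactate_mmol_l")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("measurement file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df$time_hours <- as.numeric(df$time_hours)
  df$lactate_mmol_l <- as.numeric(df$lactate_mmol_l)
  df[required]
}

#' Read a patient attribute table
#'
#' Reads a CSV with columns
#' `patient_id, age_years, first_icu_stay, icu_los_hours, sepsis, death_28d`
#' (booleans coded 0/1); any further columns are kept as optional
#' covariates for descriptive tables.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with one row per patient; `first_icu_stay`,
#'   `sepsis` and `death_28d` are logical.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("patient_id", "age_years", "first_icu_stay",
                "icu_los_hours", "sepsis", "death_28d")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("patient file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("patient table contains duplicated patient_id values",
         call. = FALSE)
  for (col in c("first_icu_stay", "sepsis", "death_28d"))
    df[[col]] <- as.logical(as.integer(df[[col]]))
  df$age_years <- as.numeric(df$age_years)
  df$icu_los_hours <- as.numeric(df$icu_los_hours)
  df[c(required, setdiff(names(df), required))]
}

# Split a measurement table into per-patient measurement_series objects.
# Patients whose in-window measurements are all clipped away are omitted.
series_index <- function(measurements, window = observation_window()) {
  window <- as_window(window)
  split_times <- split(measurements$time_hours, measurements$patient_id)
  split_vals <- split(measurements$lactate_mmol_l, measurements$patient_id)
  out <- list()
  for (pid in names(split_times)) {
    s <- tryCatch(
      measurement_series(pid, split_times[[pid]], split_vals[[pid]],
                         window = window),
      error = function(e) NULL)
    if (!is.null(s)) out[[pid]] <- s
  }
  out
}

# In-window measurement count per patient (post ingest-normalization:
# one point per distinct timestamp, pre boundary extension).
measurement_counts <- function(measurements, window = observation_window()) {
  window <- as_window(window)
  keep <- measurements$time_hours >= window$start &
    measurements$time_hours <= window$end
  m <- measurements[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(integer(0))
  key <- paste(m$patient_id, m$time_hours, sep = "\r")
  m <- m[!duplicated(key), , drop = FALSE]
  tab <- table(m$patient_id)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}
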