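#' Lactate load: area under the lactate-time curve
#'
#' The cumulative burden of hyperlactatemia over the observation window,
#' computed as the trapezoidal area under the piecewise-linear
#' lactate-versus-time curve after the first and last observed values have
#' been carried to the window edges (see [extend_to_window()]):
#' \deqn{\mathrm{load} = \sum_i \frac{Lac_{i+1} + Lac_i}{2}\,(T_{i+1} - T_i)}
#' in mmol·h/L. For a constant series the load equals the constant value
#' times the window length.
#'
#' @param series A [measurement_series()] with at least one in-window
#'   measurement.
#' @param window An [observation_window()]; default first 24 h.
#' @return Lactate load in mmol·h/L (single nonnegative number).
#' @examples
#' s <- measurement_series("p1", c(6, 18), c(2, 4))
#' lactate_load(s)              # 72 mmol·h/L
#' @export
lactate_load <- function(series, window = observation_window()) {
  window <- as_window(window)
  ext <- extend_to_window(series, window)
  t <- ext$times
  v <- ext$values
  if (!all(is.finite(v)))
    stop("non-finite lactate value in series", call. = FALSE)
  n <- length(t)
  if (n == 1L) {
    # degenerate zero-length window cannot occur (end > start enforced),
    # so a single point always gets extended; guard anyway
    return(0)
  }
  sum((v[-1L] + v[-n]) / 2 * diff(t))
}

#' Normalized lactate load: time-averaged lactate
#'
#' The [lactate_load()] divided by the window duration — the time-weighted
#' average lactate concentration over the window, in mmol/L. For a constant
#' series it equals that constant; in general it is bracketed by the
#' minimum and maximum observed values.
#'
#' @inheritParams lactate_load
#' @return Normalized lactate load in mmol/L.
#' @examples
#' s <- measurement_series("p1", c(6, 18), c(2, 4))
#' normalized_lactate_load(s)   # 3 mmol/L
#' @export
normalized_lactate_load <- function(series, window = observation_window()) {
  window <- as_window(window)
  lactate_load(series, window) / window_length(window)
}

#' Per-patient lactate burden metrics
#'
#' Summarizes one patient's in-window lactate measurements into the four
#' burden statistics reported for ICU cohorts: maximum lactate, mean
#' lactate (unweighted arithmetic mean of the raw measurements — distinct
#' from the time-weighted normalized load), lactate load and normalized
#' lactate load, together with the measurement count.
#'
#' @inheritParams lactate_load
#' @return An object of class `burden_metrics`: a list with elements
#'   `max_lactate`, `mean_lactate`, `lactate_load`,
#'   `normalized_lactate_load` (all mmol-based units) and
#'   `n_measurements` (observed points, before boundary extension).
#' @examples
#' burden_metrics(measurement_series("p1", c(6, 18), c(2, 4)))
#' @export
burden_metrics <- function(series, window = observation_window()) {
  window <- as_window(window)
  stopifnot(inherits(series, "measurement_series"))
  if (length(series$times) == 0L)
    stop("empty measurement series", call. = FALSE)
  load <- lactate_load(series, window)
  structure(list(
    max_lactate = max(series$values),
    mean_lactate = mean(series$values),
    lactate_load = load,
    normalized_lactate_load = load / window_length(window),
    n_measurements = length(series$times)
  ), class = "burden_metrics")
}

#' @export
print.burden_metrics <- function(x, ...) {
  cat("<burden_metrics>\n")
  cat(sprintf("  maximum lactate:         %.3f mmol/L\n", x$max_lactate))
  cat(sprintf("  mean lactate:            %.3f mmol/L\n", x$mean_lactate))
  cat(sprintf("  lactate load:            %.3f mmol.h/L\n", x$lactate_load))
  cat(sprintf("  normalized lactate load: %.3f mmol/L\n",
              x$normalized_lactate_load))
  cat(sprintf("  measurements:            %d\n", x$n_measurements))
  invisible(x)
}

#' Burden metrics for every patient in a measurement table
#'
#' Applies [burden_metrics()] to each patient in a long-format measurement
#' table. Patients with no in-window measurement are omitted from the
#' result (they fail the eligibility cascade anyway).
#'
#' @param measurements A data.frame with columns
#'   `patient_id, time_hours, lactate_mmol_l` (see [read_measurements()]).
#' @param window An [observation_window()]; default first 24 h.
#' @return A data.frame with one row per patient and columns `patient_id`,
#'   `n_measurements`, `max_lactate`, `mean_lactate`, `lactate_load`,
#'   `normalized_lactate_load`.
#' @export
compute_burden <- function(measurements, window = observation_window()) {
  window <- as_window(window)
  idx <- series_index(measurements, window)
  if (length(idx) == 0L)
    return(data.frame(patient_id = character(0), n_measurements = integer(0),
                      max_lactate = numeric(0), mean_lactate = numeric(0),
                      lactate_load = numeric(0),
                      normalized_lactate_load = numeric(0)))
  rows <- lapply(idx, function(s) {
    b <- burden_metrics(s, window)
    data.frame(patient_id = as.character(s$patient_id),
               n_measurements = b$n_measurements,
               max_lactate = b$max_lactate,
               mean_lactate = b$mean_lactate,
               lactate_load = b$lactate_load,
               normalized_lactate_load = b$normalized_lactate_load,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
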