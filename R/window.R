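#' Observation window for serial measurements
#'
#' Defines the time interval, in hours since ICU admission, over which
#' lactate measurements are integrated. The conventional analysis window is
#' the first 24 h of the ICU stay.
#'
#' @param start Window start in hours since ICU admission (default 0).
#' @param end Window end in hours (default 24). Must satisfy `end > start`.
#'
#' @return An object of class `observation_window`: a named list with
#'   elements `start` and `end`.
#' @examples
#' observation_window()          # the default first-24-h window
#' observation_window(0, 12)
#' @export
observation_window <- function(start = 0, end = 24) {
  if (!is.numeric(start) || length(start) != 1L || !is.finite(start))
    stop("`start` must be a single finite number", call. = FALSE)
  if (!is.numeric(end) || length(end) != 1L || !is.finite(end))
    stop("`end` must be a single finite number", call. = FALSE)
  if (end <= start)
    stop("observation window must satisfy end > start", call. = FALSE)
  structure(list(start = as.numeric(start), end = as.numeric(end)),
            class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window: [%g, %g] h>\n", x$start, x$end))
  invisible(x)
}

# Coerce a window argument: accepts an observation_window or a length-2
# numeric c(start, end).
as_window <- function(window) {
  if (inherits(window, "observation_window")) return(window)
  if (is.numeric(window) && length(window) == 2L)
    return(observation_window(window[1L], window[2L]))
  stop("`window` must be an observation_window or a numeric c(start, end)",
       call. = FALSE)
}

window_length <- function(window) window$end - window$start
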