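#' Analysis configuration for hypotension evaluation
#'
#' Bundles the thresholds and window lengths that define the evaluation:
#' the hypotension threshold on mean arterial pressure (MAP), the minimum
#' sustained duration for an episode to count as an event, the geometry of
#' normotensive non-event sections, the prediction horizons, and the alarm
#' threshold of the 0-100 index.
#'
#' @param map_threshold Hypotension threshold on MAP, mmHg. Samples strictly
#'   below this value are hypotensive; samples strictly above it qualify for
#'   non-event sections; samples exactly at it belong to neither.
#' @param min_event_duration Minimum sustained sub-threshold duration for a
#'   hypotensive event, seconds. With 20-s samples the default 60 s means at
#'   least 3 consecutive sub-threshold samples.
#' @param section_length Length of a normotensive non-event section, minutes.
#' @param section_gap Minimum separation between a non-event section and any
#'   hypotensive event boundary, minutes.
#' @param horizons Prediction horizons (look-back times before event onset),
#'   minutes.
#' @param hr_threshold Bradycardia threshold on heart rate, beats/min
#'   (strictly below).
#' @param alarm_threshold Index value at or above which the monitor alarms.
#' @param sample_interval Nominal sample spacing, seconds.
#' @param grid_tolerance Tolerated deviation from the nominal spacing before
#'   an interval counts as a gap, seconds. Gaps break consecutive-sample runs.
#' @param lookback_tolerance Maximum distance between a requested look-back
#'   time and the nearest available sample, seconds.
#' @param delta_map_window Window of the delta-MAP comparator, minutes: the
#'   score at time t is MAP(t - window) - MAP(t), positive when pressure fell.
#'
#' @return An object of class `cohort_config` (a named list).
#' @examples
#' cfg <- cohort_config()
#' cfg$map_threshold
#' @export
cohort_config <- function(map_threshold = 65,
                          min_event_duration = 60,
                          section_length = 30,
                          section_gap = 20,
                          horizons = c(5, 10, 15),
                          hr_threshold = 60,
                          alarm_threshold = 85,
                          sample_interval = 20,
                          grid_tolerance = 2,
                          lookback_tolerance = 10,
                          delta_map_window = 15) {
  cfg <- list(
    map_threshold = map_threshold,
    min_event_duration = min_event_duration,
    section_length = section_length,
    section_gap = section_gap,
    horizons = horizons,
    hr_threshold = hr_threshold,
    alarm_threshold = alarm_threshold,
    sample_interval = sample_interval,
    grid_tolerance = grid_tolerance,
    lookback_tolerance = lookback_tolerance,
    delta_map_window = delta_map_window
  )
  scalars <- setdiff(names(cfg), c("horizons", "grid_tolerance"))
  for (nm in scalars) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("cohort_config: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$grid_tolerance) || cfg$grid_tolerance < 0) {
    stop("cohort_config: 'grid_tolerance' must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(cfg$horizons) || any(cfg$horizons <= 0)) {
    stop("cohort_config: 'horizons' must be distinct positive values",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Hypotension evaluation configuration\n")
  cat(sprintf("  MAP threshold:        %g mmHg (event if < threshold for >= %g s)\n",
              x$map_threshold, x$min_event_duration))
  cat(sprintf("  non-event sections:   %g min, >= %g min from any event\n",
              x$section_length, x$section_gap))
  cat(sprintf("  horizons:             %s min\n",
              paste(x$horizons, collapse = ", ")))
  cat(sprintf("  bradycardia: HR < %g; alarm: index >= %g\n",
              x$hr_threshold, x$alarm_threshold))
  invisible(x)
}
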