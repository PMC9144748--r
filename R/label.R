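#' Step events
#'
#' An ascending list of step-event times with their count, either detected
#' from plantar pressure or taken from the synthetic generator's ground
#' truth.
#'
#' @param times_ms Numeric vector of epoch-ms event times (sorted
#'   ascending; unsorted input is sorted).
#' @param source `"pressure_detected"` or `"synthetic_truth"`.
#'
#' @return A list of class `step_events` with fields `times_ms`, `count`,
#'   `source`.
#' @export
step_events <- function(times_ms, source = c("pressure_detected", "synthetic_truth")) {
  source <- match.arg(source)
  times_ms <- sort(as.numeric(times_ms))
  structure(list(times_ms = times_ms, count = length(times_ms), source = source),
            class = "step_events")
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events:%s> %d events\n", x$source, x$count))
  invisible(x)
}

#' Peak-detector configuration
#'
#' Parameters of the threshold-based pressure peak detector: a force
#' threshold and a refractory period. The defaults follow from the sensor
#' and from gait physiology: most sensor noise stays below half of the
#' 60 N sensor range, so the threshold is 30 N; walking cadence of
#' 0.5--3 Hz spaces true peaks at least ~0.33 s apart, so crossings closer
#' than 0.2 s to the previous accepted event are treated as noise.
#'
#' @param threshold_n Force threshold, N, in (0, 60\].
#' @param min_interval_s Refractory period, s (> 0).
#'
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(threshold_n = 30, min_interval_s = 0.2) {
  if (threshold_n <= 0 || threshold_n > 60)
    stop("peak_config: threshold_n must lie in (0, 60]", call. = FALSE)
  if (min_interval_s <= 0)
    stop("peak_config: min_interval_s must be positive", call. = FALSE)
  structure(list(threshold_n = threshold_n, min_interval_s = min_interval_s),
            class = "peak_config")
}

#' Detect step events in a plantar pressure trace
#'
#' Threshold-based peak detection: a step event is emitted at each upward
#' crossing of the threshold (previous sample below, current sample at or
#' above) provided it occurs at least `min_interval_s` after the previous
#' accepted event; closer crossings are discarded as noise. The trace
#' should already be clipped ([clip_pressure()]) and smoothed
#' ([moving_average()]). Event times are the timestamps of the crossing
#' samples (no sub-sample interpolation; at 30 Hz the ~33 ms resolution is
#' far below the refractory period).
#'
#' @param pressure A `"pressure"` [scalar_trace()].
#' @param config A [peak_config()].
#'
#' @return [step_events()] with `source = "pressure_detected"`.
#' @export
detect_steps <- function(pressure, config = peak_config()) {
  if (!inherits(pressure, "scalar_trace") || trace_kind(pressure) != "pressure")
    stop("detect_steps: input must be a pressure scalar_trace", call. = FALSE)
  if (!inherits(config, "peak_config"))
    stop("detect_steps: config must be a peak_config", call. = FALSE)
  t <- pressure$time_ms
  v <- pressure$value
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("detect_steps: timestamps must be strictly increasing", call. = FALSE)
  n <- length(v)
  if (n < 2L) return(step_events(numeric(0)))
  cross <- which(v[-1L] >= config$threshold_n & v[-n] < config$threshold_n) + 1L
  ref_ms <- config$min_interval_s * 1000
  times <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (t[i] - last >= ref_ms) {
      times <- c(times, t[i])
      last <- t[i]
    }
  }
  step_events(times, source = "pressure_detected")
}

#' Count events in a half-open time window
#'
#' Number of event times `t` with `start_ms <= t < end_ms`. The half-open
#' convention guarantees that an event on a boundary shared by two
#' adjacent windows is counted exactly once when the windows tile the
#' recording.
#'
#' @param events A [step_events()].
#' @param start_ms,end_ms Window bounds, epoch ms, `start_ms < end_ms`.
#'
#' @return Integer count.
#' @export
count_events_in <- function(events, start_ms, end_ms) {
  if (!inherits(events, "step_events"))
    stop("count_events_in: events must be step_events", call. = FALSE)
  if (!is.numeric(start_ms) || !is.numeric(end_ms) || start_ms >= end_ms)
    stop("count_events_in: need start_ms < end_ms", call. = FALSE)
  sum(events$times_ms >= start_ms & events$times_ms < end_ms)
}
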