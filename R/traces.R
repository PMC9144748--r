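#' Carrying positions recognised by the pipeline
#'
#' The three smartphone carrying positions modelled throughout the package:
#' held in the hand, in a trouser pocket, or in a handbag.
#'
#' @return Character vector of the three position labels.
#' @export
carrying_positions <- function() c("handheld", "pocket", "handbag")

#' Tri-axial acceleration trace
#'
#' A timestamped recording of smartphone acceleration. Components are in
#' m/s^2 and include gravity; timestamps are epoch milliseconds (13-digit
#' integers stored as doubles). The nominal sampling rate is 30 Hz.
#'
#' @param time_ms Numeric vector of strictly increasing epoch-ms timestamps.
#' @param x,y,z Numeric acceleration components, m/s^2.
#' @param position Optional carrying-position label (see
#'   [carrying_positions()]).
#'
#' @return A data frame of class `accel_trace` with columns `time_ms`, `x`,
#'   `y`, `z` and a `position` attribute.
#' @export
#' @examples
#' accel_trace(c(0, 33, 67), x = c(0, 0, 0), y = c(0, 0, 0), z = rep(9.81, 3))
accel_trace <- function(time_ms, x, y, z, position = NULL) {
  n <- length(time_ms)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("accel_trace: time_ms, x, y and z must have equal lengths", call. = FALSE)
  time_ms <- as.numeric(time_ms)
  if (n > 1L && any(diff(time_ms) <= 0))
    stop("accel_trace: timestamps must be strictly increasing", call. = FALSE)
  if (!is.null(position))
    position <- match.arg(position, carrying_positions())
  structure(
    data.frame(time_ms = time_ms, x = as.numeric(x), y = as.numeric(y),
               z = as.numeric(z)),
    class = c("accel_trace", "data.frame"),
    position = position
  )
}

#' Scalar signal trace (magnitude or plantar force)
#'
#' A timestamped univariate signal: either the magnitude of a tri-axial
#' acceleration trace (m/s^2) or a single-foot plantar force (N). Force
#' traces are expected to lie in \[0, 60\] N after [clip_pressure()].
#'
#' @param time_ms Numeric vector of strictly increasing epoch-ms timestamps.
#' @param value Numeric signal values.
#' @param kind `"magnitude"` or `"pressure"`.
#'
#' @return A data frame of class `scalar_trace` with columns `time_ms`,
#'   `value` and a `kind` attribute.
#' @export
scalar_trace <- function(time_ms, value, kind = c("magnitude", "pressure")) {
  kind <- match.arg(kind)
  n <- length(time_ms)
  if (length(value) != n)
    stop("scalar_trace: time_ms and value must have equal lengths", call. = FALSE)
  time_ms <- as.numeric(time_ms)
  if (n > 1L && any(diff(time_ms) <= 0))
    stop("scalar_trace: timestamps must be strictly increasing", call. = FALSE)
  structure(
    data.frame(time_ms = time_ms, value = as.numeric(value)),
    class = c("scalar_trace", "data.frame"),
    kind = kind
  )
}

trace_kind <- function(trace) attr(trace, "kind", exact = TRUE)

#' @export
print.accel_trace <- function(x, ...) {
  pos <- attr(x, "position", exact = TRUE)
  cat(sprintf("<accel_trace> %d samples%s\n", nrow(x),
              if (is.null(pos)) "" else paste0(", position: ", pos)))
  if (nrow(x) > 0)
    cat(sprintf("  span: %.1f s at ~%.1f Hz\n",
                (x$time_ms[nrow(x)] - x$time_ms[1]) / 1000,
                nominal_rate_hz(x$time_ms)))
  invisible(x)
}

#' @export
print.scalar_trace <- function(x, ...) {
  cat(sprintf("<scalar_trace:%s> %d samples\n", trace_kind(x), nrow(x)))
  invisible(x)
}

# Nominal sampling rate (Hz) inferred from the median inter-sample interval.
nominal_rate_hz <- function(time_ms) {
  if (length(time_ms) < 2L) return(NA_real_)
  round(1000 / stats::median(diff(time_ms)))
}
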