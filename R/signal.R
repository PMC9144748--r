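#' Signal vector magnitude of a tri-axial acceleration trace
#'
#' Collapses the three acceleration components into their Euclidean norm,
#' `sqrt(x^2 + y^2 + z^2)`. Because the norm is invariant under rotation of
#' the sensor frame, the result does not depend on how the phone is oriented
#' at its carrying position; gravity is deliberately retained in the signal.
#'
#' @param accel An [accel_trace()].
#'
#' @return A `"magnitude"` [scalar_trace()] with the same timestamps.
#' @export
#' @examples
#' a <- accel_trace(c(0, 33), x = c(3, 0), y = c(4, 0), z = c(0, 9.81))
#' magnitude(a)$value  # 5, 9.81
magnitude <- function(accel) {
  if (!inherits(accel, "accel_trace"))
    stop("magnitude: input must be an accel_trace", call. = FALSE)
  if (nrow(accel) == 0L)
    stop("magnitude: empty acceleration trace", call. = FALSE)
  scalar_trace(accel$time_ms, sqrt(accel$x^2 + accel$y^2 + accel$z^2),
               kind = "magnitude")
}

#' Equal-weight moving-average filter
#'
#' Smooths a signal with an equal-weight window of `2 * half_width + 1`
#' samples centred on each sample (the default `half_width = 2` averages a
#' sample with its four closest neighbours, weight 1/5 each). Near the
#' edges the window shrinks symmetrically to the available neighbours, so
#' the output has the same length as the input and constant signals pass
#' through unchanged.
#'
#' @param trace A [scalar_trace()] or a plain numeric vector.
#' @param half_width Non-negative integer; samples on each side of the
#'   centre. `0` is the identity.
#'
#' @return An object of the same type as `trace`, smoothed.
#' @export
#' @examples
#' moving_average(c(0, 0, 0, 0, 1, 0, 0, 0, 0))  # 5-tap impulse response
moving_average <- function(trace, half_width = 2L) {
  half_width <- as.integer(half_width)
  if (length(half_width) != 1L || is.na(half_width) || half_width < 0L)
    stop("moving_average: half_width must be a non-negative integer", call. = FALSE)
  if (inherits(trace, "scalar_trace")) {
    out <- trace
    out$value <- ma_shrink(trace$value, half_width)
    return(out)
  }
  if (!is.numeric(trace))
    stop("moving_average: input must be a scalar_trace or numeric vector", call. = FALSE)
  ma_shrink(trace, half_width)
}

ma_shrink <- function(v, hw) {
  n <- length(v)
  if (n == 0L || hw == 0L) return(v)
  if (n >= 2L * hw + 1L) {
    out <- as.numeric(stats::filter(v, rep(1 / (2 * hw + 1), 2 * hw + 1),
                                    sides = 2))
  } else {
    out <- rep(NA_real_, n)
  }
  for (i in which(is.na(out))) {
    k <- min(hw, i - 1L, n - i)
    out[i] <- mean(v[(i - k):(i + k)])
  }
  out
}

#' Clip plantar force to the sensor's sensitive range
#'
#' The force-sensitive resistor used for plantar pressure saturates outside
#' roughly 0.5--60 N: readings below `low_n` carry no information and are
#' set to 0, readings above `high_n` are set to `high_n`. Negative raw
#' values are treated as below-range. Clipping models the physical sensor
#' and is applied before any software smoothing.
#'
#' @param raw A `"pressure"` [scalar_trace()].
#' @param low_n,high_n Sensitive range bounds in newtons.
#'
#' @return The clipped trace; idempotent.
#' @export
clip_pressure <- function(raw, low_n = 0.5, high_n = 60) {
  if (!inherits(raw, "scalar_trace") || trace_kind(raw) != "pressure")
    stop("clip_pressure: input must be a pressure scalar_trace", call. = FALSE)
  v <- raw$value
  v[v < low_n] <- 0
  v[v > high_n] <- high_n
  out <- raw
  out$value <- v
  out
}
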