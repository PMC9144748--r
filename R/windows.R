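#' Align acceleration and pressure streams by timestamp
#'
#' Trims both streams to their overlapping time span and pairs each
#' acceleration sample with the nearest-in-time pressure sample. Pairs
#' whose timestamp skew exceeds `max_skew_ms` are dropped (with a
#' warning). Both returned traces have equal length and pairwise-matched
#' rows.
#'
#' @param accel An [accel_trace()].
#' @param pressure A [scalar_trace()].
#' @param max_skew_ms Maximum tolerated timestamp skew per pair, ms.
#'
#' @return List with elements `accel` and `pressure`, trimmed and paired.
#' @export
align_streams <- function(accel, pressure, max_skew_ms = 50) {
  if (!inherits(accel, "accel_trace") || nrow(accel) == 0L)
    stop("align_streams: accel must be a non-empty accel_trace", call. = FALSE)
  if (!inherits(pressure, "scalar_trace") || nrow(pressure) == 0L)
    stop("align_streams: pressure must be a non-empty scalar_trace", call. = FALSE)
  at <- accel$time_ms
  pt <- pressure$time_ms
  lo <- max(at[1], pt[1])
  hi <- min(at[length(at)], pt[length(pt)])
  if (lo > hi)
    stop("align_streams: traces have no overlapping time span", call. = FALSE)
  keep_a <- which(at >= lo & at <= hi)
  at <- at[keep_a]
  # nearest pressure sample for each retained acceleration sample
  j <- findInterval(at, pt)
  j_lo <- pmax(j, 1L)
  j_hi <- pmin(j + 1L, length(pt))
  j_near <- ifelse(abs(at - pt[j_lo]) <= abs(pt[j_hi] - at), j_lo, j_hi)
  skew <- abs(at - pt[j_near])
  ok <- skew <= max_skew_ms
  if (any(!ok))
    warning(sprintf("align_streams: dropped %d pair(s) with skew > %g ms",
                    sum(!ok), max_skew_ms))
  ka <- keep_a[ok]
  kp <- j_near[ok]
  # pairing must be injective: if two acceleration samples claim the same
  # pressure sample, keep the first pair only
  dup <- duplicated(kp)
  ka <- ka[!dup]
  kp <- kp[!dup]
  acc_out <- accel_trace(accel$time_ms[ka], accel$x[ka], accel$y[ka],
                         accel$z[ka],
                         position = attr(accel, "position", exact = TRUE))
  pr_out <- scalar_trace(pressure$time_ms[kp], pressure$value[kp],
                         kind = trace_kind(pressure))
  list(accel = acc_out, pressure = pr_out)
}

#' Sliding-window supervised dataset
#'
#' Cuts a filtered magnitude trace into fixed-length windows advanced by a
#' constant stride (50% overlap by default: 2 s windows of 60 samples at
#' 30 Hz, advanced by 30 samples) and labels each window with the number
#' of step events falling in its half-open time span. Trailing samples
#' that do not fill a window are dropped, never padded.
#'
#' @param magnitude A `"magnitude"` [scalar_trace()] (already smoothed).
#' @param events Optional [step_events()]; if `NULL` the labels are `NA`
#'   (unlabeled windows for inference).
#' @param position Carrying-position label for all windows, or `NA`.
#' @param window_s Window length, seconds.
#' @param overlap_frac Fractional overlap between consecutive windows, in
#'   \[0, 1).
#' @param sample_rate_hz Sampling rate; inferred from the timestamps when
#'   `NULL`.
#' @param recording Identifier of the source recording (used by
#'   chronological splitting).
#'
#' @return A list of class `window_dataset` with fields `features`
#'   (n_windows x window_len matrix), `labels`, `positions`,
#'   `window_starts` (epoch ms), `recording` and `meta`.
#' @export
make_windows <- function(magnitude, events = NULL, position = NA_character_,
                         window_s = 2.0, overlap_frac = 0.5,
                         sample_rate_hz = NULL, recording = "rec1") {
  if (!inherits(magnitude, "scalar_trace"))
    stop("make_windows: magnitude must be a scalar_trace", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("make_windows: overlap_frac must lie in [0, 1)", call. = FALSE)
  t <- magnitude$time_ms
  v <- magnitude$value
  if (is.null(sample_rate_hz)) sample_rate_hz <- nominal_rate_hz(t)
  window_len <- round(window_s * sample_rate_hz)
  stride <- max(1L, round(window_len * (1 - overlap_frac)))
  n <- length(v)
  if (n < window_len)
    stop(sprintf("make_windows: trace has %d samples, need at least %d for one window",
                 n, window_len), call. = FALSE)
  starts <- seq.int(1L, n - window_len + 1L, by = stride)
  feats <- t(vapply(starts, function(i) v[i:(i + window_len - 1L)],
                    numeric(window_len)))
  window_ms <- window_s * 1000
  labels <- if (is.null(events)) {
    rep(NA_integer_, length(starts))
  } else {
    vapply(starts, function(i) count_events_in(events, t[i], t[i] + window_ms),
           integer(1))
  }
  structure(
    list(features = feats,
         labels = labels,
         positions = rep(as.character(position), length(starts)),
         window_starts = t[starts],
         recording = rep(as.character(recording), length(starts)),
         meta = list(window_s = window_s, overlap_frac = overlap_frac,
                     sample_rate_hz = sample_rate_hz,
                     window_len = window_len, stride = stride)),
    class = "window_dataset"
  )
}

#' Number of windows in a dataset
#' @param dataset A `window_dataset`.
#' @return Integer count of windows.
#' @export
n_windows <- function(dataset) nrow(dataset$features)

#' Subset a window dataset
#' @param x A `window_dataset`.
#' @param i Row (window) indices.
#' @param ... Ignored.
#' @return A `window_dataset` containing the selected windows.
#' @export
`[.window_dataset` <- function(x, i, ...) {
  structure(
    list(features = x$features[i, , drop = FALSE],
         labels = x$labels[i],
         positions = x$positions[i],
         window_starts = x$window_starts[i],
         recording = x$recording[i],
         meta = x$meta),
    class = "window_dataset"
  )
}

#' Concatenate window datasets
#'
#' Row-binds datasets built with identical window geometry (length,
#' stride, rate), e.g. one per recording of a cohort.
#'
#' @param ... `window_dataset` objects.
#' @return A single `window_dataset`.
#' @export
bind_windows <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1]], "window_dataset")) ds <- ds[[1]]
  stopifnot(length(ds) >= 1L, all(vapply(ds, inherits, logical(1), "window_dataset")))
  m1 <- ds[[1]]$meta
  for (d in ds[-1])
    if (!identical(d$meta[c("window_len", "stride", "sample_rate_hz")],
                   m1[c("window_len", "stride", "sample_rate_hz")]))
      stop("bind_windows: datasets have incompatible window geometry", call. = FALSE)
  structure(
    list(features = do.call(rbind, lapply(ds, `[[`, "features")),
         labels = unlist(lapply(ds, `[[`, "labels")),
         positions = unlist(lapply(ds, `[[`, "positions")),
         window_starts = unlist(lapply(ds, `[[`, "window_starts")),
         recording = unlist(lapply(ds, `[[`, "recording")),
         meta = m1),
    class = "window_dataset"
  )
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows x %d samples (%g s, %d%% overlap), %d recording(s)\n",
              n_windows(x), x$meta$window_len, x$meta$window_s,
              round(100 * x$meta$overlap_frac),
              length(unique(x$recording))))
  if (!all(is.na(x$labels)))
    cat(sprintf("  labels: %d..%d steps/window; positions: %s\n",
                min(x$labels, na.rm = TRUE), max(x$labels, na.rm = TRUE),
                paste(unique(x$positions), collapse = ", ")))
  invisible(x)
}
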