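# CSV interchange formats. Timestamps are epoch milliseconds; numeric
# values are written with 17 significant digits so write -> read is a
# lossless round trip for doubles.

fmt_num <- function(x) sprintf("%.17g", x)

write_csv_raw <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_csv_numeric <- function(path, required, label) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s): %s", label,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("%s: file contains no data rows", label), call. = FALSE)
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                     label, col, bad[1]), call. = FALSE)
      df[[col]] <- conv
    }
  }
  df
}

sort_by_time <- function(df, label) {
  if (is.unsorted(df$time_ms, strictly = FALSE)) {
    warning(sprintf("%s: rows were out of time order and have been sorted", label))
    df <- df[order(df$time_ms), , drop = FALSE]
  }
  df
}

#' Read/write acceleration CSV
#'
#' Format: header `time_ms,x,y,z` with an optional `position` column
#' (constant per file). Rows are sorted by `time_ms` on read, with a
#' warning if reordering was needed.
#'
#' @param path File path.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path) {
  df <- read_csv_numeric(path, c("time_ms", "x", "y", "z"), "read_accel_csv")
  df <- sort_by_time(df, "read_accel_csv")
  pos <- if ("position" %in% names(df)) as.character(df$position[1]) else NULL
  accel_trace(df$time_ms, df$x, df$y, df$z, position = pos)
}

#' @rdname read_accel_csv
#' @param trace An [accel_trace()] to serialize.
#' @export
write_accel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- as.data.frame(trace)
  pos <- attr(trace, "position", exact = TRUE)
  if (!is.null(pos)) df$position <- pos
  write_csv_raw(df, path)
}

#' Read/write plantar pressure CSV
#'
#' Format: header `time_ms,force_n`. An empty file (no data rows) is an
#' error.
#'
#' @param path File path.
#' @return A `"pressure"` [scalar_trace()].
#' @export
read_pressure_csv <- function(path) {
  df <- read_csv_numeric(path, c("time_ms", "force_n"), "read_pressure_csv")
  df <- sort_by_time(df, "read_pressure_csv")
  scalar_trace(df$time_ms, df$force_n, kind = "pressure")
}

#' @rdname read_pressure_csv
#' @param trace A pressure [scalar_trace()] to serialize.
#' @export
write_pressure_csv <- function(trace, path) {
  stopifnot(inherits(trace, "scalar_trace"), trace_kind(trace) == "pressure")
  write_csv_raw(data.frame(time_ms = trace$time_ms, force_n = trace$value), path)
}

#' Read/write magnitude CSV
#'
#' Format: header `time_ms,magnitude`.
#'
#' @param path File path.
#' @return A `"magnitude"` [scalar_trace()].
#' @export
read_magnitude_csv <- function(path) {
  df <- read_csv_numeric(path, c("time_ms", "magnitude"), "read_magnitude_csv")
  df <- sort_by_time(df, "read_magnitude_csv")
  scalar_trace(df$time_ms, df$magnitude, kind = "magnitude")
}

#' @rdname read_magnitude_csv
#' @param trace A magnitude [scalar_trace()] to serialize.
#' @export
write_magnitude_csv <- function(trace, path) {
  stopifnot(inherits(trace, "scalar_trace"), trace_kind(trace) == "magnitude")
  write_csv_raw(data.frame(time_ms = trace$time_ms, magnitude = trace$value), path)
}

#' Read/write step-event CSV
#'
#' Format: header `time_ms`, one event per row.
#'
#' @param path File path.
#' @param source Event source tag applied on read.
#' @return A [step_events()].
#' @export
read_events_csv <- function(path, source = "pressure_detected") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_ms" %in% names(df))
    stop("read_events_csv: missing column: time_ms", call. = FALSE)
  step_events(as.numeric(df$time_ms), source = source)
}

#' @rdname read_events_csv
#' @param events A [step_events()] to serialize.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "step_events"))
  write_csv_raw(data.frame(time_ms = events$times_ms), path)
}

#' Read/write window-dataset CSV
#'
#' One row per window: `window_start_ms,recording,position,label,f0...`.
#'
#' @param path File path.
#' @return A `window_dataset`.
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  need <- c("window_start_ms", "recording", "position", "label")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0 || length(fcols) == 0)
    stop("read_windows_csv: not a window dataset CSV", call. = FALSE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  feats <- as.matrix(df[, fcols])
  dimnames(feats) <- NULL
  window_len <- length(fcols)
  starts <- as.numeric(df$window_start_ms)
  # geometry: the CSV records 50%-overlap windows; the sampling rate is
  # recovered from the stride between consecutive window starts
  stride_ms <- if (length(starts) > 1) min(diff(sort(unique(starts)))) else NA
  stride <- as.integer(round(window_len / 2))
  rate <- if (is.na(stride_ms)) 30 else round(1000 * stride / stride_ms)
  structure(
    list(features = feats,
         labels = as.integer(df$label),
         positions = as.character(df$position),
         window_starts = starts,
         recording = as.character(df$recording),
         meta = list(window_s = window_len / rate, overlap_frac = 0.5,
                     sample_rate_hz = rate,
                     window_len = window_len,
                     stride = stride)),
    class = "window_dataset"
  )
}

#' @rdname read_windows_csv
#' @param dataset A `window_dataset` to serialize.
#' @export
write_windows_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "window_dataset"))
  feats <- dataset$features
  colnames(feats) <- paste0("f", seq_len(ncol(feats)) - 1L)
  df <- data.frame(window_start_ms = dataset$window_starts,
                   recording = dataset$recording,
                   position = dataset$positions,
                   label = dataset$labels)
  write_csv_raw(cbind(df, as.data.frame(feats)), path)
}

MODEL_BUNDLE_VERSION <- 1L

#' Save / load a fitted step counter
#'
#' The bundle is a versioned serialized archive embedding the fitted
#' models, window configuration and training specs (seeds included).
#' Loading a bundle written by an incompatible package version is refused
#' rather than migrated.
#'
#' @param model A fitted `step_counter`.
#' @param path File path for the bundle.
#' @return `read_model()` returns the `step_counter`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "step_counter"))
  saveRDS(list(format = "stepcountr_model", version = MODEL_BUNDLE_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "stepcountr_model"))
    stop("read_model: not a stepcountr model bundle", call. = FALSE)
  if (!identical(obj$version, MODEL_BUNDLE_VERSION))
    stop(sprintf("read_model: bundle version %s is not supported (expected %d)",
                 obj$version, MODEL_BUNDLE_VERSION), call. = FALSE)
  obj$model
}
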