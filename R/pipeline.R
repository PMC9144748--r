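#' Pipeline configuration
#'
#' The full set of tunable pipeline constants with their reference
#' defaults: 30 Hz sampling, 2 s windows with 50% overlap, a 30 N
#' detection threshold with a 0.2 s refractory period, a 0.5--60 N sensor
#' range, a 5-tap moving-average filter, and a 7:3 chronological
#' train/test split. Configurations round-trip losslessly through YAML
#' via [write_config()] / [read_config()].
#'
#' @param sample_rate_hz Sampling rate of both streams, Hz.
#' @param window_s Sliding-window length, s.
#' @param overlap_frac Fractional window overlap.
#' @param threshold_n Peak-detection force threshold, N.
#' @param min_interval_s Peak-detection refractory period, s.
#' @param clip_low_n,clip_high_n Sensor-range clipping bounds, N.
#' @param maf_half_width Moving-average half-width (2 = 5-tap filter).
#' @param train_frac Training fraction of the dataset split.
#' @param split_mode `"chronological"` or `"random"`.
#' @param seed Base RNG seed for simulation, splitting and model fits.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_rate_hz = 30,
                            window_s = 2.0,
                            overlap_frac = 0.5,
                            threshold_n = 30,
                            min_interval_s = 0.2,
                            clip_low_n = 0.5,
                            clip_high_n = 60,
                            maf_half_width = 2L,
                            train_frac = 0.7,
                            split_mode = c("chronological", "random"),
                            seed = 1L) {
  split_mode <- match.arg(split_mode)
  cfg <- list(sample_rate_hz = sample_rate_hz, window_s = window_s,
              overlap_frac = overlap_frac, threshold_n = threshold_n,
              min_interval_s = min_interval_s, clip_low_n = clip_low_n,
              clip_high_n = clip_high_n,
              maf_half_width = as.integer(maf_half_width),
              train_frac = train_frac, split_mode = split_mode,
              seed = as.integer(seed))
  if (cfg$sample_rate_hz <= 0 || cfg$window_s <= 0 ||
      cfg$overlap_frac < 0 || cfg$overlap_frac >= 1 ||
      cfg$threshold_n <= 0 || cfg$min_interval_s <= 0 ||
      cfg$clip_low_n < 0 || cfg$clip_high_n <= cfg$clip_low_n ||
      cfg$maf_half_width < 0 || cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("pipeline_config: parameter out of range", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run one pipeline stage
#'
#' Programmatic entry point behind the `stepcount` command-line tool.
#' Each command reads and writes the package's CSV/bundle formats:
#'
#' * `simulate`: generate a synthetic recording (`args`: `position`,
#'   `duration_s`, `step_freq_hz`, `seed`, outputs `out_accel`,
#'   `out_pressure`, optional `out_truth`).
#' * `preprocess`: acceleration CSV (`in_accel`) to smoothed-magnitude
#'   CSV (`out`), or pressure CSV (`in_pressure`) to clipped+smoothed
#'   pressure CSV (`out`).
#' * `label`: pressure CSV (`in_pressure`) to detected step events
#'   (`out`).
#' * `windows`: magnitude CSV (`in_magnitude`) + events CSV
#'   (`in_events`) + `position` to a window-dataset CSV (`out`).
#' * `train`: window-dataset CSV (`in_windows`) to a model bundle
#'   (`out`).
#' * `count`: model bundle (`in_model`) + acceleration CSV (`in_accel`)
#'   to a total (printed; per-window report written to `out` if given).
#' * `evaluate`: results CSV with `position,algorithm,ne,nr`
#'   (`in_results`) to a report CSV (`out`) and a formatted table.
#'
#' @param command Stage name (see above).
#' @param args Named list of stage arguments.
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list of produced artifacts.
#' @export
run_pipeline <- function(command, args = list(), config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  commands <- c("simulate", "preprocess", "label", "windows", "train",
                "count", "evaluate")
  if (length(command) != 1L || !command %in% commands) {
    cnd <- simpleError(sprintf("unknown command '%s'; expected one of: %s",
                               command, paste(commands, collapse = ", ")))
    class(cnd) <- c("usage_error", class(cnd))
    stop(cnd)
  }
  t0 <- Sys.time()
  out <- switch(command,
    simulate = {
      sc <- gait_scenario(position = args$position %||% "pocket",
                          duration_s = as.numeric(args$duration_s %||% 60),
                          step_freq_hz = as.numeric(args$step_freq_hz %||% 1.8),
                          sample_rate_hz = config$sample_rate_hz,
                          seed = as.integer(args$seed %||% config$seed))
      rec <- generate_walk(sc)
      write_accel_csv(rec$accel, args$out_accel)
      write_pressure_csv(rec$pressure, args$out_pressure)
      if (!is.null(args$out_truth)) write_events_csv(rec$truth, args$out_truth)
      pipeline_log("simulate", "%d samples, %d true steps",
                   nrow(rec$accel), rec$truth$count)
      list(accel = args$out_accel, pressure = args$out_pressure)
    },
    preprocess = {
      if (!is.null(args$in_accel)) {
        mag <- moving_average(magnitude(read_accel_csv(args$in_accel)),
                              config$maf_half_width)
        write_magnitude_csv(mag, args$out)
        pipeline_log("preprocess", "magnitude: %d samples", nrow(mag))
      } else {
        pr <- read_pressure_csv(args$in_pressure)
        pr <- moving_average(clip_pressure(pr, config$clip_low_n,
                                           config$clip_high_n),
                             config$maf_half_width)
        write_pressure_csv(pr, args$out)
        pipeline_log("preprocess", "pressure: %d samples", nrow(pr))
      }
      list(out = args$out)
    },
    label = {
      pr <- read_pressure_csv(args$in_pressure)
      pr <- moving_average(clip_pressure(pr, config$clip_low_n,
                                         config$clip_high_n),
                           config$maf_half_width)
      ev <- detect_steps(pr, peak_config(config$threshold_n,
                                         config$min_interval_s))
      write_events_csv(ev, args$out)
      pipeline_log("label", "%d step events detected", ev$count)
      list(out = args$out)
    },
    windows = {
      mag <- read_magnitude_csv(args$in_magnitude)
      ev <- read_events_csv(args$in_events)
      wd <- make_windows(mag, ev, position = args$position,
                         window_s = config$window_s,
                         overlap_frac = config$overlap_frac,
                         sample_rate_hz = config$sample_rate_hz,
                         recording = args$recording %||% basename(args$in_magnitude))
      write_windows_csv(wd, args$out)
      pipeline_log("windows", "%d windows of %d samples", n_windows(wd),
                   wd$meta$window_len)
      list(out = args$out)
    },
    train = {
      wd <- read_windows_csv(args$in_windows)
      model <- train_step_counter(wd,
        default_model_specs(seed = as.integer(args$seed %||% config$seed)))
      write_model(model, args$out)
      pipeline_log("train", "trained on %d windows", n_windows(wd))
      list(out = args$out)
    },
    count = {
      model <- read_model(args$in_model)
      res <- count_steps(model, read_accel_csv(args$in_accel),
                         algorithm = args$algorithm %||% "ensemble",
                         maf_half_width = config$maf_half_width)
      cat(sprintf("total_steps: %d\nposition: %s\n", res$total, res$position))
      if (!is.null(args$out))
        write_csv_raw(res$per_window, args$out)
      pipeline_log("count", "total %d steps (%s)", res$total, res$position)
      res
    },
    evaluate = {
      df <- utils::read.csv(args$in_results, stringsAsFactors = FALSE)
      rep <- build_report(df)
      cat(format(rep), "\n")
      if (!is.null(args$out))
        write_csv_raw(as.data.frame(rep), args$out)
      rep
    }
  )
  pipeline_log(command, "done in %.2f s",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
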