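#' End-to-end synthetic benchmark of the step counter
#'
#' Runs the complete study protocol on simulator output: generate a
#' cohort (three carrying positions, several cadences per position),
#' label every recording from its plantar pressure, build the
#' sliding-window dataset, split 7:3, train the two-stage model, and
#' evaluate on the held-out windows — position classification accuracy at
#' the window level, and per-recording step-count accuracy for each
#' regression algorithm on the held-out time span (each recording routed
#' through the classifier's majority-vote position, as at inference
#' time).
#'
#' With the defaults each position contributes three recordings (one per
#' cadence) of `minutes_per_recording` minutes, giving about 21 minutes
#' of signal per position — small enough to run on one CPU in a few
#' minutes while leaving a couple of hundred held-out steps per
#' recording.
#'
#' @param seed Integer seed controlling simulation, splitting and model
#'   fits.
#' @param minutes_per_recording Length of each simulated recording.
#' @param step_freqs_hz Cadences simulated per position.
#' @param algorithms Regression algorithms to evaluate.
#' @param split_mode Dataset split mode (see [split_dataset()]).
#' @param config A [pipeline_config()] providing the preprocessing and
#'   windowing constants.
#'
#' @return List with `classification_accuracy` (percent, window-level
#'   holdout), `report` (an [build_report()] accuracy report),
#'   `per_recording` (data frame of per-recording evaluations), `model`
#'   and `n_test_windows`.
#' @export
benchmark_step_counter <- function(seed = 1L,
                                   minutes_per_recording = 7,
                                   step_freqs_hz = c(1.2, 1.8, 2.4),
                                   algorithms = c("svm", "mlp", "random_forest",
                                                  "ensemble"),
                                   split_mode = "chronological",
                                   config = pipeline_config()) {
  seed <- as.integer(seed) %% 100000L
  positions <- carrying_positions()
  grid <- expand.grid(position = positions, freq = step_freqs_hz,
                      stringsAsFactors = FALSE)
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    gait_scenario(grid$position[i],
                  duration_s = minutes_per_recording * 60,
                  step_freq_hz = grid$freq[i],
                  sample_rate_hz = config$sample_rate_hz,
                  seed = seed * 100L + i)
  })
  cohort <- generate_cohort(scenarios)

  datasets <- list()
  truth_by_rec <- list()
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    rec_id <- sprintf("%s_f%g_s%d", rec$scenario$position,
                      rec$scenario$step_freq_hz, i)
    pr <- moving_average(clip_pressure(rec$pressure, config$clip_low_n,
                                       config$clip_high_n),
                         config$maf_half_width)
    ev <- detect_steps(pr, peak_config(config$threshold_n,
                                       config$min_interval_s))
    mag <- moving_average(magnitude(rec$accel), config$maf_half_width)
    datasets[[rec_id]] <- make_windows(mag, ev,
                                       position = rec$scenario$position,
                                       window_s = config$window_s,
                                       overlap_frac = config$overlap_frac,
                                       sample_rate_hz = config$sample_rate_hz,
                                       recording = rec_id)
    truth_by_rec[[rec_id]] <- rec$truth
  }
  dataset <- bind_windows(datasets)
  parts <- split_dataset(dataset, train_frac = config$train_frac,
                         mode = split_mode, seed = seed + 7L)
  model <- train_step_counter(parts$train,
                              default_model_specs(algorithms, seed = seed + 11L))

  pred_pos <- classify_position(model, parts$test$features)
  cls_acc <- classification_accuracy(pred_pos, parts$test$positions)

  window_ms <- model$config$window_s * 1000
  rows <- list()
  for (rec_id in unique(parts$test$recording)) {
    idx <- which(parts$test$recording == rec_id)
    votes <- table(factor(pred_pos[idx], levels = positions))
    routed <- names(votes)[which.max(votes)]
    span_start <- min(parts$test$window_starts[idx])
    span_end <- max(parts$test$window_starts[idx]) + window_ms
    nr <- count_events_in(truth_by_rec[[rec_id]], span_start, span_end)
    for (alg in algorithms) {
      preds <- predict_window_steps(model,
                                    parts$test$features[idx, , drop = FALSE],
                                    routed, alg)
      rows[[length(rows) + 1L]] <- data.frame(
        recording = rec_id,
        position = parts$test$positions[idx][1],
        routed_position = routed,
        algorithm = alg,
        ne = aggregate_window_preds(preds, model$config$stride,
                                    model$config$window_len),
        nr = nr)
    }
  }
  per_recording <- do.call(rbind, rows)
  list(classification_accuracy = cls_acc,
       report = build_report(per_recording),
       per_recording = per_recording,
       model = model,
       n_test_windows = n_windows(parts$test))
}
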