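# Fixtures are generated in code; nothing is read from disk.

quick_scenario <- function(position = "pocket", duration_s = 60,
                           step_freq_hz = 1.8, seed = 1L, ...) {
  gait_scenario(position, duration_s = duration_s,
                step_freq_hz = step_freq_hz, seed = seed, ...)
}

# clip -> smooth -> detect, the standard labeling chain
label_recording <- function(rec) {
  detect_steps(moving_average(clip_pressure(rec$pressure)))
}

# recording -> labeled window dataset (full preprocessing chain)
windows_from_recording <- function(rec, recording = "rec1") {
  ev <- label_recording(rec)
  mag <- moving_average(magnitude(rec$accel))
  make_windows(mag, ev, position = rec$scenario$position,
               recording = recording)
}

# A small labeled three-position dataset plus a fitted model, built once
# per test run and shared across ensemble tests. Two cadences per
# position so regressors see within-position variation.
shared_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    grid <- expand.grid(position = carrying_positions(), freq = c(1.4, 2.2),
                        stringsAsFactors = FALSE)
    scens <- lapply(seq_len(nrow(grid)), function(i) {
      quick_scenario(grid$position[i], duration_s = 90,
                     step_freq_hz = grid$freq[i], seed = 400L + i)
    })
    cohort <- generate_cohort(scens)
    ds <- bind_windows(lapply(seq_along(cohort), function(i) {
      windows_from_recording(cohort[[i]], recording = paste0("rec", i))
    }))
    specs <- list(
      model_spec("random_forest", "classifier",
                 hyperparams = list(ntree = 100), seed = 21L),
      model_spec("svm", "regressor", seed = 22L),
      model_spec("mlp", "regressor",
                 hyperparams = list(size = 12, maxit = 150), seed = 23L),
      model_spec("random_forest", "regressor",
                 hyperparams = list(ntree = 100), seed = 24L),
      model_spec("ensemble", "regressor", seed = 25L)
    )
    parts <- split_dataset(ds, 0.7, mode = "chronological")
    model <- train_step_counter(parts$train, specs)
    cache <<- list(cohort = cohort, dataset = ds, parts = parts,
                   model = model, specs = specs)
    cache
  }
})
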