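test_that("split honours the 7:3 ratio and its mode contracts", {
  rec <- generate_walk(quick_scenario(duration_s = 101, seed = 31))
  ds <- windows_from_recording(rec)  # 100 windows
  expect_equal(n_windows(ds), 100)
  parts <- split_dataset(ds, 0.7)
  expect_equal(n_windows(parts$train), 70)
  expect_equal(n_windows(parts$test), 30)
  # chronological: every training window precedes every test window
  expect_lt(max(parts$train$window_starts), min(parts$test$window_starts))
  r1 <- split_dataset(ds, 0.7, mode = "random", seed = 5)
  r2 <- split_dataset(ds, 0.7, mode = "random", seed = 5)
  expect_identical(r1$train$window_starts, r2$train$window_starts)
  expect_error(split_dataset(ds, 1.2), "train_frac")
  expect_error(split_dataset(ds, 0), "train_frac")
})

test_that("chronological split separates per recording in multi-recording sets", {
  fx <- shared_fixture()
  parts <- fx$parts
  for (rec in unique(fx$dataset$recording)) {
    tr <- parts$train$window_starts[parts$train$recording == rec]
    te <- parts$test$window_starts[parts$test$recording == rec]
    expect_lt(max(tr), min(te))
  }
})

test_that("the regressor bank has one fitted model per position and algorithm", {
  fx <- shared_fixture()
  model <- fx$model
  expect_setequal(names(model$regressors), carrying_positions())
  for (p in carrying_positions())
    expect_setequal(names(model$regressors[[p]]),
                    c("svm", "mlp", "random_forest"))
  expect_equal(sum(model$ensemble_weights), 1)
  # a bank restricted to one algorithm has exactly one regressor per position
  small <- train_step_counter(
    fx$parts$train,
    list(model_spec("random_forest", "classifier",
                    hyperparams = list(ntree = 30), seed = 1),
         model_spec("random_forest", "regressor",
                    hyperparams = list(ntree = 30), seed = 2)))
  for (p in carrying_positions())
    expect_equal(names(small$regressors[[p]]), "random_forest")
})

test_that("training rejects incomplete position coverage by name", {
  rec <- generate_walk(quick_scenario("pocket", duration_s = 60, seed = 8))
  ds <- windows_from_recording(rec)
  expect_error(train_step_counter(ds, list(
    model_spec("random_forest", "regressor"))),
    "handheld.*handbag|handheld, handbag")
})

test_that("regressors are trained only on their own position's windows", {
  # give each position a constant, distinct label; a forest trained per
  # position must reproduce its own constant, proving the routing
  fx <- shared_fixture()
  ds <- fx$parts$train
  rigged <- ds
  rigged$labels <- c(handheld = 0L, pocket = 5L,
                     handbag = 10L)[rigged$positions]
  m <- train_step_counter(rigged, list(
    model_spec("random_forest", "classifier",
               hyperparams = list(ntree = 30), seed = 1),
    model_spec("random_forest", "regressor",
               hyperparams = list(ntree = 30), seed = 2)))
  i_hand <- which(ds$positions == "handheld")[1:5]
  i_pock <- which(ds$positions == "pocket")[1:5]
  expect_equal(predict_window_steps(m, ds$features[i_hand, ], "handheld",
                                    "random_forest"),
               rep(0, 5), tolerance = 1e-6)
  expect_equal(predict_window_steps(m, ds$features[i_pock, ], "pocket",
                                    "random_forest"),
               rep(5, 5), tolerance = 1e-6)
  # the same windows routed to the handbag bank see that bank's constant
  expect_equal(predict_window_steps(m, ds$features[i_hand, ], "handbag",
                                    "random_forest"),
               rep(10, 5), tolerance = 1e-6)
})

test_that("position classification behaves on and off the training set", {
  fx <- shared_fixture()
  model <- fx$model
  train <- fx$parts$train
  pred <- classify_position(model, train$features)
  expect_length(pred, n_windows(train))
  # an overfit-capable forest nearly memorises its training windows
  expect_gte(mean(pred == train$positions), 0.95)
  # a pure-gravity constant window still gets one of the three labels
  flat <- rep(9.81, model$config$window_len)
  expect_true(classify_position(model, flat) %in% carrying_positions())
  expect_error(classify_position(model, flat[-1]), "expects")
})

test_that("ensemble predictions are convex combinations of their components", {
  fx <- shared_fixture()
  model <- fx$model
  X <- fx$parts$test$features[1:20, ]
  p <- fx$parts$test$positions[1]
  comps <- sapply(c("svm", "mlp", "random_forest"), function(a)
    predict_window_steps(model, X, p, a))
  ens <- predict_window_steps(model, X, p, "ensemble")
  expect_true(all(ens >= apply(comps, 1, min) - 1e-9))
  expect_true(all(ens <= apply(comps, 1, max) + 1e-9))
  expect_true(all(ens >= 0))
  expect_error(predict_window_steps(model, X, p, "cubist"), "algorithm")
  expect_error(predict_window_steps(model, X, "backpack", "svm"), "position")
})

test_that("degenerate ensemble weights reduce to the single component", {
  fx <- shared_fixture()
  specs <- list(
    model_spec("random_forest", "classifier",
               hyperparams = list(ntree = 30), seed = 21L),
    model_spec("svm", "regressor", seed = 22L),
    model_spec("mlp", "regressor",
               hyperparams = list(size = 5, maxit = 50), seed = 23L),
    model_spec("random_forest", "regressor",
               hyperparams = list(ntree = 30), seed = 24L),
    model_spec("ensemble", "regressor",
               hyperparams = list(weights = c(svm = 1, mlp = 0,
                                              random_forest = 0)),
               seed = 25L))
  m <- train_step_counter(fx$parts$train, specs)
  X <- fx$parts$test$features[1:10, ]
  expect_equal(predict_window_steps(m, X, "pocket", "ensemble"),
               predict_window_steps(m, X, "pocket", "svm"))
})

test_that("ensemble weights must be a valid convex combination", {
  expect_error(model_spec("ensemble", "regressor",
                          hyperparams = list(weights = c(svm = 0.6, mlp = 0.6,
                                                         random_forest = 0))),
               "sum to 1")
  expect_error(model_spec("ensemble", "regressor",
                          hyperparams = list(weights = c(a = 0.5, b = 0.5))),
               "named")
  expect_error(model_spec("ensemble", "classifier"), "regressor")
})

test_that("whole-recording counting is consistent at the edges", {
  fx <- shared_fixture()
  model <- fx$model
  # single-window recording: the total is the rounded window prediction
  rec <- fx$cohort[[2]]
  mag <- moving_average(magnitude(rec$accel))
  one <- accel_trace(rec$accel$time_ms[1:60], rec$accel$x[1:60],
                     rec$accel$y[1:60], rec$accel$z[1:60])
  res1 <- count_steps(model, one)
  feats <- moving_average(magnitude(one))$value
  pred <- predict_window_steps(model, feats, res1$position, "ensemble")
  expect_equal(res1$total, round(pred))
  # doubling a recording doubles the count to within one window's worth
  half <- accel_trace(rec$accel$time_ms[1:900], rec$accel$x[1:900],
                      rec$accel$y[1:900], rec$accel$z[1:900])
  t2 <- c(half$time_ms, half$time_ms + (half$time_ms[900] - half$time_ms[1]) + 33)
  doubled <- accel_trace(t2, rep(half$x, 2), rep(half$y, 2), rep(half$z, 2))
  res_half <- count_steps(model, half)
  res_double <- count_steps(model, doubled)
  max_per_window <- max(fx$dataset$labels)
  expect_lte(abs(res_double$total - 2 * res_half$total), max_per_window + 1)
  expect_error(count_steps(model, one[1:10, ]), "at least")
})

test_that("recording-level counting recovers the truth on held-out signal", {
  fx <- shared_fixture()
  model <- fx$model
  rec <- generate_walk(quick_scenario("pocket", duration_s = 120,
                                      step_freq_hz = 1.8, seed = 555))
  res <- count_steps(model, rec$accel)
  expect_identical(res$position, "pocket")
  expect_gte(step_accuracy(res$total, rec$truth$count), 90)
  expect_equal(sum(res$position_votes), n_windows(
    make_windows(moving_average(magnitude(rec$accel)), sample_rate_hz = 30)))
})

test_that("training is reproducible given identical specs and data", {
  fx <- shared_fixture()
  m2 <- train_step_counter(fx$parts$train, fx$specs)
  X <- fx$parts$test$features[1:15, ]
  for (alg in c("svm", "mlp", "random_forest", "ensemble"))
    expect_equal(predict_window_steps(m2, X, "handbag", alg),
                 predict_window_steps(fx$model, X, "handbag", alg))
  expect_identical(classify_position(m2, X), classify_position(fx$model, X))
})
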