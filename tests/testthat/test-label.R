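test_that("clean stance pulses are all detected", {
  rec <- generate_walk(quick_scenario("pocket", duration_s = 10,
                                      step_freq_hz = 2,
                                      spurious_noise_rate = 0, seed = 3))
  ev <- label_recording(rec)
  expect_equal(ev$count, 20)
  expect_equal(ev$count, length(ev$times_ms))
  expect_identical(ev$source, "pressure_detected")
})

test_that("signals that never reach the threshold yield zero events", {
  t_ms <- seq(0, by = 33, length.out = 300)
  # artifact-like bumps peaking at 25 N
  v <- 25 * abs(sin(2 * pi * seq_along(t_ms) / 30))
  ev <- detect_steps(scalar_trace(t_ms, v, kind = "pressure"))
  expect_equal(ev$count, 0)
})

test_that("the refractory period suppresses close crossings", {
  # two upward 30 N crossings 100 ms apart -> only the first survives
  t_ms <- c(0, 50, 100, 150, 200, 250, 300)
  v <- c(0, 35, 10, 35, 10, 0, 0)
  ev <- detect_steps(scalar_trace(t_ms, v, kind = "pressure"))
  expect_equal(ev$count, 1)
  expect_equal(ev$times_ms, 50)
  # spaced beyond 200 ms both survive
  v2 <- c(0, 35, 10, 0, 0, 35, 10)
  ev2 <- detect_steps(scalar_trace(t_ms, v2, kind = "pressure"))
  expect_equal(ev2$count, 2)
})

test_that("unsorted timestamps are rejected", {
  pr <- scalar_trace(c(0, 50, 100), c(0, 40, 0), kind = "pressure")
  pr$time_ms <- c(100, 50, 0)
  expect_error(detect_steps(pr), "increasing")
})

test_that("sub-threshold artifacts never change the detected count", {
  for (seed in 1:4) {
    for (f in c(0.9, 1.8, 2.6)) {
      clean <- generate_walk(quick_scenario("handheld", duration_s = 60,
                                            step_freq_hz = f,
                                            spurious_noise_rate = 0,
                                            seed = seed))
      noisy <- generate_walk(quick_scenario("handheld", duration_s = 60,
                                            step_freq_hz = f,
                                            spurious_noise_rate = 30,
                                            seed = seed))
      expect_equal(label_recording(noisy)$count, label_recording(clean)$count)
      expect_equal(label_recording(clean)$count, clean$truth$count)
    }
  }
})

test_that("lengthening the refractory period never increases the count", {
  for (seed in 1:5) {
    set.seed(seed)
    t_ms <- seq(0, by = 33, length.out = 600)
    v <- pmax(0, 40 * sin(2 * pi * 1.7 * t_ms / 1000) + rnorm(600, 0, 12))
    tr <- scalar_trace(t_ms, v, kind = "pressure")
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(ri)
      detect_steps(tr, peak_config(min_interval_s = ri))$count, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("count_events_in uses half-open windows and matches a linear scan", {
  ev <- step_events(c(100, 500, 900))
  expect_equal(count_events_in(ev, 0, 1000), 3)
  expect_equal(count_events_in(ev, 500, 900), 1)  # 500 in, 900 out
  expect_error(count_events_in(ev, 900, 500), "start_ms < end_ms")
  set.seed(42)
  for (i in 1:10) {
    times <- sort(runif(50, 0, 10000))
    ev <- step_events(times)
    bounds <- sort(runif(2, 0, 10000))
    brute <- sum(vapply(times, function(tt)
      tt >= bounds[1] && tt < bounds[2], logical(1)))
    expect_equal(count_events_in(ev, bounds[1], bounds[2]), brute)
  }
})

test_that("counts over a disjoint tiling sum to the total event count", {
  set.seed(9)
  times <- sort(runif(200, 0, 60000))
  ev <- step_events(times)
  edges <- seq(0, 60001, length.out = 13)
  tiled <- sum(vapply(seq_len(length(edges) - 1), function(i)
    count_events_in(ev, edges[i], edges[i + 1]), numeric(1)))
  expect_equal(tiled, ev$count)
})
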