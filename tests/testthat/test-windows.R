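mk_mag <- function(n, rate = 30) {
  scalar_trace(seq(0, by = round(1000 / rate), length.out = n),
               9.81 + sin(seq_len(n)), kind = "magnitude")
}

test_that("window counts follow the stride formula", {
  expect_equal(n_windows(make_windows(mk_mag(60), sample_rate_hz = 30)), 1)
  wd <- make_windows(mk_mag(90), sample_rate_hz = 30)
  expect_equal(n_windows(wd), 2)
  # consecutive windows share exactly 30 samples
  expect_equal(wd$features[1, 31:60], wd$features[2, 1:30])
  expect_equal(n_windows(make_windows(mk_mag(1000), sample_rate_hz = 30)),
               floor((1000 - 60) / 30) + 1)  # 32
  expect_error(make_windows(mk_mag(59), sample_rate_hz = 30),
               "at least")
})

test_that("window starts match brute-force enumeration of valid starts", {
  for (n in c(60, 61, 89, 90, 137, 500)) {
    for (ov in c(0.5, 0.25, 0)) {
      wd <- make_windows(mk_mag(n), overlap_frac = ov, sample_rate_hz = 30)
      L <- wd$meta$window_len
      stride <- wd$meta$stride
      brute <- 0L
      i <- 1L
      while (i + L - 1L <= n) {
        brute <- brute + 1L
        i <- i + stride
      }
      expect_equal(n_windows(wd), brute)
      expect_equal(ncol(wd$features), L)
      # no window reaches past the trace end
      last_start <- max(match(wd$window_starts, mk_mag(n)$time_ms))
      expect_lte(last_start + L - 1L, n)
    }
  }
})

test_that("window labels tile the event count at 50% overlap", {
  rec <- generate_walk(quick_scenario("pocket", duration_s = 120,
                                      step_freq_hz = 1.8, seed = 13))
  ev <- label_recording(rec)
  wd <- windows_from_recording(rec)
  # interior events are covered by exactly two overlapping windows
  covered_span_events <- count_events_in(
    ev, wd$window_starts[1],
    wd$window_starts[n_windows(wd)] + wd$meta$window_s * 1000)
  expect_lte(abs(sum(wd$labels) / 2 - covered_span_events),
             max(wd$labels))
})

test_that("windowing is deterministic", {
  rec <- generate_walk(quick_scenario(duration_s = 30, seed = 77))
  expect_identical(windows_from_recording(rec), windows_from_recording(rec))
})

test_that("identical streams align unchanged", {
  rec <- generate_walk(quick_scenario(duration_s = 10, seed = 2))
  out <- align_streams(rec$accel, rec$pressure)
  expect_equal(out$accel$time_ms, rec$accel$time_ms)
  expect_equal(out$pressure$value, rec$pressure$value)
})

test_that("small constant shifts pair within tolerance", {
  rec <- generate_walk(quick_scenario(duration_s = 10, seed = 2))
  shifted <- scalar_trace(rec$pressure$time_ms + 10, rec$pressure$value,
                          kind = "pressure")
  out <- align_streams(rec$accel, shifted)
  # all overlapping samples pair (10 ms < 50 ms tolerance)
  expect_equal(nrow(out$accel), nrow(out$pressure))
  expect_gte(nrow(out$accel), nrow(rec$accel) - 1)
  expect_true(all(abs(out$pressure$time_ms - out$accel$time_ms) <= 50))
})

test_that("disjoint spans fail and oversize skews are dropped", {
  rec <- generate_walk(quick_scenario(duration_s = 5, seed = 2))
  far <- scalar_trace(rec$pressure$time_ms + 1e7, rec$pressure$value,
                      kind = "pressure")
  expect_error(align_streams(rec$accel, far), "overlap")
  # pressure at a third of the rate: many accel samples exceed 15 ms skew
  idx <- seq(1, nrow(rec$pressure), by = 3)
  sparse <- scalar_trace(rec$pressure$time_ms[idx], rec$pressure$value[idx],
                         kind = "pressure")
  expect_warning(out <- align_streams(rec$accel, sparse, max_skew_ms = 15),
                 "dropped")
  expect_lt(nrow(out$accel), nrow(rec$accel))
})

test_that("bind and subset preserve window structure", {
  r1 <- generate_walk(quick_scenario("pocket", duration_s = 20, seed = 1))
  r2 <- generate_walk(quick_scenario("handheld", duration_s = 20, seed = 2))
  d1 <- windows_from_recording(r1, "a")
  d2 <- windows_from_recording(r2, "b")
  both <- bind_windows(d1, d2)
  expect_equal(n_windows(both), n_windows(d1) + n_windows(d2))
  expect_equal(unique(both$recording), c("a", "b"))
  sub <- both[seq_len(n_windows(d1))]
  expect_equal(sub$features, d1$features)
  expect_equal(sub$labels, d1$labels)
})
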