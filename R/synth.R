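#' Synthetic walking scenario
#'
#' Describes one simulated walking recording: carrying position, duration,
#' cadence, sampling rate, sensor noise, and the RNG seed. The defaults
#' emulate self-paced walking (roughly 0.8--1.5 m/s, i.e. a cadence near
#' 1.8 steps/s) recorded at 30 Hz, with a single toe-mounted force sensor
#' on one foot.
#'
#' Cadence is restricted to the 0.5--3 Hz walking band; scenarios outside
#' it are rejected.
#'
#' @param position Carrying position, one of [carrying_positions()].
#' @param duration_s Recording length, seconds (> 0).
#' @param step_freq_hz Cadence, steps per second, in \[0.5, 3\].
#' @param sample_rate_hz Sampling rate of both streams, Hz.
#' @param noise_sd Gaussian acceleration noise SD per axis, m/s^2.
#' @param pressure_peak_n Peak stance force, N (must exceed the 30 N
#'   detection threshold to be countable).
#' @param spurious_noise_rate Expected number of sub-threshold pressure
#'   artifacts per minute (Poisson), each with peak force in 5--25 N.
#' @param steps_per_peak Steps represented by one single-foot pressure
#'   peak. The labeler equates peaks with steps (default 1); users who read
#'   single-foot contacts as strides may set 2.
#' @param timestamp_jitter_ms SD of Gaussian jitter added to sample
#'   timestamps (default 0: jitterless, evenly spaced samples). Small
#'   values are useful for exercising timestamp alignment.
#' @param start_ms Epoch-ms timestamp of the first sample.
#' @param seed Integer RNG seed; identical scenarios generate identical
#'   recordings.
#'
#' @return A list of class `gait_scenario`.
#' @export
#' @examples
#' gait_scenario("pocket", duration_s = 10, step_freq_hz = 2)
gait_scenario <- function(position,
                          duration_s = 60,
                          step_freq_hz = 1.8,
                          sample_rate_hz = 30,
                          noise_sd = 0.3,
                          pressure_peak_n = 50,
                          spurious_noise_rate = 5,
                          steps_per_peak = 1L,
                          timestamp_jitter_ms = 0,
                          start_ms = 1.6e12,
                          seed = 1L) {
  position <- match.arg(position, carrying_positions())
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("gait_scenario: duration_s must be positive", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("gait_scenario: sample_rate_hz must be positive", call. = FALSE)
  if (step_freq_hz < 0.5 || step_freq_hz > 3)
    stop("gait_scenario: step_freq_hz must lie in the walking band [0.5, 3] Hz",
         call. = FALSE)
  if (noise_sd < 0 || pressure_peak_n <= 0 || spurious_noise_rate < 0)
    stop("gait_scenario: noise_sd/pressure_peak_n/spurious_noise_rate out of range",
         call. = FALSE)
  structure(
    list(position = position, duration_s = duration_s,
         step_freq_hz = step_freq_hz, sample_rate_hz = sample_rate_hz,
         noise_sd = noise_sd, pressure_peak_n = pressure_peak_n,
         spurious_noise_rate = spurious_noise_rate,
         steps_per_peak = as.integer(steps_per_peak),
         timestamp_jitter_ms = timestamp_jitter_ms,
         start_ms = start_ms, seed = as.integer(seed)),
    class = "gait_scenario"
  )
}

# Position-specific acceleration signatures. These are synthetic by
# construction: amplitudes (m/s^2), harmonic content and amplitude
# modulation were chosen only to make the three positions statistically
# separable, not to reproduce any measured gait signal.
#   handheld - low amplitude, smooth, gravity on z (screen up)
#   pocket   - high amplitude with a strong 2nd harmonic, gravity on x
#   handbag  - pendulum-like slow amplitude modulation, gravity on y
position_profile <- function(position) {
  switch(position,
    handheld = list(grav_axis = "z", a1 = 1.2, a2 = 0.3, lat = 0.3,
                    am_depth = 0, am_freq = 0),
    pocket   = list(grav_axis = "x", a1 = 3.0, a2 = 2.0, lat = 1.0,
                    am_depth = 0, am_freq = 0),
    handbag  = list(grav_axis = "y", a1 = 2.0, a2 = 0.5, lat = 0.8,
                    am_depth = 0.4, am_freq = 0.25)
  )
}

#' Generate one synthetic walking recording
#'
#' Simulates a paired acceleration/pressure recording with known step
#' events. The acceleration signal is a gravity baseline (9.81 m/s^2 on a
#' position-specific axis) plus a quasi-periodic component at the cadence
#' and its second harmonic, with a position-specific amplitude/harmonic/
#' modulation profile and additive Gaussian noise. The plantar force is a
#' train of half-sine stance pulses (stance fraction 0.6 of the gait
#' cycle, zero during swing) plus optional sub-threshold swing-contact
#' artifacts (0.1 s bumps of 5--25 N placed inside swing gaps, clear of
#' the stance pulses, emulating foot grazes while the foot is airborne)
#' and a
#' small sensor noise floor. One pulse is emitted per ground-truth step.
#'
#' Output is deterministic: the same scenario (including its seed) always
#' produces a bit-identical recording.
#'
#' @param scenario A [gait_scenario()].
#'
#' @return A list of class `synthetic_recording` with elements `accel`
#'   ([accel_trace()]), `pressure` (raw `"pressure"` [scalar_trace()]),
#'   `truth` ([step_events()] of pulse onsets) and `scenario`.
#' @export
#' @examples
#' rec <- generate_walk(gait_scenario("pocket", duration_s = 10,
#'                                    step_freq_hz = 2, seed = 1))
#' rec$truth$count  # 20
generate_walk <- function(scenario) {
  if (!inherits(scenario, "gait_scenario"))
    stop("generate_walk: scenario must be a gait_scenario", call. = FALSE)
  s <- scenario
  withr::with_seed(s$seed, {
    n <- round(s$duration_s * s$sample_rate_hz)
    tsec <- (seq_len(n) - 1) / s$sample_rate_hz
    if (s$timestamp_jitter_ms > 0) {
      jit <- stats::rnorm(n, 0, s$timestamp_jitter_ms) / 1000
      # keep order strict after jitter
      tsec <- sort(tsec + pmin(pmax(jit, -0.01), 0.01))
      tsec <- tsec + seq(0, 1e-6, length.out = n)
    }
    t_ms <- s$start_ms + round(tsec * 1000)
    # ms rounding (or jitter) may collide timestamps; enforce strict order
    if (n > 1L && any(diff(t_ms) <= 0)) {
      for (i in 2:n) if (t_ms[i] <= t_ms[i - 1L]) t_ms[i] <- t_ms[i - 1L] + 1
    }

    f <- s$step_freq_hz
    cycle <- 1 / f
    stance <- 0.6 * cycle
    n_steps <- floor(s$duration_s * f)
    onsets <- (seq_len(n_steps) - 1) * cycle + 0.2 * cycle

    pressure <- numeric(n)
    for (on in onsets) {
      idx <- which(tsec >= on & tsec <= on + stance)
      pressure[idx] <- pressure[idx] +
        s$pressure_peak_n * sin(pi * (tsec[idx] - on) / stance)
    }
    n_art <- stats::rpois(1, s$spurious_noise_rate * s$duration_s / 60)
    if (n_art > 0) {
      art_t <- stats::runif(n_art, 0, s$duration_s - 0.1)
      art_p <- stats::runif(n_art, 5, 25)
      # swing-contact artifacts: keep only candidates whose 0.1 s pulse
      # fits in a swing gap with >= 0.1 s clearance from every stance
      # pulse, so noise never stacks onto a stance tail
      phase <- (art_t - 0.2 * cycle) %% cycle
      in_swing <- phase >= stance + 0.1 & phase + 0.1 <= cycle - 0.1
      for (k in which(in_swing)) {
        idx <- which(tsec >= art_t[k] & tsec <= art_t[k] + 0.1)
        pressure[idx] <- pressure[idx] + art_p[k] * sin(pi * (tsec[idx] - art_t[k]) / 0.1)
      }
    }
    pressure <- pmax(pressure + stats::rnorm(n, 0, 0.15), 0)

    prof <- position_profile(s$position)
    phase <- 2 * pi * f * (tsec - 0.2 * cycle)
    am <- 1 + prof$am_depth * sin(2 * pi * prof$am_freq * tsec)
    vertical <- am * (prof$a1 * sin(phase) + prof$a2 * sin(2 * phase + 0.7))
    lateral <- am * prof$lat * sin(phase + 1.3)
    axes <- list(x = stats::rnorm(n, 0, s$noise_sd),
                 y = stats::rnorm(n, 0, s$noise_sd),
                 z = stats::rnorm(n, 0, s$noise_sd))
    axes[[prof$grav_axis]] <- axes[[prof$grav_axis]] + 9.81 + vertical
    lat_axis <- setdiff(c("x", "y", "z"), prof$grav_axis)[1]
    axes[[lat_axis]] <- axes[[lat_axis]] + lateral

    accel <- accel_trace(t_ms, axes$x, axes$y, axes$z, position = s$position)
    press <- scalar_trace(t_ms, pressure, kind = "pressure")
    truth <- step_events(s$start_ms + round(onsets * 1000),
                         source = "synthetic_truth")
    structure(list(accel = accel, pressure = press, truth = truth,
                   scenario = s),
              class = "synthetic_recording")
  })
}

#' Generate a cohort of synthetic recordings
#'
#' One recording per scenario, each generated from its own seed so the
#' recordings are mutually independent yet individually reproducible.
#'
#' @param scenarios Non-empty list of [gait_scenario()] objects.
#'
#' @return List of `synthetic_recording` objects, one per scenario.
#' @export
generate_cohort <- function(scenarios) {
  if (!is.list(scenarios) || length(scenarios) == 0L ||
      inherits(scenarios, "gait_scenario"))
    stop("generate_cohort: scenarios must be a non-empty list of gait_scenario objects",
         call. = FALSE)
  lapply(scenarios, generate_walk)
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s, %.0f s at %g Hz, cadence %g Hz, %d true steps\n",
              x$scenario$position, x$scenario$duration_s,
              x$scenario$sample_rate_hz, x$scenario$step_freq_hz,
              x$truth$count))
  invisible(x)
}
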