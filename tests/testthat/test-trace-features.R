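# Per-trial feature extraction.

test_that("differentiation: constants, ramps, and closed-form filter gain", {
  tr <- make_ramp_trace(vx = 0, vy = 0)
  v <- differentiate(tr, cutoff_hz = 25)
  expect_true(all(abs(v$vx) < 1e-9 & abs(v$vy) < 1e-9))
  tr <- make_ramp_trace(vx = 20, dur_ms = 1000)
  v <- differentiate(tr, cutoff_hz = 25)
  mid <- v$time_ms > 100 & v$time_ms < 900
  expect_true(all(abs(v$vx[mid] - 20) < 0.1))
  # 2 Hz sinusoid, 1 deg amplitude: peak velocity 4*pi attenuated by the
  # central-difference response times the FIR gain (computed closed-form)
  fs <- 250; f <- 2
  tms <- seq(0, 2000, by = 1000 / fs)
  tr <- data.frame(time_ms = tms, x_deg = sin(2 * pi * f * tms / 1000),
                   y_deg = 0, pupil_mm = NA, valid = 1L)
  v <- differentiate(tr, cutoff_hz = 25)
  g_cd <- sin(2 * pi * f / fs) / (2 * pi * f / fs)
  g_fir <- fir_gain(fir_kernel(fs, 25, 21), f, fs)
  expect_equal(max(v$vx[50:450]), 4 * pi * g_cd * g_fir, tolerance = 0.002)
  short <- make_ramp_trace(dur_ms = 200)
  short$valid <- 0L
  expect_error(differentiate(short), "50 ms")
})

test_that("saccade detection: none on pure pursuit, exact count on injections", {
  tr <- make_ramp_trace(vx = 24, dur_ms = 1200)
  expect_equal(nrow(detect_saccades(tr)), 0)
  tr <- inject_saccade(tr, 400, 1.5, 10, 30)
  tr <- inject_saccade(tr, 650, 2.0, -15, 34)
  tr <- inject_saccade(tr, 900, 1.0, 5, 26)
  ev <- detect_saccades(tr, target_direction_deg = 0)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$corrected_amplitude_deg, c(1.5, 2.0, 1.0),
               tolerance = 0.05)
  expect_true(all(ev$is_forward_catchup))
  expect_true(all(ev$offset_ms > ev$onset_ms))
  # raw amplitude includes the pursuit displacement, corrected removes it
  expect_true(all(ev$amplitude_deg > ev$corrected_amplitude_deg))
})

test_that("saccades closer than the merge gap collapse into one event", {
  tr <- make_ramp_trace(vx = 0, dur_ms = 1000)
  tr <- inject_saccade(tr, 400, 1.2, 0, 24)
  tr <- inject_saccade(tr, 426, 1.2, 0, 24)   # ~2 ms gap
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
})

test_that("pursuit correction of the main sequence", {
  # saccades riding on 20 deg/s pursuit: raw peaks are inflated by the
  # pursuit velocity, corrected peaks recover the generating line
  slope <- 45; int <- 30
  amps <- rep(seq(0.8, 2.8, by = 0.4), 5)
  tr <- make_ramp_trace(vx = 20, dur_ms = 11000)
  at <- 300 + seq_along(amps) * 300
  for (i in seq_along(amps)) {
    pk <- slope * amps[i] + int
    tr <- inject_saccade(tr, at[i], amps[i], 0, 1000 * 2 * amps[i] / pk)
  }
  ev <- detect_saccades(tr, target_direction_deg = 0)
  expect_equal(nrow(ev), length(amps))
  fit_c <- main_sequence_fit(ev)
  raw <- ev
  raw$pursuit_corrected_peak_deg_s <- raw$peak_velocity_deg_s
  fit_r <- main_sequence_fit(raw)
  expect_equal(fit_c$slope_hz, slope, tolerance = 0.05)
  expect_equal(fit_c$intercept_deg_s, int, tolerance = 0.15)
  # with forward saccades the pursuit rides fully on the peak: leaving
  # peaks uncorrected inflates the regression by ~the pursuit speed
  expect_gt(fit_r$intercept_deg_s, fit_c$intercept_deg_s + 10)
})

test_that("desaccading restores constant velocity and is a no-op otherwise", {
  tr <- make_ramp_trace(vx = 18, dur_ms = 1200)
  v <- differentiate(tr, cutoff_hz = NULL)
  expect_identical(desaccade_velocity(v, NULL), v)
  trs <- inject_saccade(tr, 500, 1.5, 0, 30)
  vs <- differentiate(trs, cutoff_hz = NULL)
  ev <- detect_saccades(trs)
  vd <- desaccade_velocity(vs, ev)
  mid <- vd$time_ms > 100 & vd$time_ms < 1100
  expect_true(all(abs(vd$vx[mid] - 18) < 0.5))
  # the removed displacement: integral of desaccaded velocity ~ 18*T
  expect_equal(sum(vd$vx[mid]) * 0.004, 18 * sum(mid) * 0.004,
               tolerance = 0.01)
})

test_that("hinge onset fit: exact on noiseless hinge, flags pure noise", {
  h <- make_hinge(break_ms = 165, slope = 120)
  on <- estimate_pursuit_onset(h$vr, h$time_ms)
  expect_true(on$valid)
  expect_lt(abs(on$latency_ms - 165), 4)
  expect_lt(abs(on$slope_deg_s2 - 120), 2)
  set.seed(31)
  noise <- rnorm(length(h$time_ms), 0, 2)
  off <- estimate_pursuit_onset(noise, h$time_ms)
  expect_false(off$valid)
})

test_that("hinge onset fit is translation equivariant", {
  h1 <- make_hinge(break_ms = 140, slope = 110)
  h2 <- make_hinge(break_ms = 180, slope = 110)
  l1 <- estimate_pursuit_onset(h1$vr, h1$time_ms)$latency_ms
  l2 <- estimate_pursuit_onset(h2$vr, h2$time_ms)$latency_ms
  expect_lt(abs((l2 - l1) - 40), 4)
})

test_that("open-loop acceleration slope", {
  tms <- seq(-200, 600, by = 4)
  vr <- pmin(pmax(tms - 150, 0), 100) * 0.12   # 0 -> 12 deg/s over 100 ms
  expect_lt(abs(open_loop_acceleration(vr, tms, 150) - 120), 0.5)
  expect_equal(open_loop_acceleration(rep(0, length(tms)), tms, 150), 0)
  expect_true(is.na(open_loop_acceleration(vr, tms, 580)))  # past trace end
})

test_that("steady-state velocity projection and direction", {
  tms <- seq(-200, 800, by = 4)
  vel <- data.frame(time_ms = tms, vx = rep(18, length(tms)),
                    vy = rep(0, length(tms)))
  ss <- steady_state_velocity(vel, 0)
  expect_equal(ss$speed_deg_s, 18)
  expect_equal(ss$direction_deg, 0)
  rot <- data.frame(time_ms = tms,
                    vx = 18 * cos(10 * pi / 180),
                    vy = 18 * sin(10 * pi / 180))
  expect_equal(steady_state_velocity(rot, 0)$direction_deg, 10,
               tolerance = 1e-6)
  # >50% invalid window flags the trial
  vel$vx[tms >= 390] <- NA
  expect_false(steady_state_velocity(vel, 0)$valid)
})

test_that("pupil fit drops degenerate transitions", {
  tms <- seq(0, 6000, by = 4)
  flat <- rep(4.5, length(tms))
  trans <- data.frame(time_ms = c(0, 1650, 3300, 4950),
                      type = c("on", "off", "on", "off"))
  fit <- fit_pupil_step(tms, flat, trans)
  expect_true(is.na(fit$contraction_tau_ms))
  expect_true(is.na(fit$dilation_tau_ms))
})

test_that("main-sequence fit: exact line, singular design flagged", {
  sac <- data.frame(corrected_amplitude_deg = seq(0.5, 3, 0.25))
  sac$pursuit_corrected_peak_deg_s <- 45 * sac$corrected_amplitude_deg + 30
  fit <- main_sequence_fit(sac)
  expect_equal(fit$slope_hz, 45, tolerance = 1e-10)
  expect_equal(fit$intercept_deg_s, 30, tolerance = 1e-10)
  expect_false(fit$low_confidence)
  same <- data.frame(corrected_amplitude_deg = rep(1.5, 12),
                     pursuit_corrected_peak_deg_s = rnorm(12, 95))
  expect_true(main_sequence_fit(same)$low_confidence)
  expect_true(is.na(main_sequence_fit(same)$slope_hz))
})

test_that("fixation error is the mean Euclidean miss", {
  g <- expand.grid(target_x = c(-5, 0, 5), target_y = c(-5, 0, 5))
  g$gaze_x <- g$target_x; g$gaze_y <- g$target_y
  expect_equal(fixation_error(g)$error_deg, 0)
  g$gaze_x <- g$target_x + 0.5
  expect_equal(fixation_error(g)$error_deg, 0.5)
  g$gaze_x[1:4] <- NA
  fe <- fixation_error(g)
  expect_equal(fe$n, 5)
  expect_true(fe$flagged)
})

test_that("zero-noise trial recovers latency and acceleration to a sample", {
  p <- fixed_run_params(c(direction_noise_deg = 1e-9))
  cfg <- perfect_config()
  s <- sample_stimulus_schedule(5, seed = 41)
  for (k in 1:3) {
    tr <- simulate_trial(p, s[k, ], cfg, noise = FALSE)
    f <- extract_trial_features(tr$trace, s[k, ])
    expect_lt(abs(f$latency_ms - tr$truth$latency_ms), 5)
    expect_equal(f$open_loop_accel_deg_s2, tr$truth$accel_deg_s2,
                 tolerance = 0.03 * tr$truth$accel_deg_s2)
    expect_equal(f$steady_speed_deg_s, tr$truth$steady_speed_deg_s,
                 tolerance = 0.02 * tr$truth$steady_speed_deg_s)
    expect_equal(f$proportion_smooth, 1)
  }
})
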