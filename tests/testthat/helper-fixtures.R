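# Shared fixtures: all synthetic, built in code.

# population table with zero between-subject and zero session variability
fixed_population <- function() {
  pop <- population_defaults()
  pop$sd[] <- 0
  pop
}

# deterministic run latents at the monocular population means
fixed_run_params <- function(overrides = NULL) {
  pop <- fixed_population()
  p <- stats::setNames(pop$mean, pop$name)
  if (!is.null(overrides)) p[names(overrides)] <- overrides
  p
}

# a noiseless "perfect tracker" configuration: no saccades, no noise
perfect_config <- function() {
  cfg <- cohort_config_defaults()
  cfg$saccade_threshold_deg <- Inf
  cfg$position_noise_sd_deg <- 0
  cfg$trial_latency_sd_ms <- 0
  cfg$trial_accel_cv <- 0
  cfg$steady_direction_sd_deg <- 0
  cfg$pupil_noise_sd_mm <- 0
  cfg
}

# constant-velocity gaze trace (deg/s) sampled at fs
make_ramp_trace <- function(vx = 20, vy = 0, dur_ms = 1000, fs = 250,
                            t0_ms = -200) {
  tms <- seq(t0_ms, dur_ms, by = 1000 / fs)
  t_s <- tms / 1000
  data.frame(time_ms = tms, x_deg = vx * pmax(t_s, 0),
             y_deg = vy * pmax(t_s, 0),
             pupil_mm = NA_real_, valid = 1L)
}

# inject a raised-cosine saccade (displacement amp_deg along dir_deg,
# duration dur_ms) into a trace starting at time at_ms
inject_saccade <- function(trace, at_ms, amp_deg, dir_deg, dur_ms) {
  t_s <- trace$time_ms / 1000
  at <- at_ms / 1000
  d <- dur_ms / 1000
  ph <- pmin(pmax((t_s - at) / d, 0), 1)
  disp <- amp_deg * (ph - sin(2 * pi * ph) / (2 * pi))
  u <- c(cos(dir_deg * pi / 180), sin(dir_deg * pi / 180))
  trace$x_deg <- trace$x_deg + disp * u[1]
  trace$y_deg <- trace$y_deg + disp * u[2]
  trace
}

# noiseless hinge radial-velocity trace: flat base then rising slope
make_hinge <- function(break_ms = 165, slope = 120, base = 0,
                       t_lo = -200, t_hi = 600, fs = 250) {
  tms <- seq(t_lo, t_hi, by = 1000 / fs)
  vr <- base + slope * pmax(tms - break_ms, 0) / 1000
  list(time_ms = tms, vr = vr)
}
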