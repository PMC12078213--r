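# Synthetic step-ramp tracking cohorts with known ground truth.
#
# One trial of the radial Rashbass paradigm: after a truncated-exponential
# fixation wait the target steps 3.2-4.8 deg away from fixation and
# immediately ramps back through it at 16-24 deg/s, continuing 700-1000 ms
# past center. The eye model is a latent-parameter tracker: pursuit starts
# after a per-trial latency, accelerates open-loop for 100 ms along a
# distorted/noisy direction, then blends into steady-state velocity whose
# projected speed encodes the subject's gain, responsiveness and Weber
# speed noise. Catch-up saccades are inserted by a delayed position-error
# trigger with raised-cosine velocity profiles riding on the pursuit, their
# peak velocity following the subject's latent main sequence.

DEFAULT_SPEEDS <- c(16, 18, 20, 22, 24)

#' Default generator configuration
#'
#' @return list of tunables: sampling rate, trial-level jitter SDs, the
#'   saccade-insertion rule, measurement noise, and the pupil light-cycle
#'   layout
#' @export
cohort_config_defaults <- function() {
  list(
    fs_hz = 250,
    pre_onset_ms = 200,
    speeds = DEFAULT_SPEEDS,
    step_range_deg = c(3.2, 4.8),
    ramp_past_center_ms = c(700, 1000),
    fixation_wait_ms = c(200, 5000),
    fixation_wait_mean_ms = 1000,     # exponential rate before truncation
    trial_latency_sd_ms = 15,         # per-trial latency scatter
    trial_accel_cv = 0.2,             # lognormal CV of per-trial acceleration
    steady_direction_sd_deg = 2,      # residual steady-state direction error
    open_loop_ms = 100,
    blend_ms = 100,
    # saccade insertion rule
    saccade_threshold_deg = 1.0,
    saccade_delay_ms = 125,
    saccade_correction = 0.85,
    saccade_amp_cv = 0.1,
    saccade_refractory_ms = 130,
    # measurement noise on gaze position (deg, after smoothing)
    position_noise_sd_deg = 0.02,
    # pupil light cycle: ~0.3 Hz square-wave duty cycle
    pupil_half_period_ms = 1650,
    pupil_cycles = 3,
    pupil_noise_sd_mm = 0.03,
    dark_diameter_mm = 6.9,
    monocular_amplitude_mm = 3.6,
    shunting_k_amplitude = 0.22,
    derive_binocular_pupil = FALSE,
    shunting_k_tau_contraction = 0.035,
    shunting_k_tau_dilation = 0.079)
}

# truncated exponential on [a, b] with pre-truncation mean m
rtruncexp <- function(n, m, a, b) {
  u <- stats::runif(n)
  ea <- exp(-a / m); eb <- exp(-b / m)
  -m * log(ea - u * (ea - eb))
}

#' Sample a step-ramp stimulus schedule
#'
#' Directions are drawn without replacement from the 4-degree grid
#' (0, 4, ..., 356); a 90-trial schedule therefore covers every grid
#' direction exactly once in random order. Speeds are uniform over
#' \{16, 18, 20, 22, 24\} deg/s, step amplitudes uniform in [3.2, 4.8] deg,
#' fixation waits truncated-exponential on [200, 5000] ms, and the ramp
#' continues 700-1000 ms past center. The step is diametrically opposite
#' the ramp (Rashbass geometry).
#'
#' @param n_trials number of trials (>= 1)
#' @param seed optional integer seed
#' @param config generator configuration
#' @return data.frame of StepRampStimulus rows
#' @export
sample_stimulus_schedule <- function(n_trials, seed = NULL,
                                     config = cohort_config_defaults()) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("n_trials must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 356, by = 4)
  dirs <- if (n_trials <= length(grid)) {
    sample(grid, n_trials, replace = FALSE)
  } else {
    sample(grid, n_trials, replace = TRUE)
  }
  data.frame(
    trial_id = seq_len(n_trials),
    ramp_direction_deg = dirs,
    step_direction_deg = wrap360(dirs + 180),
    step_amplitude_deg = stats::runif(n_trials, config$step_range_deg[1],
                                      config$step_range_deg[2]),
    ramp_speed_deg_s = sample(config$speeds, n_trials, replace = TRUE),
    fixation_wait_ms = rtruncexp(n_trials, config$fixation_wait_mean_ms,
                                 config$fixation_wait_ms[1],
                                 config$fixation_wait_ms[2]),
    ramp_past_center_ms = stats::runif(n_trials,
                                       config$ramp_past_center_ms[1],
                                       config$ramp_past_center_ms[2]))
}

# four-fold + two-fold direction-estimation distortion, in degrees.
# anisotropy = 4*a4 (positive expands differences at cardinals);
# asymmetry = 2*a2 (positive compresses toward horizontal).
direction_distortion_deg <- function(theta_deg, anisotropy, asymmetry) {
  th <- deg2rad(theta_deg)
  rad2deg(anisotropy / 4 * sin(4 * th) - asymmetry / 2 * sin(2 * th))
}

# raised-cosine saccade velocity samples; duration set by the latent main
# sequence so that peak velocity = slope*A + intercept exactly
saccade_profile <- function(amp_deg, slope, intercept, dt_s) {
  peak <- slope * amp_deg + intercept
  dur_s <- 2 * amp_deg / peak
  n <- max(2L, round(dur_s / dt_s))
  tt <- (seq_len(n) - 0.5) / n
  v <- peak / 2 * (1 - cos(2 * pi * tt))
  # normalize the discrete integral to the exact amplitude
  v * amp_deg / (sum(v) * dt_s)
}

#' Simulate one step-ramp tracking trial
#'
#' @param run_params named latent vector for one (subject, condition) run,
#'   as in \code{sample_subject_params()$conditions[[cond]]}
#' @param stim one StepRampStimulus row
#' @param config generator configuration
#' @param noise logical; FALSE freezes every stochastic term (used by the
#'   exact-recovery invariants)
#' @return list(trace, truth): \code{trace} is a data.frame with
#'   \code{time_ms, x_deg, y_deg, pupil_mm, valid} sampled at 250 Hz with
#'   motion onset at time 0; \code{truth} holds every generated event and
#'   per-trial latent
#' @export
simulate_trial <- function(run_params, stim,
                           config = cohort_config_defaults(),
                           noise = TRUE) {
  p <- run_params
  fs <- config$fs_hz; dt <- 1 / fs
  crossing_ms <- stim$step_amplitude_deg / stim$ramp_speed_deg_s * 1000
  t_end <- crossing_ms + stim$ramp_past_center_ms
  tms <- seq(-config$pre_onset_ms, t_end, by = 1000 / fs)
  n <- length(tms)
  ts <- tms / 1000

  lat_ms <- p[["latency_ms"]] +
    if (noise) stats::rnorm(1, 0, config$trial_latency_sd_ms) else 0
  lat_ms <- max(lat_ms, 60)
  acc <- p[["accel_deg_s2"]] *
    if (noise) exp(stats::rnorm(1, 0, config$trial_accel_cv)) else 1

  ramp <- stim$ramp_direction_deg
  th_init <- wrap360(ramp +
    direction_distortion_deg(ramp, p[["direction_anisotropy"]],
                             p[["direction_asymmetry"]]) +
    if (noise) stats::rnorm(1, 0, p[["direction_noise_deg"]]) else 0)
  th_steady <- wrap360(ramp +
    if (noise) stats::rnorm(1, 0, config$steady_direction_sd_deg) else 0)

  # steady radial speed: responsiveness sets the slope vs target speed, the
  # offset is chosen so the across-speed mean of speed ratios equals gain;
  # Weber noise scales with target speed so the extracted Weber fraction
  # equals the latent one
  h_mean <- 1 / mean(1 / config$speeds)   # harmonic mean of the speed set
  v_ss <- p[["speed_responsiveness"]] * stim$ramp_speed_deg_s +
    (p[["gain"]] - p[["speed_responsiveness"]]) * h_mean +
    if (noise) {
      stim$ramp_speed_deg_s * stats::rnorm(1, 0, p[["speed_noise_pct"]] / 100)
    } else 0
  v_ss <- max(v_ss, 0.5)

  # smooth velocity: zero until latency; open-loop constant acceleration
  # along th_init; then linear blend of speed and direction into steady state
  rel <- tms - lat_ms
  spd_ol <- pmin(acc * pmax(rel, 0) / 1000, acc * config$open_loop_ms / 1000)
  v_ol_end <- acc * config$open_loop_ms / 1000
  w <- pmin(pmax((rel - config$open_loop_ms) / config$blend_ms, 0), 1)
  spd <- (1 - w) * spd_ol + w * v_ss
  # the initial pursuit direction (with its distortion + noise) is held
  # through the first 160 ms of pursuit -- the window over which direction
  # noise is defined -- before rotating into the steady-state direction
  dirw <- pmin(pmax((rel - 160) / 60, 0), 1)
  th <- th_init + dirw * ang_diff(th_steady, th_init)
  vx <- spd * cos(deg2rad(th))
  vy <- spd * sin(deg2rad(th))

  # target path: jump to step position at t=0, ramp back through center
  u_step <- unit_vec(stim$step_direction_deg)
  r_t <- ifelse(tms < 0, NA, stim$step_amplitude_deg -
                  stim$ramp_speed_deg_s * ts)
  tx <- ifelse(tms < 0, 0, r_t * u_step[1])
  ty <- ifelse(tms < 0, 0, r_t * u_step[2])

  pos_sm_x <- cumsum(vx) * dt
  pos_sm_y <- cumsum(vy) * dt

  # catch-up saccades: delayed position-error trigger
  sacc_vx <- numeric(n); sacc_vy <- numeric(n)
  events <- list()
  delay_n <- round(config$saccade_delay_ms / 1000 * fs)
  refr_n <- round(config$saccade_refractory_ms / 1000 * fs)
  i_pursuit <- which(rel >= 0)[1]
  if (!is.na(i_pursuit)) {
    i_next <- i_pursuit + delay_n
    repeat {
      ex <- tx - (pos_sm_x + cumsum(sacc_vx) * dt)
      ey <- ty - (pos_sm_y + cumsum(sacc_vy) * dt)
      emag <- sqrt(ex^2 + ey^2)
      idx <- which(seq_len(n) >= i_next &
                     seq_len(n) - delay_n >= i_pursuit &
                     emag[pmax(seq_len(n) - delay_n, 1)] >
                       config$saccade_threshold_deg &
                     !is.na(tx))
      if (length(idx) == 0) break
      i0 <- idx[1]
      err_vec <- c(ex[i0], ey[i0])
      amp <- config$saccade_correction * sqrt(sum(err_vec^2)) *
        if (noise) exp(stats::rnorm(1, 0, config$saccade_amp_cv)) else 1
      dir_deg <- rad2deg(atan2(err_vec[2], err_vec[1])) +
        if (noise) stats::rnorm(1, 0, p[["saccade_dispersion_deg"]]) else 0
      prof <- saccade_profile(amp, p[["ms_slope_hz"]],
                              p[["ms_intercept_deg_s"]], dt)
      nd <- length(prof)
      if (i0 + nd > n) break
      sl <- i0:(i0 + nd - 1)
      u <- unit_vec(dir_deg)
      sacc_vx[sl] <- sacc_vx[sl] + prof * u[1]
      sacc_vy[sl] <- sacc_vy[sl] + prof * u[2]
      events[[length(events) + 1]] <- data.frame(
        onset_ms = tms[i0], offset_ms = tms[min(i0 + nd, n)],
        amplitude_deg = amp, direction_deg = wrap360(dir_deg),
        peak_velocity_deg_s = p[["ms_slope_hz"]] * amp +
          p[["ms_intercept_deg_s"]])
      i_next <- i0 + nd + refr_n
    }
  }
  truth_sacc <- if (length(events)) do.call(rbind, events) else
    data.frame(onset_ms = numeric(), offset_ms = numeric(),
               amplitude_deg = numeric(), direction_deg = numeric(),
               peak_velocity_deg_s = numeric())

  x <- pos_sm_x + cumsum(sacc_vx) * dt
  y <- pos_sm_y + cumsum(sacc_vy) * dt
  if (noise && config$position_noise_sd_deg > 0) {
    # mildly band-limited measurement noise (3-sample smoothing of white)
    nz <- function() {
      w0 <- stats::rnorm(n, 0, config$position_noise_sd_deg * sqrt(3))
      stats::filter(w0, rep(1 / 3, 3), sides = 2) |> as.numeric() |>
        (\(v) ifelse(is.na(v), 0, v))()
    }
    x <- x + nz(); y <- y + nz()
  }

  trace <- data.frame(time_ms = tms, x_deg = x, y_deg = y,
                      pupil_mm = NA_real_, valid = 1L)
  truth <- list(latency_ms = lat_ms, accel_deg_s2 = acc,
                initial_direction_deg = th_init,
                steady_direction_deg = th_steady,
                steady_speed_deg_s = v_ss,
                saccades = truth_sacc,
                stim = stim)
  list(trace = trace, truth = truth)
}

#' Simulate a pupillary light-cycle recording
#'
#' Square-wave light modulation (~0.3 Hz): the diameter relaxes
#' exponentially toward the constricted asymptote during light-on
#' half-cycles (contraction tau) and toward the dark asymptote during
#' light-off half-cycles (dilation tau). For a binocular run the
#' constriction amplitude (and optionally the time constants) can be
#' derived from the monocular amplitude through the shunting model.
#'
#' @param run_params latent vector for the run (uses
#'   \code{contraction_tau_ms}, \code{dilation_tau_ms})
#' @param condition "monocular" or "binocular"
#' @param config generator configuration
#' @param noise logical
#' @return list(trace = data.frame(time_ms, pupil_mm),
#'   transitions = data.frame(time_ms, type), amplitude_mm)
#' @export
simulate_pupil_cycle <- function(run_params, condition = "monocular",
                                 config = cohort_config_defaults(),
                                 noise = TRUE) {
  stopifnot(condition %in% c("monocular", "binocular"))
  tau_on <- run_params[["contraction_tau_ms"]]
  tau_off <- run_params[["dilation_tau_ms"]]
  if (tau_on <= 0 || tau_off <= 0) stop("pupil time constants must be > 0")
  M <- config$monocular_amplitude_mm
  amp <- M
  if (condition == "binocular") {
    amp <- binocular_from_monocular(M, config$shunting_k_amplitude)
    if (config$derive_binocular_pupil) {
      tau_on <- tau_on / (1 + config$shunting_k_tau_contraction * M)
      tau_off <- tau_off / (1 + config$shunting_k_tau_dilation * M)
    }
  }
  amp <- min(amp, config$dark_diameter_mm)   # clip at the dark diameter
  a_off <- config$dark_diameter_mm
  a_on <- config$dark_diameter_mm - amp

  fs <- config$fs_hz
  h <- config$pupil_half_period_ms
  n_seg <- 2 * config$pupil_cycles
  seg_len <- round(h / 1000 * fs)
  d0 <- a_off
  tms <- numeric(0); d <- numeric(0); trans <- list()
  t0 <- 0
  for (s in seq_len(n_seg)) {
    on <- s %% 2 == 1                      # odd segments: light on
    tau <- if (on) tau_on else tau_off
    A <- if (on) a_on else a_off
    tt <- (seq_len(seg_len) - 1) / fs * 1000
    seg <- A + (d0 - A) * exp(-tt / tau)
    tms <- c(tms, t0 + tt); d <- c(d, seg)
    trans[[s]] <- data.frame(time_ms = t0, type = if (on) "on" else "off")
    d0 <- seg[seg_len] + (A - seg[seg_len]) * (1 - exp(-(1000 / fs) / tau))
    t0 <- t0 + h
  }
  if (noise && config$pupil_noise_sd_mm > 0) {
    d <- d + stats::rnorm(length(d), 0, config$pupil_noise_sd_mm)
  }
  list(trace = data.frame(time_ms = tms, pupil_mm = d),
       transitions = do.call(rbind, trans), amplitude_mm = amp)
}

#' Simulate a 9-point calibration fixation set
#'
#' Gaze errors are isotropic bivariate normal with the per-axis SD chosen
#' so that the expected mean unsigned 2-D error equals the run's latent
#' \code{fixation_error_deg} (mean Rayleigh distance = sigma*sqrt(pi/2)).
#'
#' @param run_params latent vector for the run
#' @param noise logical
#' @return data.frame(target_x, target_y, gaze_x, gaze_y) for 9 grid points
#' @export
simulate_calibration <- function(run_params, noise = TRUE) {
  g <- expand.grid(target_x = c(-5, 0, 5), target_y = c(-5, 0, 5))
  sig <- run_params[["fixation_error_deg"]] / sqrt(pi / 2)
  e <- if (noise) matrix(stats::rnorm(18, 0, sig), 9, 2) else matrix(0, 9, 2)
  g$gaze_x <- g$target_x + e[, 1]
  g$gaze_y <- g$target_y + e[, 2]
  g
}

#' Simulate a full cohort of tracking runs
#'
#' @param n_subjects number of subjects (default 17; 10 left-eye dominant)
#' @param conditions subset of c("left", "right", "binocular")
#' @param n_trials trials per run (default 90)
#' @param seed master seed; the dataset is a pure function of it
#' @param population population table (see \code{population_defaults})
#' @param config generator configuration
#' @param condition_effects,session_jitter passed to
#'   \code{sample_subject_params}
#' @return CohortDataset: list(subjects, runs, seed); each run holds the
#'   condition, tested eye, stimulus schedule, per-trial traces + ground
#'   truth, a pupil recording, and a calibration set
#' @export
simulate_cohort <- function(n_subjects = 17,
                            conditions = c("left", "right", "binocular"),
                            n_trials = 90, seed = 1,
                            population = population_defaults(),
                            config = cohort_config_defaults(),
                            condition_effects = 1, session_jitter = 1) {
  stopifnot(all(conditions %in% c("left", "right", "binocular")),
            n_subjects >= 1)
  set.seed(seed)
  n_left <- round(n_subjects * 10 / 17)
  dominance <- rep(c("L", "R"), c(n_left, n_subjects - n_left))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sample_subject_params(population, dominance[i], i,
                          condition_effects, session_jitter)
  })
  runs <- list()
  for (sub in subjects) {
    for (cond in conditions) {
      rp <- sub$conditions[[cond]]
      sched <- sample_stimulus_schedule(n_trials, seed = NULL, config)
      trials <- lapply(seq_len(n_trials), function(k) {
        simulate_trial(rp, sched[k, ], config)
      })
      pupil <- simulate_pupil_cycle(
        rp, if (cond == "binocular") "binocular" else "monocular", config)
      calib <- simulate_calibration(rp)
      eye <- switch(cond, left = "L", right = "R", binocular = "L")
      runs[[paste(sub$subject_id, cond, sep = "_")]] <-
        list(subject_id = sub$subject_id, condition = cond, eye = eye,
             dominant_eye = sub$dominant_eye, params = rp,
             schedule = sched, trials = trials, pupil = pupil,
             calibration = calib)
    }
  }
  list(subjects = subjects, runs = runs, seed = seed)
}

#' Simulate a cohort at the metric level (no traces)
#'
#' Draws the per-run latent oculometric values directly (subject base +
#' condition effects + run jitter) and returns them as per-condition
#' subject-by-metric tables — the same shape \code{extract_cohort}
#' produces from traces. This is the fast path for power/size experiments
#' over many replicate cohorts, where simulating and re-extracting every
#' gaze trace would add nothing but the (already calibrated) run-level
#' measurement variability.
#'
#' @inheritParams simulate_cohort
#' @return list of data.frames (left, right, binocular), one row per
#'   subject, columns = 18 metrics plus subject_id and dominant_eye
#' @export
simulate_metric_cohort <- function(n_subjects = 17, seed = 1,
                                   population = population_defaults(),
                                   condition_effects = 1,
                                   session_jitter = 1) {
  set.seed(seed)
  n_left <- round(n_subjects * 10 / 17)
  dominance <- rep(c("L", "R"), c(n_left, n_subjects - n_left))
  subs <- lapply(seq_len(n_subjects), function(i) {
    sample_subject_params(population, dominance[i], i,
                          condition_effects, session_jitter)
  })
  mk <- function(cond) {
    tab <- as.data.frame(do.call(rbind, lapply(subs, function(s) {
      s$conditions[[cond]]
    })))
    tab$subject_id <- vapply(subs, `[[`, integer(1), "subject_id")
    tab$dominant_eye <- vapply(subs, `[[`, character(1), "dominant_eye")
    tab
  }
  list(left = mk("left"), right = mk("right"), binocular = mk("binocular"))
}

#' Average left- and right-eye metric tables into a "cyclopean" table
#'
#' @param left,right per-subject metric tables (aligned rows)
#' @return table of per-subject means of the two monocular runs
#' @export
cyclopean_average <- function(left, right) {
  num <- intersect(names(METRIC_BETTER_SIGN), names(left))
  out <- left
  for (m in num) out[[m]] <- (left[[m]] + right[[m]]) / 2
  out
}
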