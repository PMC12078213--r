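# Run-level aggregation: 18-oculometric profile for one (subject,
# condition) run, plus the direction/speed estimators it delegates to.

#' The 18 oculometric field names
#'
#' Canonical column order of the per-run metric profile.
#' @export
OCULOMETRIC_NAMES <- c(
  "latency_ms", "accel_deg_s2", "gain", "direction_noise_deg",
  "speed_noise_pct", "direction_anisotropy", "direction_asymmetry",
  "speed_responsiveness", "saccade_rate_hz", "saccade_amplitude_deg",
  "saccade_dispersion_deg", "proportion_smooth", "contraction_tau_ms",
  "dilation_tau_ms", "pupil_diameter_mm", "ms_slope_hz",
  "ms_intercept_deg_s", "fixation_error_deg")

#' Fit the non-linear direction-estimation distortion
#'
#' Models the direction error eps(theta) = response - target (radians) as
#' \code{c + a4 sin(4 theta + phi4) + a2 sin(2 theta + phi2)} via its
#' linearized Fourier form. Direction anisotropy is the four-fold
#' local-gain modulation depth 4*a4 (positive = direction differences
#' expanded around the cardinals); direction asymmetry is the signed
#' two-fold depth 2*a2 (positive = compression toward horizontal).
#' Cosine-phase components are absorbed into the residual.
#'
#' @param target_dirs,eye_dirs trial-wise target and response directions
#'   (deg)
#' @return list(anisotropy, asymmetry, bias_deg, residual_sd_deg,
#'   residual_deg, flagged)
#' @export
fit_direction_distortion <- function(target_dirs, eye_dirs) {
  ok <- is.finite(target_dirs) & is.finite(eye_dirs)
  th <- deg2rad(target_dirs[ok])
  eps <- deg2rad(ang_diff(eye_dirs[ok], target_dirs[ok]))
  oct <- floor(wrap360(target_dirs[ok]) / 45)
  flagged <- length(unique(oct)) < 8
  if (sum(ok) < 8) {
    return(list(anisotropy = NA, asymmetry = NA, bias_deg = NA,
                residual_sd_deg = NA, residual_deg = rep(NA, length(ok)),
                flagged = TRUE))
  }
  X <- cbind(1, sin(4 * th), cos(4 * th), sin(2 * th), cos(2 * th))
  co <- stats::coef(stats::lm.fit(X, eps))
  res <- eps - X %*% co
  out_res <- rep(NA_real_, length(ok))
  out_res[ok] <- rad2deg(res)
  list(anisotropy = unname(4 * co[2]),
       asymmetry = unname(-2 * co[4]),
       bias_deg = rad2deg(unname(co[1])),
       residual_sd_deg = stats::sd(rad2deg(res)),
       residual_deg = out_res, flagged = flagged)
}

#' Local direction noise
#'
#' Standard deviation of the pursuit direction residuals (after removing
#' the fitted distortion curve) within sliding direction windows
#' (+/- \code{window_deg}), bias-corrected (c4) and averaged over window
#' centers on the 4-degree grid.
#'
#' @inheritParams fit_direction_distortion
#' @param window_deg half-width of the local window (default 16)
#' @return mean local SD (deg), NA if no window has >= 3 trials
#' @export
direction_noise <- function(target_dirs, eye_dirs, window_deg = 16) {
  fit <- fit_direction_distortion(target_dirs, eye_dirs)
  res <- fit$residual_deg
  ok <- is.finite(res)
  if (sum(ok) < 3) return(NA_real_)
  centers <- seq(0, 356, by = 4)
  sds <- vapply(centers, function(cc) {
    w <- ok & abs(ang_diff(target_dirs, cc)) <= window_deg
    if (sum(w) < 3) return(NA_real_)
    stats::sd(res[w]) / c4_factor(sum(w))
  }, numeric(1))
  if (all(is.na(sds))) return(NA_real_)
  mean(sds, na.rm = TRUE)
}

#' Weber fraction for speed
#'
#' Mean over target speeds of 100 * SD(eye speed | target speed) / target
#' speed (plain sample SD; with ~18 trials per speed in a 90-trial run the
#' small-sample bias is under 1.5 percent).
#'
#' @param steady_speeds per-trial projected steady-state eye speeds
#' @param target_speeds matching target speeds
#' @param min_per_speed,min_speeds grouping requirements
#' @return percent Weber fraction, NA when coverage is insufficient
#' @export
speed_noise_weber <- function(steady_speeds, target_speeds,
                              min_per_speed = 2, min_speeds = 3) {
  ok <- is.finite(steady_speeds) & is.finite(target_speeds)
  sp <- split(steady_speeds[ok], target_speeds[ok])
  sp <- sp[vapply(sp, length, integer(1)) >= min_per_speed]
  if (length(sp) < min_speeds) return(NA_real_)
  mean(vapply(names(sp), function(s) {
    100 * stats::sd(sp[[s]]) / as.numeric(s)
  }, numeric(1)))
}

#' Speed responsiveness
#'
#' OLS slope of projected steady-state eye speed against target speed.
#'
#' @inheritParams speed_noise_weber
#' @return slope (unitless), NA with fewer than 3 distinct target speeds
#' @export
speed_responsiveness <- function(steady_speeds, target_speeds) {
  ok <- is.finite(steady_speeds) & is.finite(target_speeds)
  if (length(unique(target_speeds[ok])) < 3) return(NA_real_)
  unname(stats::coef(stats::lm.fit(cbind(1, target_speeds[ok]),
                                   steady_speeds[ok]))[2])
}

#' Aggregate per-trial features into the 18-oculometric profile
#'
#' Latency and acceleration are medians across valid trials; gain is the
#' mean speed ratio; the direction and speed metrics use the estimators
#' above on trial-wise initial directions and steady speeds; saccade rate
#' divides the total steady-state saccade count by the total steady-state
#' time; amplitude and dispersion use forward catch-up saccades only;
#' proportion smooth is the mean saccade-free fraction of the steady
#' window; the main-sequence fit pools saccades across trials; pupil and
#' calibration metrics come from their dedicated fits.
#'
#' @param features list of TrialFeatures (from
#'   \code{extract_trial_features})
#' @param pupil_fit optional PupilStepFit list
#' @param calibration optional calibration data.frame
#' @param min_trials minimum valid trials before flagging (default 30)
#' @return OculometricSet: named list of the 18 metrics plus
#'   \code{flagged} and \code{n_trials}
#' @export
aggregate_condition <- function(features, pupil_fit = NULL,
                                calibration = NULL, min_trials = 30) {
  lat <- vapply(features, function(f) {
    if (isTRUE(f$latency_valid)) f$latency_ms else NA_real_
  }, numeric(1))
  acc <- vapply(features, function(f) f$open_loop_accel_deg_s2 %||% NA,
                numeric(1))
  vss <- vapply(features, function(f) f$steady_speed_deg_s %||% NA,
                numeric(1))
  tsp <- vapply(features, function(f) f$target_speed, numeric(1))
  tdir <- vapply(features, function(f) f$target_direction, numeric(1))
  idir <- vapply(features, function(f) f$initial_direction_deg %||% NA,
                 numeric(1))
  psm <- vapply(features, function(f) f$proportion_smooth %||% NA,
                numeric(1))
  n_valid <- sum(is.finite(lat) & is.finite(vss))
  flagged <- n_valid < min_trials

  dfit <- fit_direction_distortion(tdir, idir)
  all_sacc <- do.call(rbind, lapply(features, `[[`, "saccades"))
  ss_sacc <- do.call(rbind, lapply(features, `[[`, "steady_saccades"))
  total_ss_time_s <- sum(vapply(features, function(f) {
    if (isTRUE(f$steady_valid)) diff(f$steady_window_ms) / 1000 else 0
  }, numeric(1)))
  if (is.null(ss_sacc)) ss_sacc <- data.frame()
  fwd <- if (nrow(ss_sacc)) {
    ss_sacc[ss_sacc$is_forward_catchup %in% TRUE, , drop = FALSE]
  } else ss_sacc
  # direction of each forward catch-up saccade relative to its target
  disp <- NA_real_
  if (nrow(fwd) >= 3 && !is.null(fwd$target_dir)) {
    rel <- ang_diff(fwd$direction_deg, fwd$target_dir)
    disp <- stats::sd(rel)
  }
  ms <- main_sequence_fit(all_sacc)

  out <- list(
    latency_ms = stats::median(lat, na.rm = TRUE),
    accel_deg_s2 = stats::median(acc, na.rm = TRUE),
    gain = mean(vss / tsp, na.rm = TRUE),
    direction_noise_deg = direction_noise(tdir, idir),
    speed_noise_pct = speed_noise_weber(vss, tsp),
    direction_anisotropy = dfit$anisotropy,
    direction_asymmetry = dfit$asymmetry,
    speed_responsiveness = speed_responsiveness(vss, tsp),
    saccade_rate_hz = if (total_ss_time_s > 0)
      nrow(ss_sacc) / total_ss_time_s else NA_real_,
    saccade_amplitude_deg = if (nrow(fwd)) mean(fwd$amplitude_deg)
      else NA_real_,
    saccade_dispersion_deg = disp,
    proportion_smooth = mean(psm, na.rm = TRUE),
    contraction_tau_ms = pupil_fit$contraction_tau_ms %||% NA_real_,
    dilation_tau_ms = pupil_fit$dilation_tau_ms %||% NA_real_,
    pupil_diameter_mm = pupil_fit$mean_diameter_mm %||% NA_real_,
    ms_slope_hz = ms$slope_hz,
    ms_intercept_deg_s = ms$intercept_deg_s,
    fixation_error_deg = if (!is.null(calibration))
      fixation_error(calibration)$error_deg else NA_real_)
  out$flagged <- flagged
  out$n_trials <- n_valid
  out
}

#' Extract the oculometric profile from one simulated run
#'
#' @param run one element of \code{simulate_cohort()$runs}
#' @return list(metrics = OculometricSet, features = per-trial features)
#' @export
extract_run <- function(run) {
  features <- lapply(seq_along(run$trials), function(k) {
    f <- extract_trial_features(run$trials[[k]]$trace, run$schedule[k, ])
    if (nrow(f$steady_saccades)) {
      f$steady_saccades$target_dir <- run$schedule$ramp_direction_deg[k]
    } else {
      f$steady_saccades$target_dir <- numeric(0)
    }
    f
  })
  pupil_fit <- fit_pupil_step(run$pupil$trace$time_ms,
                              run$pupil$trace$pupil_mm,
                              run$pupil$transitions)
  list(metrics = aggregate_condition(features, pupil_fit,
                                     run$calibration),
       features = features)
}

#' Extract per-subject metric tables for a whole cohort
#'
#' @param cohort CohortDataset from \code{simulate_cohort} (or
#'   \code{read_cohort})
#' @param keep_features keep per-trial features per run (memory-heavy)
#' @return list of per-condition data.frames (one row per subject, columns
#'   = 18 metrics), plus \code{features} when requested
#' @export
extract_cohort <- function(cohort, keep_features = FALSE) {
  conds <- unique(vapply(cohort$runs, `[[`, character(1), "condition"))
  tabs <- list()
  feats <- list()
  for (cond in conds) {
    rows <- list()
    for (rn in names(cohort$runs)) {
      run <- cohort$runs[[rn]]
      if (run$condition != cond) next
      ex <- extract_run(run)
      m <- ex$metrics[OCULOMETRIC_NAMES]
      row <- as.data.frame(m)
      row$subject_id <- run$subject_id
      row$dominant_eye <- run$dominant_eye
      rows[[length(rows) + 1]] <- row
      if (keep_features) feats[[rn]] <- ex$features
    }
    tabs[[cond]] <- do.call(rbind, rows)
  }
  if (keep_features) tabs$features <- feats
  tabs
}
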