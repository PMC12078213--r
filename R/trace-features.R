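# Per-trial kinematic feature extraction from gaze/pupil traces.
#
# Velocity is obtained by central differencing followed by a zero-phase
# windowed-sinc low-pass (25 Hz for smooth-pursuit analysis). Saccades are
# detected on the residual speed after subtracting a running-median pursuit
# estimate; their peak velocity is measured on lightly-processed
# first-difference velocity and corrected for the concurrent pursuit.
# Pursuit onset is a hinge (flat-then-rising) least-squares fit on the
# radial velocity.

#' Zero-phase FIR low-pass filter
#'
#' Hamming-windowed sinc kernel; symmetric, hence zero group delay. Edges
#' are handled by replicate padding.
#'
#' @param x signal
#' @param fs_hz sampling rate
#' @param cutoff_hz -6 dB cutoff
#' @param n_taps kernel length (odd; default 21)
#' @return filtered signal, same length
#' @export
lowpass_fir <- function(x, fs_hz, cutoff_hz, n_taps = 21) {
  stopifnot(n_taps %% 2 == 1)
  h <- fir_kernel(fs_hz, cutoff_hz, n_taps)
  half <- (n_taps - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, h, sides = 2))[(half + 1):(half + length(x))]
}

#' Windowed-sinc FIR kernel
#' @inheritParams lowpass_fir
#' @return normalized kernel coefficients
#' @export
fir_kernel <- function(fs_hz, cutoff_hz, n_taps = 21) {
  m <- n_taps - 1
  k <- 0:m - m / 2
  fc <- cutoff_hz / fs_hz
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h <- h * (0.54 - 0.46 * cos(2 * pi * (0:m) / m))
  h / sum(h)
}

#' Frequency response magnitude of the FIR kernel
#' @param h kernel
#' @param f_hz frequency (Hz)
#' @param fs_hz sampling rate
#' @return gain at \code{f_hz}
#' @export
fir_gain <- function(h, f_hz, fs_hz) {
  k <- seq_along(h) - 1
  abs(sum(h * exp(-2i * pi * f_hz / fs_hz * k)))
}

#' Differentiate a gaze trace
#'
#' Central-difference velocity, optionally low-passed with the zero-phase
#' FIR filter. Samples flagged invalid propagate as NA.
#'
#' @param trace data.frame with \code{time_ms, x_deg, y_deg, valid}
#' @param cutoff_hz low-pass cutoff; NULL for raw central differences
#' @return data.frame(time_ms, vx, vy) in deg/s
#' @export
differentiate <- function(trace, cutoff_hz = 25) {
  t_s <- trace$time_ms / 1000
  n <- nrow(trace)
  if (n < 3) stop("trace too short")
  dt <- stats::median(diff(t_s))
  if (sum(trace$valid, na.rm = TRUE) * dt * 1000 < 50) {
    stop("fewer than 50 ms of valid samples: trial rejected")
  }
  cd <- function(x) {
    v <- c(NA, (x[3:n] - x[1:(n - 2)]) / (2 * dt), NA)
    v[1] <- (x[2] - x[1]) / dt
    v[n] <- (x[n] - x[n - 1]) / dt
    v
  }
  vx <- cd(trace$x_deg); vy <- cd(trace$y_deg)
  if (!is.null(cutoff_hz)) {
    fs <- 1 / dt
    vx <- lowpass_fir(vx, fs, cutoff_hz)
    vy <- lowpass_fir(vy, fs, cutoff_hz)
  }
  bad <- !as.logical(trace$valid)
  vx[bad] <- NA; vy[bad] <- NA
  data.frame(time_ms = trace$time_ms, vx = vx, vy = vy)
}

running_median <- function(x, k) {
  # odd-width running median with edge replication
  if (k %% 2 == 0) k <- k + 1
  n <- length(x)
  half <- (k - 1) / 2
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::runmed(xp, k)[(half + 1):(half + n)]
}

#' Detect saccades on a velocity trace
#'
#' Events are runs where the residual speed (velocity minus a running-median
#' pursuit estimate) exceeds \code{threshold} for at least \code{min_dur_ms};
#' events closer than \code{merge_gap_ms} are merged, and boundaries are
#' padded by \code{pad_ms}. Peak velocity is measured on first-difference
#' velocity with quadratic interpolation around the maximum, and corrected
#' by subtracting the projection of the interpolated smooth (pursuit)
#' velocity onto the saccade direction. \code{corrected_amplitude_deg}
#' removes the pursuit displacement accumulated over the event.
#'
#' @param trace gaze trace (positions; used for amplitudes)
#' @param vel velocity data.frame from \code{differentiate} (detection runs
#'   on this; default re-computed at 40 Hz cutoff)
#' @param threshold residual speed threshold (deg/s)
#' @param min_dur_ms minimum supra-threshold duration
#' @param merge_gap_ms merge events with shorter gaps
#' @param pad_ms boundary padding
#' @param target_direction_deg optional target motion direction used to
#'   label forward catch-up saccades (within +/-90 deg)
#' @return data.frame of SaccadeEvent rows (possibly empty)
#' @export
detect_saccades <- function(trace, vel = NULL, threshold = 30,
                            min_dur_ms = 8, merge_gap_ms = 20, pad_ms = 8,
                            target_direction_deg = NA) {
  if (is.null(vel)) vel <- differentiate(trace, cutoff_hz = NULL)
  tms <- vel$time_ms
  n <- length(tms)
  dt_ms <- stats::median(diff(tms))
  k <- max(3, round(120 / dt_ms))
  px <- running_median(ifelse(is.na(vel$vx), 0, vel$vx), k)
  py <- running_median(ifelse(is.na(vel$vy), 0, vel$vy), k)
  res <- sqrt((vel$vx - px)^2 + (vel$vy - py)^2)
  over <- !is.na(res) & res > threshold

  empty <- data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      start_x = numeric(), start_y = numeric(),
                      end_x = numeric(), end_y = numeric(),
                      amplitude_deg = numeric(),
                      corrected_amplitude_deg = numeric(),
                      direction_deg = numeric(),
                      peak_velocity_deg_s = numeric(),
                      pursuit_corrected_peak_deg_s = numeric(),
                      is_forward_catchup = logical())
  if (!any(over)) return(empty)

  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- cbind(starts[r$values], ends[r$values])
  # merge events separated by short gaps
  if (nrow(ev) > 1) {
    keep <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if ((tms[ev[i, 1]] - tms[last[2]]) < merge_gap_ms) {
        keep[[length(keep)]] <- c(last[1], ev[i, 2])
      } else keep[[length(keep) + 1]] <- ev[i, ]
    }
    ev <- do.call(rbind, keep)
  }
  # drop events shorter than min duration (pre-padding); each
  # supra-threshold sample accounts for one sample period
  dur <- (ev[, 2] - ev[, 1] + 1) * dt_ms
  ev <- ev[dur >= min_dur_ms, , drop = FALSE]
  if (nrow(ev) == 0) return(empty)

  pad_n <- round(pad_ms / dt_ms)
  # raw first-difference speed for peak measurement
  dtv <- diff(tms) / 1000
  fdx <- c(diff(trace$x_deg) / dtv, NA)
  fdy <- c(diff(trace$y_deg) / dtv, NA)
  fspd <- sqrt(fdx^2 + fdy^2)

  out <- lapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1, ev[i, 1] - pad_n)
    i1 <- min(n, ev[i, 2] + pad_n)
    sx <- trace$x_deg[i0]; sy <- trace$y_deg[i0]
    ex <- trace$x_deg[i1]; ey <- trace$y_deg[i1]
    amp <- sqrt((ex - sx)^2 + (ey - sy)^2)
    dir <- wrap360(rad2deg(atan2(ey - sy, ex - sx)))
    # smooth velocity interpolated across the event (pre/post medians)
    pre <- max(1, i0 - 5):max(1, i0 - 1)
    post <- min(n, i1 + 1):min(n, i1 + 5)
    smx <- mean(c(px[pre], px[post])); smy <- mean(c(py[pre], py[post]))
    # pursuit displacement removed from the amplitude
    dur_s <- (tms[i1] - tms[i0]) / 1000
    cx <- (ex - sx) - smx * dur_s
    cy <- (ey - sy) - smy * dur_s
    camp <- sqrt(cx^2 + cy^2)
    cdir <- wrap360(rad2deg(atan2(cy, cx)))
    seg <- i0:min(i1, n - 1)
    pk_i <- seg[which.max(fspd[seg])]
    pk <- fspd[pk_i]
    if (pk_i > i0 && pk_i < min(i1, n - 1)) {
      y3 <- fspd[(pk_i - 1):(pk_i + 1)]
      if (all(is.finite(y3))) {
        denom <- y3[1] - 2 * y3[2] + y3[3]
        if (denom < 0) pk <- y3[2] - (y3[3] - y3[1])^2 / (8 * denom)
      }
    }
    proj <- smx * cos(deg2rad(cdir)) + smy * sin(deg2rad(cdir))
    data.frame(onset_ms = tms[i0], offset_ms = tms[i1],
               start_x = sx, start_y = sy, end_x = ex, end_y = ey,
               amplitude_deg = amp, corrected_amplitude_deg = camp,
               direction_deg = cdir,
               peak_velocity_deg_s = pk,
               pursuit_corrected_peak_deg_s = pk - proj,
               is_forward_catchup = if (is.na(target_direction_deg)) NA else
                 abs(ang_diff(cdir, target_direction_deg)) <= 90)
  })
  do.call(rbind, out)
}

#' Replace saccadic intervals with interpolated smooth velocity
#'
#' Saccade intervals (already padded by the detector) are linearly
#' interpolated in velocity space, per component.
#'
#' @param vel velocity data.frame
#' @param saccades events from \code{detect_saccades}
#' @return velocity data.frame with saccadic samples replaced
#' @export
desaccade_velocity <- function(vel, saccades) {
  if (is.null(saccades) || nrow(saccades) == 0) return(vel)
  tms <- vel$time_ms
  n <- length(tms)
  for (i in seq_len(nrow(saccades))) {
    i0 <- findInterval(saccades$onset_ms[i], tms)
    i1 <- findInterval(saccades$offset_ms[i], tms)
    i0 <- max(1, i0); i1 <- min(n, i1)
    a <- max(1, i0 - 1); b <- min(n, i1 + 1)
    for (comp in c("vx", "vy")) {
      v0 <- vel[[comp]][a]; v1 <- vel[[comp]][b]
      if (!is.finite(v0)) v0 <- v1
      if (!is.finite(v1)) v1 <- v0
      w <- seq(0, 1, length.out = i1 - i0 + 3)[2:(i1 - i0 + 2)]
      vel[[comp]][i0:i1] <- v0 + (v1 - v0) * w
    }
  }
  vel
}

#' Estimate pursuit onset latency by hinge regression
#'
#' Fits a flat-baseline-then-rising two-piece model to the radial smooth
#' velocity: \code{v(t) = base + m * max(t - c, 0)}, with the baseline
#' level fixed at the pre-onset mean. Candidate breakpoints c are scanned
#' on the sample grid over \code{search_window_ms}; for each, the rising
#' slope is fit by least squares and the squared error is accumulated over
#' one fixed evaluation window (baseline start to \code{eval_end_ms}) so
#' that candidates are compared on identical data. The latency is the
#' breakpoint minimizing that error; trials whose best slope falls below
#' \code{min_slope_deg_s2} are flagged invalid.
#'
#' @param vr radial (target-projected) smooth velocity, deg/s
#' @param time_ms sample times (motion onset at 0)
#' @param search_window_ms candidate latency range (default c(80, 300))
#' @param eval_end_ms end of the common evaluation window (default 380,
#'   chosen to precede steady state for plausible latencies)
#' @param min_slope_deg_s2 slope floor below which the trial is flagged
#' @return list(latency_ms, slope_deg_s2, valid)
#' @export
estimate_pursuit_onset <- function(vr, time_ms,
                                   search_window_ms = c(80, 300),
                                   eval_end_ms = 380,
                                   min_slope_deg_s2 = 20) {
  ok <- is.finite(vr)
  base <- mean(vr[ok & time_ms < 0])
  if (!is.finite(base)) base <- 0
  cand <- which(time_ms >= search_window_ms[1] &
                  time_ms <= search_window_ms[2])
  if (length(cand) < 3) {
    return(list(latency_ms = NA, slope_deg_s2 = NA, valid = FALSE))
  }
  t_s <- time_ms / 1000
  scan_lat <- scan_slope <- scan_mse <- scan_n <- numeric(0)
  for (ci in cand) {
    # per-candidate evaluation window [-100, c + 100] ms; mean squared
    # error makes candidates with different window lengths comparable
    ev <- which(time_ms >= -100 &
                  time_ms <= min(time_ms[ci] + 100, eval_end_ms) & ok)
    if (length(ev) < 10) next
    y <- vr[ev] - base
    x <- pmax(t_s[ev] - t_s[ci], 0)
    sxx <- sum(x^2)
    if (sxx == 0) next
    m <- sum(y * x) / sxx
    scan_lat <- c(scan_lat, time_ms[ci])
    scan_slope <- c(scan_slope, m)
    scan_mse <- c(scan_mse, mean((y - m * x)^2))
    scan_n <- c(scan_n, length(ev))
  }
  keep <- scan_slope >= min_slope_deg_s2
  if (!any(keep)) {
    return(list(latency_ms = NA, slope_deg_s2 = NA, valid = FALSE))
  }
  # one-SE elbow rule: before the true onset the MSE surface is flat at
  # the noise floor (early candidates fit noise equally well) and rises
  # steeply afterwards; take the latest candidate statistically
  # indistinguishable from the minimum
  i_min <- which(keep)[which.min(scan_mse[keep])]
  thr <- scan_mse[i_min] * (1 + 0.5 * sqrt(2 / scan_n[i_min]))
  i_best <- max(which(keep & scan_mse <= thr))
  best <- list(lat = scan_lat[i_best], slope = scan_slope[i_best])
  lat <- best$lat
  # refinement: the hinge break under noise sits slightly early (late
  # breaks are penalized by the full rise amplitude, early ones only by
  # chord curvature). Back-extrapolate a free line fit on the clean rise
  # to its baseline crossing.
  ri <- which(time_ms >= lat + 12 & time_ms <= lat + 100 & ok)
  if (length(ri) >= 5) {
    co <- stats::coef(stats::lm.fit(cbind(1, t_s[ri]), vr[ri]))
    if (is.finite(co[2]) && co[2] > min_slope_deg_s2) {
      cross <- (base - co[1]) / co[2] * 1000
      if (abs(cross - lat) <= 40) {
        lat <- cross
        best$slope <- unname(co[2])
      }
    }
  }
  list(latency_ms = lat, slope_deg_s2 = best$slope, valid = TRUE)
}

#' Open-loop acceleration
#'
#' Least-squares slope of the radial smooth speed over the first 100 ms of
#' pursuit.
#'
#' @param vr radial smooth velocity (deg/s)
#' @param time_ms sample times
#' @param latency_ms pursuit onset
#' @param window_ms open-loop duration (default 100)
#' @return acceleration (deg/s^2) or NA when the window leaves the trace
#' @export
open_loop_acceleration <- function(vr, time_ms, latency_ms,
                                   window_ms = 100) {
  if (!is.finite(latency_ms)) return(NA_real_)
  if (latency_ms + window_ms > max(time_ms)) return(NA_real_)
  idx <- which(time_ms >= latency_ms & time_ms <= latency_ms + window_ms &
                 is.finite(vr))
  if (length(idx) < 3) return(NA_real_)
  t_s <- time_ms[idx] / 1000
  unname(stats::coef(stats::lm.fit(cbind(1, t_s), vr[idx]))[2])
}

#' Steady-state velocity over the 400-700 ms window
#'
#' @param vel desaccaded velocity data.frame
#' @param target_direction_deg ramp direction
#' @param window_ms analysis window after motion onset (default c(400, 700))
#' @return list(speed_deg_s = projection onto the target direction,
#'   direction_deg, mean_vx, mean_vy, valid)
#' @export
steady_state_velocity <- function(vel, target_direction_deg,
                                  window_ms = c(400, 700)) {
  idx <- which(vel$time_ms >= window_ms[1] & vel$time_ms <= window_ms[2])
  ok <- idx[is.finite(vel$vx[idx]) & is.finite(vel$vy[idx])]
  if (length(ok) < 0.5 * length(idx) || length(ok) < 3) {
    return(list(speed_deg_s = NA, direction_deg = NA, mean_vx = NA,
                mean_vy = NA, valid = FALSE))
  }
  mx <- mean(vel$vx[ok]); my <- mean(vel$vy[ok])
  u <- unit_vec(target_direction_deg)
  list(speed_deg_s = mx * u[1] + my * u[2],
       direction_deg = wrap360(rad2deg(atan2(my, mx))),
       mean_vx = mx, mean_vy = my, valid = TRUE)
}

#' Fit pupil step responses
#'
#' Fits a single exponential \code{d(t) = A + (B - A) exp(-(t - t0)/tau)}
#' to each light transition segment by nonlinear least squares (asymptote
#' A free, starting level B anchored at the transition). Contraction tau is
#' averaged over light-on steps, dilation tau over light-off steps.
#' Transitions whose fit fails or whose tau falls outside [20, 10000] ms
#' are dropped; if all transitions of a type drop, that time constant is NA
#' (missing-data case).
#'
#' @param time_ms,pupil_mm pupil recording
#' @param transitions data.frame(time_ms, type) with type "on"/"off"
#' @return PupilStepFit list: contraction_tau_ms, dilation_tau_ms,
#'   mean_diameter_mm, n_on, n_off, residual_rms
#' @export
fit_pupil_step <- function(time_ms, pupil_mm, transitions) {
  stopifnot(nrow(transitions) >= 2)
  taus <- list(on = numeric(), off = numeric())
  resid <- numeric()
  tr_t <- transitions$time_ms
  for (i in seq_len(nrow(transitions))) {
    t0 <- tr_t[i]
    t1 <- if (i < nrow(transitions)) tr_t[i + 1] else max(time_ms) + 1
    idx <- which(time_ms >= t0 & time_ms < t1)
    if (length(idx) < 20) next
    tt <- time_ms[idx] - t0
    d <- pupil_mm[idx]
    B0 <- mean(d[seq_len(5)])
    A0 <- mean(d[(length(d) - 9):length(d)])
    if (!is.finite(A0) || !is.finite(B0) || abs(A0 - B0) < 1e-6) next
    cross <- B0 + (A0 - B0) * 0.632
    ic <- if (A0 < B0) which(d <= cross)[1] else which(d >= cross)[1]
    tau0 <- if (is.na(ic)) diff(range(tt)) / 3 else max(tt[ic], 30)
    # warnOnly + suppressWarnings: on noiseless segments nls hits its
    # iteration cap at machine precision; the tau bound check below is the
    # real acceptance gate
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(d ~ A + (B - A) * exp(-tt / tau),
                   start = list(A = A0, B = B0, tau = tau0),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    tau <- stats::coef(fit)[["tau"]]
    if (!is.finite(tau) || tau < 20 || tau > 10000) next
    taus[[transitions$type[i]]] <- c(taus[[transitions$type[i]]], tau)
    resid <- c(resid, stats::resid(fit))
  }
  per <- 2 * stats::median(diff(tr_t))
  full <- which(time_ms >= tr_t[1] &
                  time_ms < tr_t[1] + floor((max(time_ms) - tr_t[1]) / per) *
                  per)
  if (length(full) < 10) full <- seq_along(time_ms)
  list(contraction_tau_ms = if (length(taus$on)) mean(taus$on) else NA_real_,
       dilation_tau_ms = if (length(taus$off)) mean(taus$off) else NA_real_,
       mean_diameter_mm = mean(pupil_mm[full]),
       n_on = length(taus$on), n_off = length(taus$off),
       residual_rms = if (length(resid)) sqrt(mean(resid^2)) else NA_real_)
}

#' Main-sequence regression
#'
#' Ordinary least squares of pursuit-corrected peak velocity against
#' pursuit-corrected amplitude across a pool of saccades.
#'
#' @param saccades data.frame of SaccadeEvent rows
#' @param min_n minimum saccade count for a confident fit (default 10)
#' @return list(slope_hz, intercept_deg_s, n, low_confidence)
#' @export
main_sequence_fit <- function(saccades, min_n = 10) {
  if (is.null(saccades) || nrow(saccades) == 0) {
    return(list(slope_hz = NA_real_, intercept_deg_s = NA_real_,
                n = 0L, low_confidence = TRUE))
  }
  ok <- is.finite(saccades$corrected_amplitude_deg) &
    is.finite(saccades$pursuit_corrected_peak_deg_s)
  a <- saccades$corrected_amplitude_deg[ok]
  v <- saccades$pursuit_corrected_peak_deg_s[ok]
  if (length(a) < 2 || stats::sd(a) == 0) {
    return(list(slope_hz = NA_real_, intercept_deg_s = NA_real_,
                n = length(a), low_confidence = TRUE))
  }
  co <- stats::coef(stats::lm.fit(cbind(1, a), v))
  list(slope_hz = unname(co[2]), intercept_deg_s = unname(co[1]),
       n = length(a), low_confidence = length(a) < min_n)
}

#' Mean fixation error over the calibration grid
#'
#' @param calibration data.frame(target_x, target_y, gaze_x, gaze_y)
#' @return list(error_deg = mean Euclidean error, n, flagged)
#' @export
fixation_error <- function(calibration) {
  d <- sqrt((calibration$gaze_x - calibration$target_x)^2 +
              (calibration$gaze_y - calibration$target_y)^2)
  d <- d[is.finite(d)]
  list(error_deg = mean(d), n = length(d), flagged = length(d) < 6)
}

#' Extract per-trial features from one trial
#'
#' Runs the full per-trial chain: velocity estimation, saccade detection,
#' desaccading, onset/acceleration/steady-state measurement, and the
#' saccade bookkeeping needed by the run-level aggregation.
#'
#' @param trace gaze trace
#' @param stim StepRampStimulus row
#' @param steady_window_ms steady-state window (default c(400, 700))
#' @return TrialFeatures list
#' @export
extract_trial_features <- function(trace, stim,
                                   steady_window_ms = c(400, 700)) {
  # detection runs on unsmoothed central-difference velocity: at 250 Hz a
  # small catch-up saccade only spans 3-5 samples and a 40 Hz zero-phase
  # filter already pushes its residual peak below threshold
  vraw <- differentiate(trace, cutoff_hz = NULL)
  sacc <- detect_saccades(trace, vraw,
                          target_direction_deg = stim$ramp_direction_deg)
  # desaccade the raw velocity first, then low-pass: filtering before
  # removal would smear saccade energy past the interpolation anchors and
  # leak saccadic displacement into the smooth velocity
  vdes <- desaccade_velocity(vraw, sacc)
  fs <- 1000 / stats::median(diff(trace$time_ms))
  vsm <- data.frame(time_ms = vdes$time_ms,
                    vx = lowpass_fir(vdes$vx, fs, 25),
                    vy = lowpass_fir(vdes$vy, fs, 25))
  u <- unit_vec(stim$ramp_direction_deg)
  vr <- vsm$vx * u[1] + vsm$vy * u[2]
  # onset detection runs on unsmoothed desaccaded velocity: any zero-phase
  # low-pass rounds the pursuit-onset corner and biases the hinge fit
  # early, while the hinge regression itself averages out white noise
  vr_on <- vdes$vx * u[1] + vdes$vy * u[2]
  on <- estimate_pursuit_onset(vr_on, vsm$time_ms)
  accel <- open_loop_acceleration(vr, vsm$time_ms, on$latency_ms)
  # initial pursuit direction: mean desaccaded velocity over the first
  # 160 ms of pursuit
  init_dir <- NA_real_
  if (on$valid) {
    idx <- which(vsm$time_ms >= on$latency_ms &
                   vsm$time_ms <= on$latency_ms + 160)
    if (length(idx) >= 3) {
      init_dir <- wrap360(rad2deg(atan2(mean(vsm$vy[idx], na.rm = TRUE),
                                        mean(vsm$vx[idx], na.rm = TRUE))))
    }
  }
  ss <- steady_state_velocity(vsm, stim$ramp_direction_deg,
                              steady_window_ms)
  # steady-state saccades and smooth fraction
  win <- steady_window_ms
  in_ss <- sacc[sacc$offset_ms > win[1] & sacc$onset_ms < win[2], ,
                drop = FALSE]
  occ <- 0
  if (nrow(in_ss)) {
    iv <- cbind(pmax(in_ss$onset_ms, win[1]), pmin(in_ss$offset_ms, win[2]))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    last_end <- -Inf
    for (j in seq_len(nrow(iv))) {
      s <- max(iv[j, 1], last_end); e <- iv[j, 2]
      if (e > s) occ <- occ + (e - s)
      last_end <- max(last_end, e)
    }
  }
  list(latency_ms = on$latency_ms, latency_valid = on$valid,
       open_loop_accel_deg_s2 = accel,
       initial_direction_deg = init_dir,
       steady_speed_deg_s = ss$speed_deg_s,
       steady_direction_deg = ss$direction_deg,
       steady_valid = ss$valid,
       saccades = sacc, steady_saccades = in_ss,
       steady_saccade_time_ms = occ,
       steady_window_ms = win,
       proportion_smooth = 1 - occ / diff(win),
       target_speed = stim$ramp_speed_deg_s,
       target_direction = stim$ramp_direction_deg)
}
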