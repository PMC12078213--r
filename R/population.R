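# Normative population table for the synthetic cohort generator.
#
# Means and between-subject SDs are the published monocular normative values
# for healthy, well-rested adults on the radial step-ramp task; the
# binocular and dominant-eye deltas are the corresponding differences of
# condition means. `session_sd` is the within-subject run-to-run SD of each
# extracted metric, calibrated so that the paired condition comparisons in a
# simulated cohort reproduce the published paired t statistics (the paired
# SD of a difference of two runs is sqrt(2) * session_sd, plus the
# between-run split of the monocular average where applicable).

#' Default population parameter table
#'
#' One row per generative parameter: monocular population mean and
#' between-subject SD, physical truncation bounds, additive condition
#' effects (binocular minus monocular; dominant minus non-dominant), and the
#' within-subject between-run SD.
#'
#' @return data.frame with columns \code{name, mean, sd, lower, upper,
#'   binocular_delta, dominant_delta, session_sd}
#' @export
population_defaults <- function() {
  tab <- rbind(
    # name                     mean    sd    lower  upper  bino_d  dom_d session
    c("latency_ms",             165,    11,    80,   400,   -13,    2,    4.7),
    c("accel_deg_s2",           117,    18,    20,   400,     7,    8,    9.6),
    c("gain",                  0.87,  0.08,  0.30,  1.20, -0.01, 0.02,   0.07),
    c("direction_noise_deg",    9.5,   2.6,   1.0,    45,  -0.7, -1.3,    1.0),
    c("speed_noise_pct",       15.6,   2.7,   2.0,    60,  -0.3, -0.7,    1.8),
    c("direction_anisotropy",  0.26,  0.11,    -1,     1,  0.09, 0.06,   0.12),
    c("direction_asymmetry",   0.05,  0.13,    -1,     1,  0.07,-0.02,   0.13),
    c("speed_responsiveness",  0.53,  0.25,  0.05,   1.5,  0.02,-0.09,   0.09),
    c("saccade_rate_hz",       3.49,  0.73,   0.2,     8, -0.43, 0.13,   0.34),
    c("saccade_amplitude_deg", 1.48,  0.48,   0.3,     5, -0.21,-0.02,   0.18),
    c("saccade_dispersion_deg",16.8,   7.1,   3.0,    60,  -0.8, -0.4,    3.0),
    c("proportion_smooth",     0.78,  0.05,  0.40,  1.00,  0.04, -0.01,  0.041),
    c("contraction_tau_ms",     178,    22,    60,   600,   -16,    8,     15),
    c("dilation_tau_ms",        924,   439,   150,  4500,  -247,  285,    150),
    c("pupil_diameter_mm",      3.4,   0.4,   1.5,   7.0,  -0.5, -0.2,    0.3),
    c("ms_slope_hz",           43.8,   8.9,    15,   100,  -4.6, -0.2,    4.7),
    c("ms_intercept_deg_s",    29.0,  10.2,     2,   100,   2.9, -1.2,    7.7),
    c("fixation_error_deg",    0.57,  0.16,  0.05,   3.0,  0.02, 0.04,    0.2))
  out <- data.frame(name = tab[, 1], stringsAsFactors = FALSE)
  num <- apply(tab[, -1], 2, as.numeric)
  colnames(num) <- c("mean", "sd", "lower", "upper", "binocular_delta",
                     "dominant_delta", "session_sd")
  cbind(out, num)
}

# truncated-normal draw (vectorized over the table)
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw latent per-subject, per-condition oculometric parameters
#'
#' Each subject gets a base latent value per parameter from a truncated
#' normal at the population mean/SD. Condition values are then
#' base + condition effect + run-level jitter:
#' the binocular run adds \code{binocular_delta}; the dominant-eye run adds
#' \code{+dominant_delta/2} and the non-dominant \code{-dominant_delta/2}
#' (so their average is the subject's base, matching the "cyclopean"
#' monocular average); every run adds independent N(0, session_sd) jitter.
#'
#' @param population table as returned by \code{population_defaults()};
#'   SDs may be zeroed for deterministic subjects
#' @param dominant_eye "L" or "R"
#' @param subject_id identifier stored with the draw
#' @param condition_effects multiplier on the delta columns (set 0 for null
#'   simulations)
#' @param session_jitter multiplier on \code{session_sd} (set 0 to make the
#'   run latents equal the subject latents)
#' @return SubjectParams: list with \code{subject_id}, \code{dominant_eye},
#'   \code{base} (named vector) and \code{conditions}, a named list of
#'   per-run latent vectors for "left", "right" and "binocular"
#' @export
sample_subject_params <- function(population = population_defaults(),
                                  dominant_eye = "R", subject_id = 1L,
                                  condition_effects = 1,
                                  session_jitter = 1) {
  stopifnot(dominant_eye %in% c("L", "R"))
  if (any(population$sd < 0) || any(population$session_sd < 0)) {
    stop("SDs must be >= 0")
  }
  p <- population
  base <- mapply(function(m, s, lo, hi) rtruncnorm1(1, m, s, lo, hi),
                 p$mean, p$sd, p$lower, p$upper)
  names(base) <- p$name
  clip <- function(x) pmin(pmax(x, p$lower), p$upper)
  jit <- function() {
    if (session_jitter == 0) rep(0, nrow(p))
    else stats::rnorm(nrow(p), 0, session_jitter * p$session_sd)
  }
  dom_half <- condition_effects * p$dominant_delta / 2
  conds <- list(
    left = clip(base + (if (dominant_eye == "L") dom_half else -dom_half) +
                  jit()),
    right = clip(base + (if (dominant_eye == "R") dom_half else -dom_half) +
                   jit()),
    binocular = clip(base + condition_effects * p$binocular_delta + jit()))
  conds <- lapply(conds, function(v) stats::setNames(v, p$name))
  list(subject_id = subject_id, dominant_eye = dominant_eye,
       base = base, conditions = conds)
}
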