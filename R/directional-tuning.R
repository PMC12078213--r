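# Directional tuning: per-direction binning of pursuit metrics in world or
# retinal coordinates, quadrant asymmetry t-tests, and the SEM-normalized
# chi-square circularity / condition-difference tests.

RETINAL_LABELS <- c("0" = "T", "90" = "S", "180" = "N", "270" = "I")
WORLD_LABELS <- c("0" = "R", "90" = "U", "180" = "L", "270" = "D")

#' Map a trial's ramp direction to a retinal locus
#'
#' Onset metrics (latency, acceleration, direction noise) are driven by the
#' stimulus at the retinal locus of the step (the eye leads the target
#' early in the trial); steady-state metrics by the locus of the ramp
#' motion (the eye lags). The visual-field position maps to the retina by
#' 180-degree optical inversion, and left-eye loci are mirrored about the
#' vertical axis so nasal/temporal align across eyes (angles are reported
#' in a right-eye-equivalent frame: 0 = temporal, 90 = superior,
#' 180 = nasal, 270 = inferior).
#'
#' @param ramp_direction_deg world ramp direction(s)
#' @param eye "L" or "R"
#' @param phase "onset" or "steady"
#' @return list(angle_deg, quadrant = N/T/S/I label of the nearest cardinal)
#' @export
map_to_retinal <- function(ramp_direction_deg, eye, phase) {
  if (!eye %in% c("L", "R")) stop("eye must be 'L' or 'R'")
  if (!phase %in% c("onset", "steady")) {
    stop("phase must be 'onset' or 'steady'")
  }
  field <- if (phase == "onset") wrap360(ramp_direction_deg + 180)
           else wrap360(ramp_direction_deg)
  ret <- wrap360(field + 180)              # optical inversion
  if (eye == "L") ret <- wrap360(180 - ret) # mirror about vertical axis
  quad <- wrap360(90 * round(ret / 90))
  list(angle_deg = ret,
       quadrant = unname(RETINAL_LABELS[as.character(quad)]))
}

#' Bin a per-trial metric by direction
#'
#' Half-open angular bins \code{[center - w, center + w)} centered on the
#' octants (0, 45, ..., 315) or quadrants (0, 90, 180, 270). Per-subject
#' bin values are aggregated with \code{agg} (median for latency and
#' acceleration, mean otherwise), then summarized across subjects as
#' mean and SEM per bin.
#'
#' @param values per-trial metric values
#' @param directions per-trial binning directions (world or retinal, deg)
#' @param subjects per-trial subject ids
#' @param n_bins 4 or 8
#' @param agg per-subject aggregator (default mean)
#' @return DirectionalBins list: centers, per_subject (matrix subjects x
#'   bins), mean, sem, n (subjects contributing per bin)
#' @export
bin_metric_by_direction <- function(values, directions, subjects,
                                    n_bins = 8, agg = mean) {
  stopifnot(n_bins %in% c(4, 8))
  centers <- seq(0, 359, by = 360 / n_bins)
  half <- 180 / n_bins
  subj <- sort(unique(subjects))
  per <- matrix(NA_real_, length(subj), length(centers),
                dimnames = list(subj, centers))
  for (si in seq_along(subj)) {
    for (bi in seq_along(centers)) {
      inbin <- subjects == subj[si] &
        ang_diff(directions, centers[bi]) >= -half &
        ang_diff(directions, centers[bi]) < half
      v <- values[inbin & is.finite(values)]
      if (length(v)) per[si, bi] <- agg(v)
    }
  }
  n <- colSums(is.finite(per))
  m <- colMeans(per, na.rm = TRUE)
  sem <- apply(per, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col) / sqrt(length(col))
  })
  list(centers = centers, per_subject = per, mean = m, sem = sem, n = n,
       flagged = any(n < length(subj)))
}

#' Quadrant asymmetry t-tests
#'
#' Paired two-tailed t-tests across subjects on opposing quadrants and on
#' the horizontal-vs-vertical average, Bonferroni-corrected for the three
#' repeated tests. In retinal coordinates the contrasts are N-T, S-I, H-V;
#' in world coordinates R-L, U-D, H-V.
#'
#' @param per_subject subjects x 4 matrix with columns at centers
#'   0, 90, 180, 270
#' @param frame "retinal" or "world"
#' @return data.frame(contrast, t, df, p_raw, p_bonferroni, n)
#' @export
quadrant_asymmetry_tests <- function(per_subject, frame = "retinal") {
  stopifnot(ncol(per_subject) == 4, frame %in% c("retinal", "world"))
  lab <- if (frame == "retinal") RETINAL_LABELS else WORLD_LABELS
  c0 <- per_subject[, 1]; c90 <- per_subject[, 2]
  c180 <- per_subject[, 3]; c270 <- per_subject[, 4]
  mk <- function(name, a, b) {
    ok <- is.finite(a) & is.finite(b)
    d <- a[ok] - b[ok]
    n <- length(d)
    if (n < 2 || stats::sd(d) == 0) {
      tt <- list(t = 0, df = max(n - 1, 0), p = 1)
    } else {
      # computed directly so that n = 2 (df = 1) is still returned
      tstat <- mean(d) / (stats::sd(d) / sqrt(n))
      tt <- list(t = tstat, df = n - 1,
                 p = 2 * stats::pt(-abs(tstat), n - 1))
    }
    data.frame(contrast = name, t = tt$t, df = tt$df, p_raw = tt$p,
               p_bonferroni = min(1, 3 * tt$p), n = n)
  }
  ax1 <- paste0(lab[["180"]], "-", lab[["0"]])   # N-T or L-R... see below
  ax2 <- paste0(lab[["90"]], "-", lab[["270"]])  # S-I or U-D
  if (frame == "world") ax1 <- paste0(lab[["0"]], "-", lab[["180"]])
  rbind(
    if (frame == "world") mk(ax1, c0, c180) else mk(ax1, c180, c0),
    mk(ax2, c90, c270),
    mk("H-V", (c0 + c180) / 2, (c90 + c270) / 2))
}

#' Chi-square circularity test (single condition)
#'
#' \code{chi2 = sum_b (mean_b - grand)^2 / SEM_b^2} with df = bins - 1;
#' the grand mean is the unweighted mean of the bin means.
#'
#' @param mean,sem per-bin across-subject means and SEMs
#' @return list(chi2, df, p)
#' @export
chi2_circularity <- function(mean, sem) {
  stopifnot(length(mean) == length(sem))
  if (any(!is.finite(sem)) || any(sem <= 0)) {
    stop("degenerate input: every bin needs a positive SEM")
  }
  chi2 <- sum((mean - base::mean(mean))^2 / sem^2)
  df <- length(mean) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df,
                                               lower.tail = FALSE))
}

#' Conjoint two-eye circularity test
#'
#' Sum of the two single-eye chi-square statistics, each about its own eye
#' mean (allowing arbitrary mean offsets between eyes); df = 2*bins - 2.
#'
#' @param mean_left,sem_left,mean_right,sem_right per-bin summaries per eye
#' @return list(chi2, df, p)
#' @export
chi2_circularity_conjoint <- function(mean_left, sem_left,
                                      mean_right, sem_right) {
  a <- chi2_circularity(mean_left, sem_left)
  b <- chi2_circularity(mean_right, sem_right)
  chi2 <- a$chi2 + b$chi2
  df <- a$df + b$df
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df,
                                               lower.tail = FALSE))
}

#' Chi-square condition-difference test
#'
#' \code{chi2 = sum_b (meanA_b - meanB_b)^2 / (SEMA_b^2 + SEMB_b^2)}; the
#' normalizer is the variance of the difference of the two component
#' means. df = bins - 1 (as conventionally tabulated for these polar
#' comparisons).
#'
#' @param mean_a,sem_a,mean_b,sem_b per-bin summaries per condition
#' @return list(chi2, df, p)
#' @export
chi2_condition_difference <- function(mean_a, sem_a, mean_b, sem_b) {
  if (length(mean_a) != length(mean_b)) stop("mismatched bin structure")
  if (any(!is.finite(c(sem_a, sem_b))) || any(c(sem_a, sem_b) <= 0)) {
    stop("degenerate input: every bin needs a positive SEM")
  }
  chi2 <- sum((mean_a - mean_b)^2 / (sem_a^2 + sem_b^2))
  df <- length(mean_a) - 1
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df,
                                               lower.tail = FALSE))
}

#' Horizontal centroid of a directional tuning curve
#'
#' First cosine Fourier coefficient: \code{(2/K) sum_b value_b
#' cos(center_b)}. Zero for flat tuning.
#'
#' @param values per-bin values
#' @param centers_deg bin centers
#' @return centroid (same units as values)
#' @export
horizontal_centroid <- function(values, centers_deg) {
  2 / length(values) * sum(values * cos(deg2rad(centers_deg)))
}

#' Nasal-temporal horizontal-shift test
#'
#' Computes each subject's horizontal tuning centroid per eye in world
#' coordinates and tests, by paired two-tailed t across subjects, whether
#' the left- and right-eye curves are systematically shifted horizontally
#' in opposite world directions — the world-coordinate signature of a
#' common nasal-temporal asymmetry (mirroring the left eye flips the sign
#' of its world centroid, so the test contrasts left vs right centroids).
#'
#' @param per_subject_left,per_subject_right subjects x 8 octant matrices
#'   in world coordinates (aligned rows)
#' @param centers_deg octant centers (default 0, 45, ..., 315)
#' @return list(t, df, p, mean_shift, centroids_left, centroids_right)
#' @export
nt_shift_test <- function(per_subject_left, per_subject_right,
                          centers_deg = seq(0, 315, by = 45)) {
  stopifnot(nrow(per_subject_left) == nrow(per_subject_right))
  cl <- apply(per_subject_left, 1, horizontal_centroid, centers_deg)
  cr <- apply(per_subject_right, 1, horizontal_centroid, centers_deg)
  ok <- is.finite(cl) & is.finite(cr)
  if (sum(ok) < 3) stop("need at least 3 subjects with complete octants")
  d <- cl[ok] - cr[ok]
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = sum(ok) - 1, p = 1, mean_shift = mean(d),
                centroids_left = cl, centroids_right = cr))
  }
  tt <- paired_t(cl[ok], cr[ok], tails = 2)
  list(t = tt$t, df = tt$df, p = tt$p, mean_shift = mean(d),
       centroids_left = cl, centroids_right = cr)
}

#' Per-direction tuning of the seven pursuit metrics for one run
#'
#' Computes per-trial values (latency, acceleration, gain, proportion
#' smooth, initial-direction residual, speed ratio) from extracted
#' features and bins each by direction. Latency and acceleration use
#' per-bin medians; direction noise uses the SD of distortion residuals
#' within the bin; speed noise the within-bin Weber fraction;
#' responsiveness the within-bin OLS slope.
#'
#' @param features per-trial features of one run
#' @param n_bins 4 or 8
#' @param frame "world" or "retinal"
#' @param eye "L"/"R" (needed for retinal frame)
#' @return named list of per-bin vectors (one per metric)
#' @export
tune_run_metrics <- function(features, n_bins = 8, frame = "world",
                             eye = "R") {
  tdir <- vapply(features, `[[`, numeric(1), "target_direction")
  bin_dir_onset <- tdir; bin_dir_steady <- tdir
  if (frame == "retinal") {
    bin_dir_onset <- map_to_retinal(tdir, eye, "onset")$angle_deg
    bin_dir_steady <- map_to_retinal(tdir, eye, "steady")$angle_deg
  }
  centers <- seq(0, 359, by = 360 / n_bins)
  half <- 180 / n_bins
  lat <- vapply(features, function(f) f$latency_ms %||% NA, numeric(1))
  acc <- vapply(features, function(f) f$open_loop_accel_deg_s2 %||% NA,
                numeric(1))
  vss <- vapply(features, function(f) f$steady_speed_deg_s %||% NA,
                numeric(1))
  tsp <- vapply(features, function(f) f$target_speed, numeric(1))
  psm <- vapply(features, function(f) f$proportion_smooth %||% NA,
                numeric(1))
  idir <- vapply(features, function(f) f$initial_direction_deg %||% NA,
                 numeric(1))
  dres <- fit_direction_distortion(tdir, idir)$residual_deg
  per_bin <- function(dirs, v, fun) {
    vapply(centers, function(cc) {
      w <- ang_diff(dirs, cc) >= -half & ang_diff(dirs, cc) < half &
        is.finite(v)
      if (sum(w) < 2) return(NA_real_)
      fun(v[w], w)
    }, numeric(1))
  }
  list(
    centers = centers,
    latency_ms = per_bin(bin_dir_onset, lat,
                         function(v, w) stats::median(v)),
    accel_deg_s2 = per_bin(bin_dir_onset, acc,
                           function(v, w) stats::median(v)),
    gain = per_bin(bin_dir_steady, vss / tsp, function(v, w) mean(v)),
    proportion_smooth = per_bin(bin_dir_steady, psm,
                                function(v, w) mean(v)),
    direction_noise_deg = per_bin(bin_dir_onset, dres, function(v, w) {
      stats::sd(v) / c4_factor(length(v))
    }),
    speed_noise_pct = vapply(centers, function(cc) {
      w <- ang_diff(bin_dir_steady, cc) >= -half &
        ang_diff(bin_dir_steady, cc) < half & is.finite(vss)
      if (sum(w) < 4) return(NA_real_)
      speed_noise_weber(vss[w], tsp[w], min_per_speed = 2, min_speeds = 2)
    }, numeric(1)),
    speed_responsiveness = vapply(centers, function(cc) {
      w <- ang_diff(bin_dir_steady, cc) >= -half &
        ang_diff(bin_dir_steady, cc) < half & is.finite(vss)
      if (sum(w) < 4) return(NA_real_)
      speed_responsiveness(vss[w], tsp[w])
    }, numeric(1)))
}
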