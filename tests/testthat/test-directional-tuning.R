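# Directional tuning, retinal mapping, and the chi-square battery.

test_that("retinal mapping: optical inversion and eye mirroring", {
  # upward ramp, steady state: image in upper field -> inferior retina
  expect_equal(map_to_retinal(90, "R", "steady")$quadrant, "I")
  expect_equal(map_to_retinal(90, "L", "steady")$quadrant, "I")
  # upward ramp => downward step; onset: lower field -> superior retina
  expect_equal(map_to_retinal(90, "R", "onset")$quadrant, "S")
  # rightward field: nasal for the right eye, temporal for the left
  expect_equal(map_to_retinal(0, "R", "steady")$quadrant, "N")
  expect_equal(map_to_retinal(0, "L", "steady")$quadrant, "T")
  expect_error(map_to_retinal(0, "X", "steady"), "eye")
  expect_error(map_to_retinal(0, "R", "mid"), "phase")
})

test_that("retinal mapping is a bijection and mirroring an involution", {
  grid <- seq(0, 356, by = 4)
  for (eye in c("L", "R")) {
    ret <- map_to_retinal(grid, eye, "steady")$angle_deg
    expect_setequal(ret, grid)        # permutation of the grid
  }
  # applying the left-eye mirror twice is the identity
  mirror <- function(a) (180 - a) %% 360
  expect_equal(mirror(mirror(grid)), grid)
})

test_that("octant binning: half-open boundary rule", {
  vals <- c(1, 2, 3)
  dirs <- c(22, 45, 22.5)
  b <- bin_metric_by_direction(vals, dirs, subjects = c(1, 1, 1), n_bins = 8)
  expect_equal(unname(b$per_subject[1, "0"]), 1)        # 22 < 22.5
  expect_equal(unname(b$per_subject[1, "45"]), mean(c(2, 3)))  # 22.5 joins 45
})

test_that("binning aggregates per subject before across-subject summary", {
  set.seed(51)
  dirs <- rep(seq(0, 315, by = 45), times = 6)
  subj <- rep(1:3, each = 16)
  vals <- rnorm(48, mean = subj)       # subject offsets
  b <- bin_metric_by_direction(vals, dirs, subj, n_bins = 8)
  expect_equal(dim(b$per_subject), c(3, 8))
  expect_equal(b$n, rep(3, 8), ignore_attr = TRUE)
  man <- vapply(seq(0, 315, 45), function(cc) {
    per <- vapply(1:3, function(s) mean(vals[subj == s & dirs == cc]),
                  numeric(1))
    sd(per) / sqrt(3)
  }, numeric(1))
  expect_equal(unname(b$sem), man)
})

test_that("quadrant asymmetry tests with Bonferroni", {
  per <- matrix(rnorm(17 * 4, 100, 5), 17, 4)
  same <- matrix(rep(rnorm(17, 100, 5), 4), 17, 4)
  r0 <- quadrant_asymmetry_tests(same, frame = "retinal")
  expect_equal(r0$t, rep(0, 3))
  expect_equal(r0$p_raw, rep(1, 3))
  r <- quadrant_asymmetry_tests(per, frame = "retinal")
  expect_equal(r$contrast, c("N-T", "S-I", "H-V"))
  expect_equal(r$p_bonferroni, pmin(1, 3 * r$p_raw))
  rw <- quadrant_asymmetry_tests(per, frame = "world")
  expect_equal(rw$contrast, c("R-L", "U-D", "H-V"))
  # two subjects: df = 1, still returned
  r2 <- quadrant_asymmetry_tests(per[1:2, ], frame = "world")
  expect_equal(r2$df, rep(1, 3))
})

test_that("quadrant N-T power at the published effect size", {
  set.seed(52)
  hits <- replicate(60, {
    nt_diff <- rnorm(17, -6, 5)             # N-T latency difference
    base <- rnorm(17, 163, 12)
    per <- cbind(base - nt_diff / 2, base + rnorm(17, 0, 5),
                 base + nt_diff / 2, base + rnorm(17, 0, 5))
    quadrant_asymmetry_tests(per, "retinal")$p_bonferroni[1] < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("chi-square circularity: frozen oracles and additivity", {
  flat <- chi2_circularity(rep(5, 8), rep(1, 8))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  # alternating +/-1 SEM deviations: grand mean unchanged, chi2 = 8
  m <- 5 + rep(c(1, -1), 4)
  one_eye <- chi2_circularity(m, rep(1, 8))
  expect_equal(one_eye$chi2, 8)
  conj <- chi2_circularity_conjoint(m, rep(1, 8), m + 3, rep(1, 8))
  expect_equal(conj$chi2, 16)            # eye-mean offsets drop out
  expect_equal(conj$df, 14)
  expect_equal(conj$p, pchisq(16, 14, lower.tail = FALSE))
  expect_equal(round(conj$p, 3), 0.313)
  # single-bin deviation: the grand mean shifts with it (frozen oracle:
  # (3 - 3/8)^2 + 7*(3/8)^2 = 7.875)
  single <- chi2_circularity(c(3, rep(0, 7)), rep(1, 8))
  expect_equal(single$chi2, 7.875)
  expect_error(chi2_circularity(m, rep(0, 8)), "degenerate")
})

test_that("condition-difference chi-square", {
  a <- c(10, 11, 12, 11, 10, 9, 8, 9)
  expect_equal(chi2_condition_difference(a, rep(1, 8), a, rep(1, 8))$chi2, 0)
  # uniform offset 1 with SEM 1 on both sides: each term 1/2
  r <- chi2_condition_difference(a + 1, rep(1, 8), a, rep(1, 8))
  expect_equal(r$chi2, 4)
  expect_equal(r$df, 7)
  # scaled isotropy: B = 1.1*A with proportional SEMs
  semA <- 0.1 * a
  r2 <- chi2_condition_difference(a, semA, 1.1 * a, 1.1 * semA)
  expect_equal(r2$chi2, sum((0.1 * a)^2 / (semA^2 * (1 + 1.21))))
  expect_error(chi2_condition_difference(a[1:4], rep(1, 4), a, rep(1, 8)),
               "mismatched")
})

test_that("conjoint chi-square equals the sum of single-eye statistics", {
  set.seed(53)
  mL <- rnorm(8, 10); sL <- runif(8, 0.5, 1.5)
  mR <- rnorm(8, 14); sR <- runif(8, 0.5, 1.5)
  conj <- chi2_circularity_conjoint(mL, sL, mR, sR)
  expect_equal(conj$chi2,
               chi2_circularity(mL, sL)$chi2 + chi2_circularity(mR, sR)$chi2)
})

test_that("horizontal centroid and the N-T shift test", {
  centers <- seq(0, 315, by = 45)
  expect_equal(horizontal_centroid(rep(7, 8), centers), 0)
  # cosine tuning of unit depth has centroid 1
  expect_equal(horizontal_centroid(5 + cos(centers * pi / 180), centers), 1)
  flatL <- matrix(rep(rnorm(17, 160, 10), 8), 17, 8)
  r0 <- nt_shift_test(flatL, flatL)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # opposite-signed horizontal shifts in the two eyes (the world-frame
  # signature of a nasal advantage) are detected
  set.seed(54)
  hits <- replicate(60, {
    base <- matrix(rnorm(17 * 8, 160, 3), 17, 8)
    shift <- rnorm(17, 3, 2)
    left <- base + outer(shift, cos(centers * pi / 180))
    right <- base - outer(shift, cos(centers * pi / 180))
    nt_shift_test(left, right)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("estimated-SEM chi-square inflates size; known-SEM is calibrated", {
  # the circularity test treats the per-bin SEM as a known variance; with
  # SEMs estimated from n = 17 subjects the statistic is anticonservative
  set.seed(55)
  n <- 17; reps <- 600
  rej_est <- rej_known <- 0
  for (r in seq_len(reps)) {
    x <- matrix(rnorm(n * 8), n, 8)
    m <- colMeans(x)
    sem_est <- apply(x, 2, sd) / sqrt(n)
    if (chi2_circularity(m, sem_est)$p < 0.05) rej_est <- rej_est + 1
    if (chi2_circularity(m, rep(1 / sqrt(n), 8))$p < 0.05) {
      rej_known <- rej_known + 1
    }
  }
  expect_gt(rej_est / reps, 0.07)    # measured inflation ~0.10
  expect_lt(abs(rej_known / reps - 0.05), 0.025)
})

test_that("isotropic run tuning is flat within sampling error", {
  p <- fixed_run_params(c(direction_anisotropy = 0,
                          direction_asymmetry = 0))
  cfg <- cohort_config_defaults()
  sch <- sample_stimulus_schedule(90, seed = 56)
  set.seed(56)
  feats <- lapply(seq_len(90), function(k) {
    tr <- simulate_trial(p, sch[k, ], cfg)
    extract_trial_features(tr$trace, sch[k, ])
  })
  tune <- tune_run_metrics(feats, n_bins = 8, frame = "world")
  expect_length(tune$gain, 8)
  expect_true(all(is.finite(tune$gain)))
  expect_lt(diff(range(tune$gain)), 0.25)
  ret <- tune_run_metrics(feats, n_bins = 8, frame = "retinal", eye = "L")
  expect_true(all(is.finite(ret$latency_ms)))
})
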