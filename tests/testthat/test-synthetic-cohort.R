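# Synthetic cohort generator.

test_that("90-trial schedule covers the 4-degree grid exactly once", {
  s <- sample_stimulus_schedule(90, seed = 1)
  expect_setequal(s$ramp_direction_deg, seq(0, 356, by = 4))
  expect_equal(anyDuplicated(s$ramp_direction_deg), 0)
  expect_true(all((s$step_direction_deg - s$ramp_direction_deg) %% 360
                  == 180))                               # Rashbass geometry
  expect_true(all(s$step_amplitude_deg >= 3.2 & s$step_amplitude_deg <= 4.8))
  expect_true(all(s$ramp_speed_deg_s %in% c(16, 18, 20, 22, 24)))
  expect_true(all(s$fixation_wait_ms >= 200 & s$fixation_wait_ms <= 5000))
  expect_true(all(s$ramp_past_center_ms >= 700 &
                    s$ramp_past_center_ms <= 1000))
})

test_that("schedule is deterministic under seed and validates input", {
  expect_identical(sample_stimulus_schedule(90, seed = 1),
                   sample_stimulus_schedule(90, seed = 1))
  s1 <- sample_stimulus_schedule(1, seed = 3)
  expect_equal(nrow(s1), 1)
  expect_error(sample_stimulus_schedule(0), "positive")
})

test_that("subject sampling: zero-SD config is deterministic", {
  pop <- fixed_population()
  sub <- sample_subject_params(pop, "R", 1, session_jitter = 0)
  # monocular non-dominant latency = mean - dominant_delta/2
  expect_equal(unname(sub$base[["latency_ms"]]), 165)
  expect_equal(unname(sub$conditions$binocular[["latency_ms"]]), 152)
  # zero condition effects + zero jitter: identical latents across runs
  sub0 <- sample_subject_params(pop, "L", 1, condition_effects = 0,
                                session_jitter = 0)
  expect_identical(sub0$conditions$left, sub0$conditions$right)
  expect_identical(sub0$conditions$left, sub0$conditions$binocular)
  bad <- pop; bad$sd[1] <- -1
  expect_error(sample_subject_params(bad), "SD")
})

test_that("subject sampling: Monte Carlo moments match the table", {
  set.seed(11)
  pop <- population_defaults()
  g <- replicate(1000, sample_subject_params(pop)$base[["gain"]])
  se <- 0.08 / sqrt(1000)
  expect_lt(abs(mean(g) - 0.87), 3 * se + 1e-3)  # truncation shifts < 1e-3
})

test_that("perfect tracker: steady radial speed equals target speed", {
  p <- fixed_run_params(c(gain = 1, speed_responsiveness = 1,
                          direction_noise_deg = 1e-9))
  cfg <- perfect_config()
  s <- sample_stimulus_schedule(3, seed = 2)
  tr <- simulate_trial(p, s[1, ], cfg, noise = FALSE)
  expect_equal(tr$truth$steady_speed_deg_s, s$ramp_speed_deg_s[1])
  expect_equal(nrow(tr$truth$saccades), 0)
  # ground-truth latency is the latent latency exactly
  expect_equal(tr$truth$latency_ms, p[["latency_ms"]])
  # uniform 250 Hz sampling
  expect_true(all(abs(diff(tr$trace$time_ms) - 4) < 1e-9))
})

test_that("trial simulation is deterministic under seed", {
  p <- fixed_run_params()
  s <- sample_stimulus_schedule(1, seed = 4)
  set.seed(99); t1 <- simulate_trial(p, s[1, ])
  set.seed(99); t2 <- simulate_trial(p, s[1, ])
  expect_identical(t1, t2)
})

test_that("Weber scaling: speed-noise fraction is scale invariant", {
  p <- fixed_run_params()
  base_cfg <- cohort_config_defaults()
  fast_cfg <- base_cfg
  fast_cfg$speeds <- base_cfg$speeds * 2
  webers <- vapply(list(base_cfg, fast_cfg), function(cfg) {
    set.seed(21)
    sch <- sample_stimulus_schedule(200, seed = 21, config = cfg)
    v <- vapply(seq_len(200), function(k) {
      simulate_trial(p, sch[k, ], cfg)$truth$steady_speed_deg_s
    }, numeric(1))
    speed_noise_weber(v, sch$ramp_speed_deg_s)
  }, numeric(1))
  expect_equal(webers[1], webers[2], tolerance = 0.1)
  expect_equal(webers[1], p[["speed_noise_pct"]], tolerance = 0.15)
})

test_that("pupil cycle: shunting amplitude derivation and clipping", {
  p <- fixed_run_params()
  cfg <- perfect_config()
  mono <- simulate_pupil_cycle(p, "monocular", cfg, noise = FALSE)
  expect_equal(mono$amplitude_mm, 3.6)
  bino <- simulate_pupil_cycle(p, "binocular", cfg, noise = FALSE)
  expect_equal(bino$amplitude_mm, 2 * 3.6 / (1 + 0.22 * 3.6))
  expect_equal(round(bino$amplitude_mm, 1), 4.0)   # printed pair
  cfg0 <- cfg; cfg0$shunting_k_amplitude <- 0
  b0 <- simulate_pupil_cycle(p, "binocular", cfg0, noise = FALSE)
  expect_equal(b0$amplitude_mm, min(2 * 3.6, cfg$dark_diameter_mm))
  bad <- p; bad[["contraction_tau_ms"]] <- -1
  expect_error(simulate_pupil_cycle(bad, "monocular", cfg), "> 0")
})

test_that("noiseless pupil step fit recovers the generating tau", {
  p <- fixed_run_params(c(contraction_tau_ms = 160,
                          dilation_tau_ms = 588))
  cfg <- perfect_config()
  pc <- simulate_pupil_cycle(p, "monocular", cfg, noise = FALSE)
  fit <- fit_pupil_step(pc$trace$time_ms, pc$trace$pupil_mm,
                        pc$transitions)
  expect_equal(fit$contraction_tau_ms, 160, tolerance = 1 / 160)
  expect_equal(fit$dilation_tau_ms, 588, tolerance = 2 / 588)
})

test_that("cohort simulation: structure and seed determinism", {
  c1 <- simulate_cohort(n_subjects = 2, conditions = c("left", "binocular"),
                        n_trials = 4, seed = 7)
  expect_length(c1$subjects, 2)
  expect_length(c1$runs, 4)
  conds <- vapply(c1$runs, `[[`, character(1), "condition")
  expect_equal(sort(unique(conds)), c("binocular", "left"))
  expect_true(all(vapply(c1$runs, function(r) nrow(r$schedule), 0L) == 4))
  c2 <- simulate_cohort(n_subjects = 2, conditions = c("left", "binocular"),
                        n_trials = 4, seed = 7)
  expect_identical(c1, c2)
  expect_error(simulate_cohort(conditions = "cyclops"))
})

test_that("metric-level cohort reflects configured condition effects", {
  set.seed(12)
  mc <- simulate_metric_cohort(n_subjects = 200, seed = 12,
                               session_jitter = 0)
  d <- mean(cyclopean_average(mc$left, mc$right)$latency_ms) -
    mean(mc$binocular$latency_ms)
  expect_lt(abs(d - 13), 0.5)               # binocular latency advantage
  mc0 <- simulate_metric_cohort(n_subjects = 5, seed = 3,
                                condition_effects = 0, session_jitter = 0)
  expect_identical(mc0$left$latency_ms, mc0$binocular$latency_ms)
})
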