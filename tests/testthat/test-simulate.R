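test_that("learner reproduces the hand-computed aim-direct recursion", {
  sched <- mini_schedule(2, rotation_deg = 45)
  p <- noiseless_params(strategy_mode = "none", retention_A = 1,
                        learning_rate_B = 0.1)
  lr <- simulate_learner(sched, p)
  expect_equal(lr$state_post_deg, c(-4.5, -8.55), tolerance = 1e-12)
})

test_that("no learning means no aftereffects; a perfect strategy zeroes cursor error", {
  cfg <- experiment_config("exp1", "pointer", baseline_block = FALSE,
                           n_blocks = 1)
  sched <- make_schedule(cfg, seed = 2)
  lr0 <- simulate_learner(sched, noiseless_params(learning_rate_B = 0,
                                                  strategy_mode = "none"))
  expect_true(all(lr0$state_post_deg == 0))

  lrs <- simulate_learner(sched, noiseless_params(
    learning_rate_B = 0, strategy_mode = "instructed_full"))
  adapt_fb <- lrs$cycle_type == "adaptation" & lrs$feedback
  expect_equal(lrs$cursor_error_deg[adapt_fb],
               rep(0, sum(adapt_fb)), tolerance = 1e-12)
})

test_that("state converges to the algebraic fixed point under constant rotation", {
  p <- noiseless_params(strategy_mode = "none")
  sched <- mini_schedule(400, rotation_deg = 45, hand_target = 45,
                         cursor_target = 45)
  lr <- simulate_learner(sched, p)
  fp <- learner_fixed_point(p$retention_A, p$learning_rate_B, 45)
  expect_equal(fp, -0.15 * 45 / (1 - 0.95 + 0.15))
  expect_lt(abs(lr$state_post_deg[400] - fp), 1e-9)
})

test_that("no-feedback reaches apply retention only", {
  sched <- mini_schedule(3, rotation_deg = 45)
  sched$feedback <- c(TRUE, FALSE, FALSE)
  p <- noiseless_params(strategy_mode = "none", retention_A = 0.9,
                        learning_rate_B = 0.2)
  lr <- simulate_learner(sched, p)
  expect_equal(lr$state_post_deg[1], -9)          # -0.2 * 45
  expect_equal(lr$state_post_deg[2], -9 * 0.9)
  expect_equal(lr$state_post_deg[3], -9 * 0.81)
})

test_that("noiseless trajectories land on the intended direction and pace", {
  p <- sim_params()
  tr <- simulate_trajectory(20, p, noise_sd_deg = 0)
  f <- reach_features(tr)
  expect_equal(f$raw_direction_deg, 20, tolerance = 0.01)
  expect_gt(max(trace_speed(tr)), 5)
  # the endpoint is read at movement offset (speed < 5 cm/s), a hair
  # before the trajectory's final sample
  expect_lt(abs(f$extent_cm - p$movement_extent_cm), 0.1)
  expect_lt(f$duration_to_radius_ms, 300)

  slow <- reach_features(simulate_trajectory(20, p, preset = "slow",
                                             noise_sd_deg = 0))
  expect_gt(slow$duration_to_radius_ms, 300)

  curved <- reach_features(simulate_trajectory(20, p, preset = "curved",
                                               noise_sd_deg = 0))
  expect_gt(curved$linearity_index, 0.2)
})

test_that("pointer reports honor bias sign conventions and recover location/scale", {
  trial <- data.frame(trial_id = "t", is_localization = TRUE,
                      cycle_type = "adaptation", rotation_dir = "ccw")
  p0 <- noiseless_params()
  rep0 <- simulate_pointer_report(c(0, 10), trial, p0)
  expect_equal(c(rep0$reported_x_cm, rep0$reported_y_cm), c(0, 10),
               tolerance = 1e-4)

  # bias 2 deg toward the cursor in a CW cycle: raw angular error -2,
  # +2 after sign correction
  trial_cw <- transform(trial, rotation_dir = "cw")
  pb <- noiseless_params(loc_bias_deg = 2)
  repb <- simulate_pointer_report(c(0, 10), trial_cw, pb)
  err <- angular_errors(cbind(repb, actual_x_cm = 0, actual_y_cm = 10)[
    , c("reported_x_cm", "reported_y_cm", "actual_x_cm", "actual_y_cm")])
  expect_equal(err$angular_error_deg, -2, tolerance = 1e-6)
  expect_equal(sign_correct(err$angular_error_deg, "cw"), 2, tolerance = 1e-6)

  # location/scale recovery at n = 5000 (spec-level property)
  set.seed(1)
  ps <- sim_params(loc_bias_deg = 2, loc_sigma_deg = 5, radial_sigma_cm = 0)
  errs <- replicate(5000, {
    r <- simulate_pointer_report(c(0, 10), trial, ps)
    xy_to_deg(r$reported_x_cm, r$reported_y_cm)
  })
  expect_lt(abs(mean(errs) - 2), 3 * 5 / sqrt(5000))
  expect_lt(abs(iqr_deg(errs) / (1.349 * 5) - 1), 0.10)

  expect_error(simulate_pointer_report(c(0, 10),
                                       transform(trial,
                                                 is_localization = FALSE),
                                       p0),
               "localization trials")
})

test_that("2AFC responses are deterministic at steep slopes and counterbalanced", {
  trial <- data.frame(trial_id = "t", is_localization = TRUE,
                      cycle_type = "washout", rotation_dir = "ccw")
  p <- sim_params(afc_slope_per_deg = 1e6, loc_bias_deg = 0)
  r <- simulate_afc_report(NULL, trial, p, 20)
  expect_identical(r$response, "left")
  expect_true(r$correct)
  r2 <- simulate_afc_report(NULL, trial, p, -20)
  expect_identical(r2$response, "right")
  expect_true(r2$correct)

  ds <- simulate_experiment(experiment_config("exp1", "afc2", n_blocks = 2),
                            sim_params("exp1", seed = 8))
  for (b in unique(ds$reports$block)) {
    for (ct in c("adaptation", "washout")) {
      offs <- ds$reports$probe_offset_deg[ds$reports$block == b &
                                            ds$reports$cycle_type == ct]
      expect_equal(unname(table(offs)), rep(3L, 6L), ignore_attr = TRUE)
    }
  }
})

test_that("simulated experiments are reproducible and structured as scheduled", {
  cfg <- experiment_config("exp2", n_blocks = 2)
  d1 <- simulate_experiment(cfg, sim_params("exp2", seed = 77))
  d2 <- simulate_experiment(cfg, sim_params("exp2", seed = 77))
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$reports, d2$reports)

  # aim-direct geometry: cursor misses the target by rotation + state
  fb <- d1$trials$cycle_type == "adaptation" & d1$trials$feedback
  pred <- 45 + d1$trials$state_pre_deg[fb] +
    (d1$trials$executed_direction_deg[fb] - d1$trials$aim_deg[fb] -
       d1$trials$state_pre_deg[fb])
  expect_equal(d1$trials$cursor_error_deg[fb],
               wrap_deg(pred), tolerance = 1e-9)
})

test_that("aftereffects grow with the number of preceding rotated reaches", {
  # seed-averaged property of the exp1 generator
  cfg <- experiment_config("exp1", "pointer", baseline_block = FALSE,
                           n_blocks = 2)
  means <- sapply(1:5, function(s) {
    ds <- simulate_experiment(cfg, sim_params("exp1", seed = 100 + s),
                              n_subjects = 2)
    rep <- run_pipeline(ds, match = FALSE)
    g <- attr(rep$aftereffects, "group")
    g$aftereffect_deg[order(g$preceding_cycle_length)]
  })
  avg <- rowMeans(means)
  expect_true(avg[1] < avg[2] && avg[2] < avg[3])
})
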