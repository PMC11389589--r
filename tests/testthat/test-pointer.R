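rep_df <- function(rep_ang, act_ang, rep_r = 10, act_r = 10) {
  rxy <- deg_to_xy(rep_ang, rep_r)
  axy <- deg_to_xy(act_ang, act_r)
  data.frame(reported_x_cm = rxy[, 1], reported_y_cm = rxy[, 2],
             actual_x_cm = axy[, 1], actual_y_cm = axy[, 2])
}

test_that("angular errors follow the definition and a brute-force recomputation", {
  expect_equal(angular_errors(rep_df(20, 20))$angular_error_deg, 0,
               tolerance = 1e-9)
  expect_equal(angular_errors(rep_df(23, 20))$angular_error_deg, 3,
               tolerance = 1e-9)

  set.seed(10)
  ra <- runif(50, -170, 170)
  aa <- runif(50, -170, 170)
  got <- angular_errors(rep_df(ra, aa, rep_r = runif(50, 5, 12)))
  # independent recomputation via atan2
  brute <- mapply(function(r, a, rr) {
    pr <- c(-rr * sin(r * pi / 180), rr * cos(r * pi / 180))
    pa <- c(-10 * sin(a * pi / 180), 10 * cos(a * pi / 180))
    d <- (atan2(-pr[1], pr[2]) - atan2(-pa[1], pa[2])) * 180 / pi
    ((d + 180) %% 360) - 180
  }, ra, aa, sqrt(got$reported_x_cm^2 + got$reported_y_cm^2))
  brute[brute == -180] <- 180
  expect_equal(got$angular_error_deg, unname(brute), tolerance = 1e-9)

  expect_error(angular_errors(rep_df(0, 20, rep_r = 0)),
               class = "vmr_zero_radius")
})

test_that("sign correction flips CW cycles only and restores a common bias", {
  expect_equal(sign_correct(-2, "cw"), 2)
  expect_equal(sign_correct(c(1.5, -3), c("ccw", "none")), c(1.5, -3))
  # equal-magnitude, opposite-sign biases per direction -> common bias
  errs <- c(rep(2, 10), rep(-2, 10))
  dirs <- c(rep("ccw", 10), rep("cw", 10))
  expect_equal(mean(sign_correct(errs, dirs)), 2)
})

test_that("bias bins are exact on a hand-computed fixture", {
  fx <- data.frame(
    subject_id = "S01",
    cycle_type = rep(c("adaptation", "washout"), each = 6),
    cycle_length = rep(c(2, 2, 3, 3, 4, 4), 2),
    hand_target_base_deg = 20,
    error_deg = c(1, 3, 2, 6, 5, 7, 0, 1, -1, 1, 2, -2))
  b <- compute_bias(fx)
  g <- function(ct, rn) b$bias_deg[b$cycle_type == ct & b$reach_number == rn]
  expect_equal(g("adaptation", "2"), 2)
  expect_equal(g("adaptation", "3"), 4)
  expect_equal(g("adaptation", "4"), 6)
  expect_equal(g("adaptation", "all"), 4)
  expect_equal(g("washout", "all"), 1 / 6)
  expect_equal(b$n_reports[b$reach_number == "all"], c(6L, 6L))

  expect_equal(compute_bias(transform(fx, error_deg = 2))$bias_deg,
               rep(2, 8))
})

test_that("bias is shift equivariant and IQR shift invariant / scale equivariant", {
  set.seed(3)
  fx <- data.frame(subject_id = "S01", cycle_type = "adaptation",
                   cycle_length = sample(2:4, 60, TRUE),
                   hand_target_base_deg = 20,
                   error_deg = rnorm(60, 0, 5))
  b0 <- compute_bias(fx); i0 <- compute_iqr(fx)
  fx2 <- transform(fx, error_deg = error_deg + 3)
  b1 <- compute_bias(fx2); i1 <- compute_iqr(fx2)
  expect_equal(b1$bias_deg, b0$bias_deg + 3, tolerance = 1e-12)
  expect_equal(i1$iqr_deg, i0$iqr_deg, tolerance = 1e-12)
  fx3 <- transform(fx, error_deg = error_deg * 2.5)
  expect_equal(compute_iqr(fx3)$iqr_deg, i0$iqr_deg * 2.5, tolerance = 1e-12)
})

test_that("IQR bins: constants give 0; per-target bias subtraction tightens mixtures", {
  fx <- data.frame(subject_id = "S01", cycle_type = "adaptation",
                   cycle_length = 2, hand_target_base_deg = 20,
                   error_deg = rep(2, 12))
  expect_equal(compute_iqr(fx)$iqr_deg, c(0, 0))

  set.seed(8)
  n <- 4000
  two <- data.frame(
    subject_id = "S01", cycle_type = "adaptation",
    cycle_length = 2,
    hand_target_base_deg = rep(c(20, 65), each = n / 2),
    error_deg = rnorm(n, 0, 3) + rep(c(4, -4), each = n / 2))
  with_sub <- compute_iqr(two, by_reach = FALSE)$iqr_deg
  pooled <- transform(two, hand_target_base_deg = 20)  # no target split
  without <- compute_iqr(pooled, by_reach = FALSE)$iqr_deg
  expect_lt(abs(with_sub / (1.349 * 3) - 1), 0.05)
  expect_gt(without, with_sub * 1.2)
})

test_that("low-count IQR bins are flagged", {
  fx <- data.frame(subject_id = "S01", cycle_type = "washout",
                   cycle_length = c(2, 2, 3), hand_target_base_deg = 20,
                   error_deg = c(1, 2, 3))
  out <- compute_iqr(fx)
  expect_true(all(out$low_n))
})

test_that("performance scores interpolate linearly between the anchors", {
  expect_equal(performance_score(0), 100)
  expect_equal(performance_score(12), 0)
  expect_equal(performance_score(10), 0)
  expect_equal(performance_score(5), 50)
  expect_error(performance_score(-1), "non-negative")
})

test_that("aftereffects mirror the learner state exactly in a noiseless run", {
  cfg <- experiment_config("exp2", n_blocks = 1)
  p <- noiseless_params(strategy_mode = "none")
  ds <- simulate_experiment(cfg, p)
  w1 <- ds$trials$cycle_type == "washout" &
    ds$trials$reach_index_in_cycle == 1
  feats <- compute_features(ds)
  dirs <- feats$direction_deg[match(ds$trials$trial_id[w1], feats$trial_id)]
  # positive-CW convention: signed direction equals minus the carried state
  expect_equal(dirs, -ds$trials$state_pre_deg[w1], tolerance = 1e-9)

  # no learning, no aftereffect
  ds0 <- simulate_experiment(cfg, noiseless_params(strategy_mode = "none",
                                                   learning_rate_B = 0))
  rep0 <- run_pipeline(ds0, match = FALSE)
  expect_equal(rep0$aftereffects$aftereffect_deg,
               rep(0, nrow(rep0$aftereffects)), tolerance = 1e-9)
})
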