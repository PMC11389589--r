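test_that("onset/offset detection matches the exhaustive scan oracle", {
  set.seed(21)
  p <- sim_params()
  for (i in 1:20) {
    preset <- sample(c("normal", "normal", "slow", "curved"), 1)
    tr <- simulate_trajectory(runif(1, -10, 80), p, preset = preset,
                              extent_cm = runif(1, 9.5, 11.5),
                              noise_sd_deg = 0)
    on <- detect_onset(tr)
    expect_identical(on, oracle_onset(tr))
    off <- detect_offset(tr, on)
    exp_off <- oracle_offset(tr, on)
    if (is.na(exp_off)) {
      expect_true(off$no_offset_flag)
    } else {
      expect_identical(off$offset_ms, exp_off)
      expect_false(off$no_offset_flag)
    }
  }
})

test_that("onset requires speed AND radius conditions at the same sample", {
  # 100 ms of fast jitter inside the 0.5 cm home region, then a real reach
  t_jit <- 0:99
  x_jit <- 0.3 * sin(0.02 * t_jit)   # 6 cm/s along a 0.3 cm circle
  y_jit <- 0.3 * cos(0.02 * t_jit)
  out <- simulate_trajectory(0, sim_params(), noise_sd_deg = 0)
  tr <- make_trace(c(x_jit, out$samples$x_cm),
                   c(y_jit, out$samples$y_cm),
                   t = 0:(99 + nrow(out$samples)))
  sp <- trace_speed(tr)
  # jitter exceeds the speed threshold but not the radius threshold
  expect_true(any(sp[1:100] > 5))
  on <- detect_onset(tr)
  expect_gte(on, 100)
  expect_identical(on, oracle_onset(tr))
})

test_that("degenerate traces raise NoOnset / fall back with a flag", {
  still <- make_trace(rep(0, 50), rep(0, 50))
  expect_error(detect_onset(still), class = "vmr_no_onset")

  # speed clamped above threshold to the end
  ramp <- make_trace(seq(0, 2, length.out = 201) * 0,
                     cumsum(rep(0.02, 201)))  # 20 cm/s forever
  on <- detect_onset(ramp)
  off <- detect_offset(ramp, on)
  expect_true(off$no_offset_flag)
  expect_equal(off$offset_ms, 200)
  expect_error(detect_offset(ramp), "onset")
})

test_that("double-peaked speed profiles end after the first peak's descent", {
  # two bell-shaped bursts separated by a pause
  burst <- function(t0, d0) {
    tau <- seq(0, 1, by = 1 / 150)
    d0 * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  }
  y <- c(burst(0, 8), 8 + burst(0, 4)[-1])
  tr <- make_trace(rep(0, length(y)), y)
  on <- detect_onset(tr)
  off <- detect_offset(tr, on)
  expect_identical(off$offset_ms, oracle_offset(tr, on))
  # offset falls inside the pause, before the second burst begins
  expect_lt(off$offset_ms, 160)
})

test_that("linearity index matches closed-form geometry", {
  straight <- make_trace(seq(0, 0, length.out = 101),
                         seq(0, 10, length.out = 101))
  expect_equal(linearity_index(straight, 0, 100), 0, tolerance = 1e-9)

  tri <- make_trace(c(0, 5, 10), c(0, 2, 0), t = c(0, 1, 2))
  expect_equal(linearity_index(tri, 0, 2), 0.2, tolerance = 1e-9)

  phi <- seq(-pi / 2, pi / 2, length.out = 201)
  semi <- make_trace(5 * cos(phi), 5 + 5 * sin(phi), t = seq_along(phi) - 1)
  expect_equal(linearity_index(semi, 0, 200), 0.5, tolerance = 1e-9)

  athome <- make_trace(c(0, 1, 0), c(0, 1, 0), t = c(0, 1, 2))
  expect_error(linearity_index(athome, 0, 2), class = "vmr_zero_extent")
})

test_that("features are translation invariant and rotation equivariant", {
  set.seed(4)
  p <- sim_params()
  tr <- simulate_trajectory(25, p, noise_sd_deg = 0)
  f0 <- reach_features(tr)

  shift <- tr
  shift$samples$x_cm <- shift$samples$x_cm + 3.7
  shift$samples$y_cm <- shift$samples$y_cm - 1.2
  shift$home_xy_cm <- tr$home_xy_cm + c(3.7, -1.2)
  fs <- reach_features(shift)
  expect_equal(fs$raw_direction_deg, f0$raw_direction_deg, tolerance = 1e-9)
  expect_equal(fs$extent_cm, f0$extent_cm, tolerance = 1e-9)
  expect_equal(fs$linearity_index, f0$linearity_index, tolerance = 1e-9)

  delta <- 30
  th <- delta * pi / 180
  rot <- tr
  # CCW rotation about home: angles increase by delta
  rot$samples$x_cm <- tr$samples$x_cm * cos(th) - tr$samples$y_cm * sin(th)
  rot$samples$y_cm <- tr$samples$x_cm * sin(th) + tr$samples$y_cm * cos(th)
  fr <- reach_features(rot)
  expect_equal(wrap_deg(fr$raw_direction_deg - f0$raw_direction_deg), delta,
               tolerance = 1e-9)
  expect_equal(fr$extent_cm, f0$extent_cm, tolerance = 1e-9)
  expect_equal(fr$linearity_index, f0$linearity_index, tolerance = 1e-9)
})

test_that("signed directions follow each experiment's convention", {
  # exp2: positive CW; reach exactly at the target
  expect_equal(signed_direction(20, 20, "ccw", "exp2"), 0)
  expect_equal(signed_direction(17, 20, "ccw", "exp2"), 3)   # 3 deg CW
  # exp1, CW-rotation cycle (target 65): 3 deg CCW drift is +3
  expect_equal(signed_direction(68, 65, "cw", "exp1"), 3)
  # exp1, CCW cycle (target 20): CW drift is positive
  expect_equal(signed_direction(17, 20, "ccw", "exp1"), 3)
})

test_that("batch features equal per-trace recomputation", {
  cfg <- experiment_config("exp2", n_blocks = 1,
                           cycles_per_type_per_block = 3)
  ds <- simulate_experiment(cfg, sim_params("exp2", seed = 5), traces = TRUE)
  feats <- compute_features(ds)
  for (i in seq_len(nrow(ds$trials))) {
    tr <- ds$traces[[ds$trials$trial_id[i]]]
    on <- oracle_onset(tr)
    off <- oracle_offset(tr, on)
    expect_equal(feats$onset_ms[i], on)
    expect_equal(feats$offset_ms[i], off)
    # direction at peak speed from position relative to home
    sp <- oracle_speed(tr)
    win <- which(tr$samples$t_ms >= on & tr$samples$t_ms <= off)
    pk <- win[which.max(sp[win])]
    expect_equal(feats$raw_direction_deg[i],
                 xy_to_deg(tr$samples$x_cm[pk], tr$samples$y_cm[pk]),
                 tolerance = 1e-9)
  }
})
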