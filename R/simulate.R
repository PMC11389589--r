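#' Generative parameters for the paradigm simulator
#'
#' The simulator stands in for human participants so that every analysis
#' stage can be exercised with known ground truth. Implicit adaptation follows
#' a single-state linear state-space learner per hand target,
#' `x <- A x - B e`, driven on feedback reaches by the visual error `e` of the
#' rotated cursor relative to the aim point; no-feedback reaches apply
#' retention only. Localization reports are the actual endpoint plus a
#' cycle-type-dependent bias toward the cursor and Gaussian dispersion
#' (pointer), or Bernoulli left/right draws from a logistic curve whose PSE is
#' shifted toward the cursor (2AFC).
#'
#' Default report parameters emulate the magnitudes the paradigm is designed
#' to detect (bias about 2 deg in adaptation vs 0.5 deg in washout; dispersion
#' giving angular-error IQRs of about 10.6 vs 6.0 deg; 2AFC JNDs of about 10.4
#' vs 6.9 deg) and are ordinary configuration, not ground truth of any real
#' dataset.
#'
#' @param experiment optional experiment id used to resolve the default
#'   `strategy_mode` (`"none"` for `exp2`, otherwise `"instructed_full"`).
#' @param retention_A retention factor per reach, in `[0, 1]`.
#' @param learning_rate_B learning rate per reach, in `[0, 1]`.
#' @param motor_noise_sd_deg SD of directional execution noise (deg).
#' @param strategy_mode `"instructed_full"` (aim at the hand target, fully
#'   countering the rotation) or `"none"` (aim at the displayed/cursor
#'   target).
#' @param strategy_noise_sd_deg SD of extra aiming noise on adaptation-cycle
#'   reaches under the instructed strategy (deg); this is what makes hand
#'   positions more variable in adaptation than washout.
#' @param per_target_states keep a separate learner state per hand target
#'   (needed in `exp1`, where rotation directions alternate between targets).
#' @param loc_bias_deg named vector (`baseline`, `adaptation`, `washout`) of
#'   localization bias toward the cursor (deg); scalars are recycled.
#' @param loc_sigma_deg named vector of angular report noise SDs (deg).
#' @param radial_sigma_cm SD of the radial pointer-report noise (cm).
#' @param afc_slope_per_deg named vector of logistic slopes (log-odds per
#'   deg) for 2AFC responses; JND = 2 ln 3 / slope.
#' @param premature_press_rate probability that a pointer report is submitted
#'   prematurely at less than half the movement extent (screening fodder).
#' @param movement_extent_cm mean movement extent; reaches stop just behind
#'   the 10 cm target.
#' @param extent_sd_cm SD of movement extent (cm).
#' @param movement_duration_ms duration of the simulated reach.
#' @param sample_rate_hz kinematic sampling rate.
#' @param seed integer seed used by [simulate_experiment()].
#' @return an object of class `vmr_params` (a list).
#' @examples
#' p <- sim_params(seed = 1)
#' p$loc_sigma_deg
#' @export
sim_params <- function(experiment = NULL,
                       retention_A = 0.95,
                       learning_rate_B = 0.15,
                       motor_noise_sd_deg = 2.8,
                       strategy_mode = NULL,
                       strategy_noise_sd_deg = 7.8,
                       per_target_states = TRUE,
                       loc_bias_deg = c(baseline = 0, adaptation = 2,
                                        washout = 0.5),
                       loc_sigma_deg = c(baseline = 5.03, adaptation = 7.84,
                                         washout = 4.46),
                       radial_sigma_cm = 0.8,
                       afc_slope_per_deg = c(baseline = 0.32,
                                             adaptation = 0.211,
                                             washout = 0.32),
                       premature_press_rate = 0,
                       movement_extent_cm = 10.5,
                       extent_sd_cm = 0.3,
                       movement_duration_ms = 350,
                       sample_rate_hz = 1000,
                       seed = NULL) {
  if (is.null(strategy_mode)) {
    strategy_mode <- if (identical(experiment, "exp2")) "none"
      else "instructed_full"
  }
  strategy_mode <- match.arg(strategy_mode, c("instructed_full", "none"))
  expand <- function(v, what) {
    types <- c("baseline", "adaptation", "washout")
    if (is.null(names(v))) {
      if (length(v) == 1L) v <- rep(v, 3L)
      if (length(v) != 3L) stop(what, " must be a scalar or named by cycle type",
                                call. = FALSE)
      names(v) <- types
    }
    if (!all(types %in% names(v))) stop(what, " must name all cycle types",
                                        call. = FALSE)
    v[types]
  }
  loc_bias_deg <- expand(loc_bias_deg, "loc_bias_deg")
  loc_sigma_deg <- expand(loc_sigma_deg, "loc_sigma_deg")
  afc_slope_per_deg <- expand(afc_slope_per_deg, "afc_slope_per_deg")
  stopifnot(retention_A >= 0, retention_A <= 1,
            learning_rate_B >= 0, learning_rate_B <= 1,
            all(loc_sigma_deg > 0), all(afc_slope_per_deg > 0),
            motor_noise_sd_deg >= 0, strategy_noise_sd_deg >= 0,
            premature_press_rate >= 0, premature_press_rate <= 1)
  structure(list(
    retention_A = retention_A, learning_rate_B = learning_rate_B,
    motor_noise_sd_deg = motor_noise_sd_deg, strategy_mode = strategy_mode,
    strategy_noise_sd_deg = strategy_noise_sd_deg,
    per_target_states = per_target_states,
    loc_bias_deg = loc_bias_deg, loc_sigma_deg = loc_sigma_deg,
    radial_sigma_cm = radial_sigma_cm,
    afc_slope_per_deg = afc_slope_per_deg,
    premature_press_rate = premature_press_rate,
    movement_extent_cm = movement_extent_cm, extent_sd_cm = extent_sd_cm,
    movement_duration_ms = movement_duration_ms,
    sample_rate_hz = sample_rate_hz, seed = seed
  ), class = "vmr_params")
}

# Sign of "toward the cursor": +1 in CCW-rotation cycles, -1 in CW cycles.
cursor_sign <- function(rotation_dir) {
  ifelse(rotation_dir == "cw", -1, 1)
}

#' Simulate the state-space learner over a schedule
#'
#' Walks the trial table in order, updating the implicit state on every
#' feedback reach (`x <- A x - B e`, with `e` the angular error of the rotated
#' cursor relative to the aim point) and applying retention only
#' (`x <- A x`) on no-feedback localization reaches. Under
#' `strategy_mode = "instructed_full"`, adaptation-cycle reaches aim at the
#' hand target (the full 45 deg counter-rotation) with additional aiming
#' noise; under `"none"` they aim at the displayed cursor target.
#'
#' @param schedule a `vmr_schedule` (or any data frame with its columns).
#' @param params a `vmr_params`.
#' @return the schedule with columns `aim_deg`, `state_pre_deg`,
#'   `state_post_deg`, `intended_direction_deg` (aim + strategy noise +
#'   state), `executed_direction_deg` (+ motor noise),
#'   `cursor_direction_deg` and `cursor_error_deg` (cursor minus cursor
#'   target; `NA` on no-feedback reaches).
#' @examples
#' sched <- make_schedule(experiment_config("exp2"), seed = 1)
#' p <- sim_params("exp2", motor_noise_sd_deg = 0)
#' lr <- simulate_learner(sched, p)
#' head(lr$state_post_deg)
#' @export
simulate_learner <- function(schedule, params) {
  n <- nrow(schedule)
  A <- params$retention_A
  B <- params$learning_rate_B
  motor <- stats::rnorm(n, 0, params$motor_noise_sd_deg)
  strat <- if (params$strategy_mode == "instructed_full") {
    stats::rnorm(n, 0, params$strategy_noise_sd_deg) *
      (schedule$cycle_type == "adaptation")
  } else rep(0, n)

  aim <- ifelse(schedule$cycle_type == "adaptation" &
                  params$strategy_mode == "instructed_full",
                schedule$hand_target_deg, schedule$cursor_target_deg)

  state_key <- if (params$per_target_states) {
    paste(schedule$subject_id, schedule$hand_target_base_deg)
  } else schedule$subject_id
  states <- new.env(parent = emptyenv())

  state_pre <- state_post <- executed <- numeric(n)
  cursor_dir <- cursor_err <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    key <- state_key[i]
    x <- if (is.null(states[[key]])) 0 else states[[key]]
    state_pre[i] <- x
    executed[i] <- aim[i] + strat[i] + x + motor[i]
    if (schedule$feedback[i]) {
      cd <- executed[i] + schedule$rotation_applied_deg[i]
      cursor_dir[i] <- cd
      cursor_err[i] <- wrap_deg(cd - schedule$cursor_target_deg[i])
      x <- A * x - B * wrap_deg(cd - aim[i])
    } else {
      x <- A * x
    }
    state_post[i] <- x
    states[[key]] <- x
  }
  out <- schedule
  out$aim_deg <- aim
  out$state_pre_deg <- state_pre
  out$state_post_deg <- state_post
  out$intended_direction_deg <- aim + strat + state_pre
  out$executed_direction_deg <- executed
  out$cursor_direction_deg <- cursor_dir
  out$cursor_error_deg <- cursor_err
  out
}

#' Fixed point of the learner under a constant rotation
#'
#' Solves `x* = A x* - B (r + x*)` for the asymptotic implicit state reached
#' under aim-direct reaching with a constant rotation `r`.
#'
#' @param retention_A,learning_rate_B learner parameters.
#' @param rotation_deg signed rotation (+ = CCW).
#' @return the asymptotic state in degrees.
#' @export
learner_fixed_point <- function(retention_A, learning_rate_B, rotation_deg) {
  -learning_rate_B * rotation_deg / (1 - retention_A + learning_rate_B)
}

#' Simulate a single reach trajectory
#'
#' Generates a minimum-jerk, bell-shaped 2-D hand path at the configured
#' sampling rate, starting at home and travelling `extent_cm` (stopping just
#' behind the 10 cm target) in the given direction plus Gaussian direction
#' noise. Two pathological presets support screening tests: `"slow"`
#' lengthens the movement so the target radius is crossed after more than
#' 300 ms, `"curved"` bows the path so its linearity index exceeds 0.2.
#'
#' @param direction_deg intended movement direction (deg CCW from straight
#'   ahead).
#' @param params a `vmr_params`.
#' @param preset `"normal"`, `"slow"`, or `"curved"`.
#' @param extent_cm movement extent; defaults to `params$movement_extent_cm`.
#' @param noise_sd_deg direction noise SD; defaults to the params value (set
#'   0 when the direction already includes execution noise).
#' @param trial_id optional identifier carried on the trace.
#' @return an object of class `vmr_trace`: a list with `samples`
#'   (`data.frame` of `t_ms`, `x_cm`, `y_cm` at 1 ms steps), `home_xy_cm`,
#'   `trial_id`, and the realized `direction_deg`.
#' @examples
#' tr <- simulate_trajectory(20, sim_params(), noise_sd_deg = 0)
#' nrow(tr$samples)
#' @export
simulate_trajectory <- function(direction_deg, params = sim_params(),
                                preset = c("normal", "slow", "curved"),
                                extent_cm = NULL, noise_sd_deg = NULL,
                                trial_id = NULL) {
  preset <- match.arg(preset)
  if (is.null(extent_cm)) extent_cm <- params$movement_extent_cm
  if (is.null(noise_sd_deg)) noise_sd_deg <- params$motor_noise_sd_deg
  duration_ms <- switch(preset, normal = params$movement_duration_ms,
                        slow = 600, curved = params$movement_duration_ms)
  curvature <- if (preset == "curved") 0.25 else 0
  dir <- direction_deg +
    if (noise_sd_deg > 0) stats::rnorm(1, 0, noise_sd_deg) else 0

  dt_ms <- 1000 / params$sample_rate_hz
  t <- seq(0, duration_ms, by = dt_ms)
  tau <- t / duration_ms
  along <- extent_cm * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  perp <- curvature * extent_cm * sin(pi * tau)
  u <- deg_to_xy(dir, 1)
  v <- deg_to_xy(dir + 90, 1)
  structure(list(
    samples = data.frame(t_ms = t,
                         x_cm = along * u[1] + perp * v[1],
                         y_cm = along * u[2] + perp * v[2]),
    home_xy_cm = c(0, 0),
    trial_id = trial_id,
    direction_deg = dir
  ), class = "vmr_trace")
}

trace_positions <- function(trace) {
  as.matrix(trace$samples[, c("x_cm", "y_cm")])
}

resolve_endpoint <- function(x) {
  if (inherits(x, "vmr_trace")) {
    p <- trace_positions(x)
    p[nrow(p), ] - x$home_xy_cm
  } else {
    as.numeric(x)
  }
}

#' Simulate a pointer localization report
#'
#' The reported position is the actual endpoint shifted angularly toward the
#' cursor by the cycle type's localization bias (CCW in CCW-rotation cycles,
#' CW in CW cycles) plus Gaussian angular and radial noise. With probability
#' `premature_press_rate` the report is a premature pedal press at less than
#' half the movement extent.
#'
#' @param trace a `vmr_trace`, or an endpoint as `c(x, y)` relative to home.
#' @param trial the trial's schedule row (a localization trial).
#' @param params a `vmr_params`.
#' @return one-row `data.frame` with reported and actual positions.
#' @export
simulate_pointer_report <- function(trace, trial, params) {
  if (!isTRUE(trial$is_localization)) {
    stop("pointer reports are only defined for localization trials",
         call. = FALSE)
  }
  ep <- resolve_endpoint(trace)
  ang <- xy_to_deg(ep[1], ep[2])
  rad <- sqrt(sum(ep^2))
  ct <- trial$cycle_type
  s <- cursor_sign(trial$rotation_dir)
  rep_ang <- ang + s * params$loc_bias_deg[[ct]] +
    stats::rnorm(1, 0, params$loc_sigma_deg[[ct]])
  rep_rad <- rad + stats::rnorm(1, 0, params$radial_sigma_cm)
  if (params$premature_press_rate > 0 &&
      stats::runif(1) < params$premature_press_rate) {
    rep_rad <- stats::runif(1, 0.1, 0.45) * rad
  }
  rep_rad <- max(rep_rad, 0.05)
  xy <- deg_to_xy(rep_ang, rep_rad)
  data.frame(trial_id = trial$trial_id %||% NA_character_,
             reported_x_cm = xy[1], reported_y_cm = xy[2],
             actual_x_cm = ep[1], actual_y_cm = ep[2])
}

#' Simulate a 2AFC localization report
#'
#' Draws a left/right judgment of a probe at `probe_offset_deg` relative to
#' the actual hand position from a logistic curve: the probability of
#' responding "left" (CCW of the hand) is
#' `plogis(slope * (offset - pse))`, with the PSE shifted toward the cursor
#' by the cycle type's localization bias.
#'
#' @param trace unused placeholder for signature symmetry (responses depend
#'   only on the probe offset relative to the actual hand position); may be
#'   `NULL`.
#' @param trial the trial's schedule row.
#' @param params a `vmr_params`.
#' @param probe_offset_deg signed probe offset, from the design set
#'   `c(-20, -10, -3.33, 3.33, 10, 20)`.
#' @return one-row `data.frame` with `probe_offset_deg`, `response`
#'   (`"left"`/`"right"`), `response_left`, and `correct`.
#' @export
simulate_afc_report <- function(trace, trial, params, probe_offset_deg) {
  ct <- trial$cycle_type
  s <- cursor_sign(trial$rotation_dir)
  pse <- s * params$loc_bias_deg[[ct]]
  slope <- params$afc_slope_per_deg[[ct]]
  p_left <- stats::plogis(slope * (probe_offset_deg - pse))
  left <- stats::runif(1) < p_left
  data.frame(trial_id = trial$trial_id %||% NA_character_,
             probe_offset_deg = probe_offset_deg,
             response = if (left) "left" else "right",
             response_left = left,
             correct = (probe_offset_deg > 0) == left)
}

#' Probe offsets used in the 2AFC design
#' @return the six signed offsets, in degrees.
#' @export
afc_probe_offsets <- function() c(-20, -10, -3.33, 3.33, 10, 20)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete experiment with known ground truth
#'
#' Generates schedules, learner states, reach endpoints (optionally full
#' 1 kHz trajectories), and localization reports for `n_subjects`
#' participants, fully determined by `params$seed`.
#'
#' With `traces = FALSE` (the default) the bundle carries endpoint-level
#' kinematics (executed direction, sampled extent) and
#' [compute_features()] derives idealized reach features directly from them;
#' with `traces = TRUE` every reach gets a minimum-jerk trajectory and
#' features are recovered by event detection, which is slower but exercises
#' the full kinematic path.
#'
#' @param config a `vmr_config`.
#' @param params a `vmr_params` (its `seed`, if non-`NULL`, seeds the run).
#' @param n_subjects number of simulated participants.
#' @param traces generate full kinematic traces?
#' @return an object of class `vmr_dataset`: a list with `trials` (schedule +
#'   learner + endpoint columns), `reports`, `traces` (named list or `NULL`),
#'   `config`, `params`, and `ground_truth`.
#' @examples
#' ds <- simulate_experiment(experiment_config("exp2"),
#'                           sim_params("exp2", seed = 1))
#' nrow(ds$trials)
#' @export
simulate_experiment <- function(config, params = sim_params(config$experiment),
                                n_subjects = 1L, traces = FALSE) {
  stopifnot(inherits(config, "vmr_config"), inherits(params, "vmr_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  all_trials <- vector("list", n_subjects)
  all_reports <- vector("list", n_subjects)
  trace_list <- if (traces) list() else NULL

  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    sched <- make_schedule(config, seed = NULL, subject_id = sid)
    tr <- simulate_learner(sched, params)
    n <- nrow(tr)
    tr$extent_actual_cm <- stats::rnorm(n, params$movement_extent_cm,
                                        params$extent_sd_cm)
    ep <- deg_to_xy(tr$executed_direction_deg, tr$extent_actual_cm)
    tr$endpoint_x_cm <- ep[, 1]
    tr$endpoint_y_cm <- ep[, 2]

    if (traces) {
      for (i in seq_len(n)) {
        trace_list[[tr$trial_id[i]]] <- simulate_trajectory(
          tr$executed_direction_deg[i], params,
          extent_cm = tr$extent_actual_cm[i], noise_sd_deg = 0,
          trial_id = tr$trial_id[i])
      }
    }

    loc <- tr[tr$is_localization, ]
    if (config$localization_method == "pointer") {
      reps <- lapply(seq_len(nrow(loc)), function(i) {
        simulate_pointer_report(
          c(loc$endpoint_x_cm[i], loc$endpoint_y_cm[i]), loc[i, ], params)
      })
    } else {
      # counterbalance the six probe offsets within block x cycle type
      loc$probe_offset_deg <- NA_real_
      for (b in unique(loc$block)) {
        for (ct in unique(loc$cycle_type[loc$block == b])) {
          idx <- which(loc$block == b & loc$cycle_type == ct)
          offs <- rep(afc_probe_offsets(),
                      length.out = length(idx))
          loc$probe_offset_deg[idx] <- sample(offs)
        }
      }
      reps <- lapply(seq_len(nrow(loc)), function(i) {
        simulate_afc_report(NULL, loc[i, ], params, loc$probe_offset_deg[i])
      })
    }
    reports <- do.call(rbind, reps)
    reports <- cbind(
      loc[, c("subject_id", "block", "cycle_index", "cycle_type",
              "cycle_length", "rotation_dir", "hand_target_base_deg",
              "hand_target_deg")],
      reports)
    all_trials[[s]] <- tr
    all_reports[[s]] <- reports
  }

  structure(list(
    trials = do.call(rbind, all_trials),
    reports = do.call(rbind, all_reports),
    traces = trace_list,
    config = config,
    params = params,
    ground_truth = list(
      loc_bias_deg = params$loc_bias_deg,
      loc_sigma_deg = params$loc_sigma_deg,
      loc_iqr_deg = iqr_norm_factor * params$loc_sigma_deg,
      afc_jnd_deg = 2 * log(3) / params$afc_slope_per_deg,
      learner = c(A = params$retention_A, B = params$learning_rate_B)
    )
  ), class = "vmr_dataset")
}

#' @export
print.vmr_dataset <- function(x, ...) {
  cat("<vmr_dataset> ", x$config$experiment, " / ",
      x$config$localization_method, "\n", sep = "")
  cat("  subjects: ", length(unique(x$trials$subject_id)),
      ", trials: ", nrow(x$trials),
      ", localization reports: ", nrow(x$reports), "\n", sep = "")
  cat("  traces: ", if (is.null(x$traces)) "endpoint-level (none stored)"
      else length(x$traces), "\n", sep = "")
  invisible(x)
}
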