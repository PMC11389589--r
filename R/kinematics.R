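#' Hand speed along a trace
#'
#' Speed from central differences of position (one-sided at the ends), with
#' no smoothing: simulated traces are noise-free between samples, and an
#' optional low-pass filter hook (`smooth_fun`) is provided for real
#' recordings.
#'
#' @param trace a `vmr_trace`.
#' @param smooth_fun optional function applied to each position column before
#'   differentiation (e.g. a low-pass filter); default none.
#' @return numeric vector of speeds in cm/s, one per sample.
#' @export
trace_speed <- function(trace, smooth_fun = NULL) {
  p <- trace_positions(trace)
  if (!is.null(smooth_fun)) p <- apply(p, 2, smooth_fun)
  t <- trace$samples$t_ms
  n <- nrow(p)
  if (n < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  v <- matrix(NA_real_, n, 2)
  v[1, ] <- (p[2, ] - p[1, ]) / (t[2] - t[1])
  v[n, ] <- (p[n, ] - p[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2L) {
    idx <- 2:(n - 1)
    v[idx, ] <- (p[idx + 1, ] - p[idx - 1, ]) / (t[idx + 1] - t[idx - 1])
  }
  sqrt(rowSums(v^2)) * 1000  # cm/ms -> cm/s
}

trace_radius <- function(trace) {
  p <- trace_positions(trace)
  sqrt((p[, 1] - trace$home_xy_cm[1])^2 + (p[, 2] - trace$home_xy_cm[2])^2)
}

#' Detect movement onset
#'
#' Onset is the first sample at which the hand speed exceeds
#' `speed_threshold` AND the radial distance from home exceeds
#' `radius_threshold` — both conditions must hold at the same sample.
#'
#' @param trace a `vmr_trace`.
#' @param speed_threshold cm/s (default 5).
#' @param radius_threshold cm (default 0.5).
#' @param smooth_fun optional position filter, see [trace_speed()].
#' @return onset time in ms.
#' @section Errors: signals a condition of class `vmr_no_onset` when no
#'   sample satisfies both thresholds.
#' @export
detect_onset <- function(trace, speed_threshold = 5, radius_threshold = 0.5,
                         smooth_fun = NULL) {
  sp <- trace_speed(trace, smooth_fun)
  r <- trace_radius(trace)
  idx <- which(sp > speed_threshold & r > radius_threshold)
  if (length(idx) == 0L) {
    stop(errorCondition("no movement onset detected",
                        class = c("vmr_no_onset", "error", "condition")))
  }
  trace$samples$t_ms[idx[1]]
}

#' Detect movement offset
#'
#' Offset is the first sample after the first post-onset speed peak at which
#' speed falls below `speed_threshold`. Searching only after the first peak
#' avoids triggering on sub-threshold jitter right at onset; with a
#' double-peaked speed profile the offset follows the first peak's descent
#' below threshold. If speed never falls below threshold, the last sample is
#' returned with `no_offset_flag = TRUE`.
#'
#' @param trace a `vmr_trace`.
#' @param onset_ms onset time from [detect_onset()].
#' @param speed_threshold cm/s (default 5).
#' @param smooth_fun optional position filter.
#' @return list with `offset_ms` and `no_offset_flag`.
#' @export
detect_offset <- function(trace, onset_ms, speed_threshold = 5,
                          smooth_fun = NULL) {
  if (missing(onset_ms) || is.null(onset_ms) || is.na(onset_ms)) {
    stop("onset_ms is required; run detect_onset() first", call. = FALSE)
  }
  sp <- trace_speed(trace, smooth_fun)
  t <- trace$samples$t_ms
  i0 <- which(t >= onset_ms)[1]
  n <- length(sp)
  # first post-onset peak above threshold
  k <- NA_integer_
  for (i in i0:n) {
    if (sp[i] > speed_threshold && (i == n || sp[i + 1] <= sp[i])) {
      k <- i
      break
    }
  }
  if (is.na(k)) k <- i0
  below <- which(sp < speed_threshold)
  below <- below[below > k]
  if (length(below) == 0L) {
    list(offset_ms = t[n], no_offset_flag = TRUE)
  } else {
    list(offset_ms = t[below[1]], no_offset_flag = FALSE)
  }
}

#' Linearity index of a reach path
#'
#' The maximum perpendicular distance between the trajectory (from onset to
#' offset) and the straight line from home to the movement endpoint, divided
#' by the movement extent. 0 for a perfectly straight reach; 0.5 for a
#' semicircular detour.
#'
#' @param trace a `vmr_trace`.
#' @param onset_ms,offset_ms movement window (ms).
#' @return the linearity index (dimensionless, >= 0).
#' @section Errors: signals a condition of class `vmr_zero_extent` when the
#'   endpoint coincides with home.
#' @export
linearity_index <- function(trace, onset_ms, offset_ms) {
  stopifnot(onset_ms < offset_ms)
  t <- trace$samples$t_ms
  win <- which(t >= onset_ms & t <= offset_ms)
  p <- trace_positions(trace)
  home <- trace$home_xy_cm
  end <- p[win[length(win)], ] - home
  extent <- sqrt(sum(end^2))
  if (extent < 1e-9) {
    stop(errorCondition("zero movement extent: linearity index undefined",
                        class = c("vmr_zero_extent", "error", "condition")))
  }
  u <- end / extent
  dx <- p[win, 1] - home[1]
  dy <- p[win, 2] - home[2]
  perp <- abs(dx * u[2] - dy * u[1])
  max(perp) / extent
}

#' Signed movement direction under the study's conventions
#'
#' Converts a raw direction into a target-relative signed direction:
#' positive CW for CCW-only designs (`exp2`, `exp3`, and baseline cycles),
#' and positive in the direction of expected adaptation in `exp1` (CW for the
#' target associated with CCW rotation, CCW for the target associated with CW
#' rotation).
#'
#' @param raw_direction_deg raw direction, deg CCW from straight ahead.
#' @param hand_target_deg the instructed aim direction.
#' @param rotation_dir `"cw"`, `"ccw"`, or `"none"` (governing cycle
#'   direction; washout cycles carry the preceding adaptation cycle's).
#' @param experiment `"exp1"`, `"exp2"`, or `"exp3"`.
#' @return signed direction in degrees.
#' @export
signed_direction <- function(raw_direction_deg, hand_target_deg, rotation_dir,
                             experiment) {
  dev <- wrap_deg(raw_direction_deg - hand_target_deg)
  if (identical(experiment, "exp1")) {
    ifelse(rotation_dir == "cw", dev, -dev)
  } else {
    -dev
  }
}

#' Extract reach features from one trace
#'
#' Computes onset, offset, time of peak speed (first global maximum within
#' the movement window), movement direction at peak speed (angle of the hand
#' position relative to home at that time), movement extent (radial distance
#' of the endpoint), linearity index, and the onset-to-target-radius duration
#' (`NA` if the 10 cm circle is never crossed). The signed direction applies
#' the experiment's sign convention via [signed_direction()].
#'
#' @param trace a `vmr_trace`.
#' @param trial the trial's schedule row (for targets and sign convention);
#'   may be `NULL`, in which case only convention-free features are filled.
#' @param experiment experiment id; defaults to `"exp2"` conventions.
#' @param target_distance_cm radius of the target circle (default 10).
#' @param speed_threshold,radius_threshold onset/offset thresholds.
#' @param smooth_fun optional position filter.
#' @return one-row `data.frame` of features.
#' @export
reach_features <- function(trace, trial = NULL, experiment = "exp2",
                           target_distance_cm = 10, speed_threshold = 5,
                           radius_threshold = 0.5, smooth_fun = NULL) {
  onset <- detect_onset(trace, speed_threshold, radius_threshold, smooth_fun)
  off <- detect_offset(trace, onset, speed_threshold, smooth_fun)
  t <- trace$samples$t_ms
  sp <- trace_speed(trace, smooth_fun)
  r <- trace_radius(trace)
  p <- trace_positions(trace)
  home <- trace$home_xy_cm

  win <- which(t >= onset & t <= off$offset_ms)
  pk <- win[which.max(sp[win])]
  raw_dir <- xy_to_deg(p[pk, 1] - home[1], p[pk, 2] - home[2])
  iend <- win[length(win)]
  extent <- r[iend]
  li <- linearity_index(trace, onset, off$offset_ms)

  crossed <- which(r >= target_distance_cm & t >= onset)
  dur <- if (length(crossed) == 0L) NA_real_ else t[crossed[1]] - onset

  dir_signed <- if (is.null(trial)) NA_real_ else {
    signed_direction(raw_dir, trial$hand_target_deg, trial$rotation_dir,
                     experiment)
  }
  data.frame(
    trial_id = if (is.null(trial)) trace$trial_id %||% NA_character_
      else trial$trial_id,
    onset_ms = onset, offset_ms = off$offset_ms, peak_speed_ms = t[pk],
    raw_direction_deg = raw_dir, direction_deg = dir_signed,
    extent_cm = extent, linearity_index = li,
    duration_to_radius_ms = dur,
    endpoint_x_cm = p[iend, 1] - home[1], endpoint_y_cm = p[iend, 2] - home[2],
    no_offset_flag = off$no_offset_flag)
}

#' Compute reach features for a whole dataset
#'
#' For trace-bearing datasets, runs [reach_features()] on every stored
#' trajectory. For endpoint-level datasets (simulated with `traces = FALSE`),
#' features come directly from the generator's executed directions and
#' sampled extents, with idealized event times and zero curvature — the
#' kinematic screens then pass by construction and the dataset exercises the
#' report-level pipeline at scale.
#'
#' @param dataset a `vmr_dataset`.
#' @param ... passed to [reach_features()] in trace mode.
#' @return `data.frame` of features, one row per reach, keyed by `trial_id`.
#' @export
compute_features <- function(dataset, ...) {
  stopifnot(inherits(dataset, "vmr_dataset"))
  trials <- dataset$trials
  experiment <- dataset$config$experiment
  if (!is.null(dataset$traces)) {
    feats <- lapply(seq_len(nrow(trials)), function(i) {
      reach_features(dataset$traces[[trials$trial_id[i]]], trials[i, ],
                     experiment = experiment, ...)
    })
    do.call(rbind, feats)
  } else {
    raw <- trials$executed_direction_deg
    data.frame(
      trial_id = trials$trial_id,
      onset_ms = 60, offset_ms = 340, peak_speed_ms = 160,
      raw_direction_deg = raw,
      direction_deg = signed_direction(raw, trials$hand_target_deg,
                                       trials$rotation_dir, experiment),
      extent_cm = trials$extent_actual_cm,
      linearity_index = 0,
      duration_to_radius_ms = ifelse(trials$extent_actual_cm >= 10, 240,
                                     NA_real_),
      endpoint_x_cm = trials$endpoint_x_cm,
      endpoint_y_cm = trials$endpoint_y_cm,
      no_offset_flag = FALSE)
  }
}
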