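# Independent brute-force oracles and fixture builders used across tests.

# Build a vmr_trace from raw coordinates (1 ms sampling by default).
make_trace <- function(x, y, t = seq_along(x) - 1, home = c(0, 0)) {
  structure(list(samples = data.frame(t_ms = t, x_cm = x, y_cm = y),
                 home_xy_cm = home, trial_id = "fixture"),
            class = "vmr_trace")
}

# Plain sample-by-sample speed (central differences), written independently.
oracle_speed <- function(trace) {
  s <- trace$samples
  n <- nrow(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1)
    hi <- min(n, i + 1)
    dx <- s$x_cm[hi] - s$x_cm[lo]
    dy <- s$y_cm[hi] - s$y_cm[lo]
    out[i] <- sqrt(dx^2 + dy^2) / (s$t_ms[hi] - s$t_ms[lo]) * 1000
  }
  out
}

# Exhaustive scan: first sample with speed > vth AND radius > rth.
oracle_onset <- function(trace, vth = 5, rth = 0.5) {
  sp <- oracle_speed(trace)
  s <- trace$samples
  for (i in seq_len(nrow(s))) {
    r <- sqrt((s$x_cm[i] - trace$home_xy_cm[1])^2 +
                (s$y_cm[i] - trace$home_xy_cm[2])^2)
    if (sp[i] > vth && r > rth) return(s$t_ms[i])
  }
  NA_real_
}

# Exhaustive scan: first sub-threshold sample after the first post-onset
# speed peak; NA if speed never drops below threshold again.
oracle_offset <- function(trace, onset_ms, vth = 5) {
  sp <- oracle_speed(trace)
  t <- trace$samples$t_ms
  n <- length(sp)
  i0 <- which(t >= onset_ms)[1]
  k <- NA_integer_
  for (i in i0:n) {
    if (sp[i] > vth && (i == n || sp[i + 1] <= sp[i])) { k <- i; break }
  }
  if (is.na(k)) k <- i0
  if (k < n) {
    for (i in (k + 1):n) if (sp[i] < vth) return(t[i])
  }
  NA_real_
}

# Minimal trial table accepted by simulate_learner().
mini_schedule <- function(n, cycle_type = "adaptation", rotation_deg = 45,
                          rotation_dir = "ccw", hand_target = 20,
                          cursor_target = hand_target, feedback = TRUE,
                          subject = "S01") {
  data.frame(subject_id = subject,
             trial_id = sprintf("%s_t%03d", subject, seq_len(n)),
             cycle_type = cycle_type,
             rotation_dir = rotation_dir,
             rotation_applied_deg = rotation_deg,
             hand_target_base_deg = hand_target,
             hand_target_deg = hand_target,
             cursor_target_deg = cursor_target,
             feedback = feedback)
}

noiseless_params <- function(...) {
  defaults <- list(motor_noise_sd_deg = 0, strategy_noise_sd_deg = 0,
                   extent_sd_cm = 0, loc_bias_deg = 0, loc_sigma_deg = 1e-6,
                   radial_sigma_cm = 0)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
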