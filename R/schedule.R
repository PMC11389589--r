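#' Configure a cyclic visuomotor-rotation experiment
#'
#' Builds the design parameters for one of the three study layouts. All three
#' alternate short adaptation cycles (rotated cursor feedback) with washout
#' cycles (veridical feedback); each cycle comprises 2, 3, or 4 reaches in
#' total and ends with a no-feedback reach after which the unseen hand is
#' localized.
#'
#' Layouts:
#' * `exp1` (reaiming): rotation alternates CW/CCW across adaptation cycles;
#'   two targets (hand target and cursor target 45 deg apart, base directions
#'   20 and 65 deg CCW of midline, +/-7.5 deg jitter per cycle); participants
#'   re-aim at the hand target so the cursor hits the cursor target.
#' * `exp2` (aim-direct): CCW rotation only, a single target at 45 deg
#'   (+/-15 deg jitter); participants aim straight at the target, so learning
#'   is purely implicit.
#' * `exp3` (cued localization): CCW only, hand target 20 deg (+/-15 deg
#'   jitter), cursor target 45 deg CCW of it; localization trials are cued in
#'   advance.
#'
#' @param experiment one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param localization_method `"pointer"` or `"afc2"`. Defaults to the
#'   methods used in the study (`exp3` is pointer-only).
#' @param n_blocks number of adaptation/washout blocks. Defaults: 6 for
#'   pointer groups, 7 for 2AFC groups, 3 for `exp3`.
#' @param baseline_block prepend a block of veridical-feedback cycles
#'   (default `TRUE` only for the `exp1` pointer group, as in the study).
#' @param n_targets_on_localization number of targets displayed at the start
#'   of cued localization trials (`exp3` groups: 1 or 2).
#' @param cycles_per_type_per_block adaptation (and washout) cycles per block
#'   (default 18; must be divisible by the number of cycle lengths).
#' @param cycle_lengths admissible total reaches per cycle, localization
#'   reach included (default `c(2, 3, 4)`).
#' @param rotation_deg magnitude of the visuomotor rotation (default 45).
#' @param target_jitter_deg half-width of the uniform per-cycle target jitter.
#'   Defaults: 7.5 (`exp1`), 15 (`exp2`, `exp3`).
#' @param movement_distance_cm home-to-target distance (default 10).
#' @param target_radius_cm target radius (default 0.5).
#' @param home_xy_cm home position (analysis frame origin).
#' @return an object of class `vmr_config` (a list).
#' @seealso [make_schedule()], [simulate_experiment()]
#' @examples
#' cfg <- experiment_config("exp1", localization_method = "pointer")
#' cfg$n_blocks
#' @export
experiment_config <- function(experiment = c("exp1", "exp2", "exp3"),
                              localization_method = NULL,
                              n_blocks = NULL,
                              baseline_block = NULL,
                              n_targets_on_localization = 2L,
                              cycles_per_type_per_block = 18L,
                              cycle_lengths = c(2L, 3L, 4L),
                              rotation_deg = 45,
                              target_jitter_deg = NULL,
                              movement_distance_cm = 10,
                              target_radius_cm = 0.5,
                              home_xy_cm = c(0, 0)) {
  experiment <- match.arg(experiment)
  if (is.null(localization_method)) {
    localization_method <- "pointer"
  }
  localization_method <- match.arg(localization_method, c("pointer", "afc2"))
  if (experiment == "exp3" && localization_method != "pointer") {
    stop("exp3 uses the pointer method only", call. = FALSE)
  }
  if (is.null(n_blocks)) {
    n_blocks <- if (experiment == "exp3") 3L
      else if (localization_method == "pointer") 6L else 7L
  }
  if (is.null(baseline_block)) {
    baseline_block <- experiment == "exp1" && localization_method == "pointer"
  }
  if (is.null(target_jitter_deg)) {
    target_jitter_deg <- if (experiment == "exp1") 7.5 else 15
  }
  rotation_scheme <- if (experiment == "exp1") "alternating_cw_ccw" else "ccw_only"
  hand_target_deg <- switch(experiment,
    exp1 = c(ccw = 20, cw = 65),  # aim target by rotation direction
    exp2 = c(ccw = 45),
    exp3 = c(ccw = 20))

  cycle_lengths <- sort(unique(as.integer(cycle_lengths)))
  if (any(cycle_lengths < 2L)) {
    stop("cycle lengths must be at least 2 (the first reach never requires ",
         "localization)", call. = FALSE)
  }
  if (cycles_per_type_per_block %% length(cycle_lengths) != 0L) {
    stop("cycles_per_type_per_block (", cycles_per_type_per_block,
         ") is not divisible by the number of cycle lengths (",
         length(cycle_lengths), ")", call. = FALSE)
  }
  if (rotation_deg <= 0) stop("rotation_deg must be positive", call. = FALSE)
  if (target_jitter_deg < 0) stop("target_jitter_deg must be >= 0", call. = FALSE)
  if (!n_targets_on_localization %in% 1:2) {
    stop("n_targets_on_localization must be 1 or 2", call. = FALSE)
  }

  structure(list(
    experiment = experiment,
    localization_method = localization_method,
    n_blocks = as.integer(n_blocks),
    baseline_block = isTRUE(baseline_block),
    cycles_per_type_per_block = as.integer(cycles_per_type_per_block),
    cycle_lengths = cycle_lengths,
    rotation_deg = rotation_deg,
    rotation_scheme = rotation_scheme,
    hand_target_deg = hand_target_deg,
    target_jitter_deg = target_jitter_deg,
    cue_localization = experiment == "exp3",
    n_targets_on_localization = as.integer(n_targets_on_localization),
    movement_distance_cm = movement_distance_cm,
    target_radius_cm = target_radius_cm,
    home_xy_cm = home_xy_cm
  ), class = "vmr_config")
}

#' @export
print.vmr_config <- function(x, ...) {
  cat("<vmr_config> ", x$experiment, " / ", x$localization_method, "\n", sep = "")
  cat("  blocks: ", x$n_blocks,
      if (x$baseline_block) " (+ baseline block)", "\n", sep = "")
  cat("  cycles per type per block: ", x$cycles_per_type_per_block,
      ", lengths {", paste(x$cycle_lengths, collapse = ","), "}\n", sep = "")
  cat("  rotation: ", x$rotation_deg, " deg (", x$rotation_scheme, ")\n", sep = "")
  cat("  hand target(s): ", paste(x$hand_target_deg, collapse = ", "),
      " deg, jitter +/-", x$target_jitter_deg, " deg\n", sep = "")
  invisible(x)
}

# One row per cycle: type, length, governing rotation direction, targets.
build_cycles <- function(config) {
  n_per_len <- config$cycles_per_type_per_block / length(config$cycle_lengths)
  lens <- function() sample(rep(config$cycle_lengths, n_per_len))

  cyc <- list()
  if (config$baseline_block) {
    n_base <- 2L * config$cycles_per_type_per_block
    base_lens <- sample(rep(config$cycle_lengths,
                            n_base / length(config$cycle_lengths)))
    cyc[[1L]] <- data.frame(block = 0L, cycle_type = "baseline",
                            cycle_length = base_lens)
  }
  for (b in seq_len(config$n_blocks)) {
    la <- lens(); lw <- lens()
    k <- config$cycles_per_type_per_block
    cyc[[length(cyc) + 1L]] <- data.frame(
      block = b,
      cycle_type = rep(c("adaptation", "washout"), k),
      cycle_length = as.vector(rbind(la, lw)))
  }
  cycles <- do.call(rbind, cyc)
  cycles$cycle_index <- seq_len(nrow(cycles))

  # rotation direction per cycle
  if (config$rotation_scheme == "alternating_cw_ccw") {
    first_dir <- sample(c("cw", "ccw"), 1L)
    dirs <- rep(NA_character_, nrow(cycles))
    adapt <- which(cycles$cycle_type == "adaptation")
    dirs[adapt] <- rep(c(first_dir, setdiff(c("cw", "ccw"), first_dir)),
                       length.out = length(adapt))
    cycles$rotation_dir <- dirs
  } else {
    cycles$rotation_dir <- ifelse(cycles$cycle_type == "baseline",
                                  NA_character_, "ccw")
  }

  # targets + jitter; washout inherits the preceding adaptation cycle's
  # (jittered) target and governing direction, so its required movement
  # direction matches that cycle
  n <- nrow(cycles)
  cycles$hand_target_base_deg <- NA_real_
  cycles$hand_target_deg <- NA_real_
  cycles$cursor_target_deg <- NA_real_
  base_alt <- config$hand_target_deg[
    rep(seq_along(config$hand_target_deg),
        length.out = sum(cycles$cycle_type == "baseline"))]
  i_base <- 0L
  for (i in seq_len(n)) {
    type <- cycles$cycle_type[i]
    jit <- stats::runif(1, -config$target_jitter_deg, config$target_jitter_deg)
    if (type == "baseline") {
      i_base <- i_base + 1L
      base <- unname(base_alt[i_base])
      cycles$hand_target_base_deg[i] <- base
      cycles$hand_target_deg[i] <- base + jit
      cycles$cursor_target_deg[i] <- base + jit
      cycles$rotation_dir[i] <- "none"
    } else if (type == "adaptation") {
      dir <- cycles$rotation_dir[i]
      base <- if (config$experiment == "exp1") {
        unname(config$hand_target_deg[if (dir == "cw") "cw" else "ccw"])
      } else {
        unname(config$hand_target_deg[1L])
      }
      rot <- if (dir == "ccw") config$rotation_deg else -config$rotation_deg
      cycles$hand_target_base_deg[i] <- base
      cycles$hand_target_deg[i] <- base + jit
      cycles$cursor_target_deg[i] <- if (config$experiment == "exp2") {
        base + jit          # single displayed target; cursor error is read
      } else {              # against it even under rotation
        base + jit + rot
      }
    } else {  # washout
      if (config$experiment == "exp2") {
        base <- unname(config$hand_target_deg[1L])
        cycles$hand_target_base_deg[i] <- base
        cycles$hand_target_deg[i] <- base + jit
        cycles$cursor_target_deg[i] <- base + jit
        cycles$rotation_dir[i] <- "ccw"
      } else {
        # preceding cycle within the block is always an adaptation cycle
        cycles$hand_target_base_deg[i] <- cycles$hand_target_base_deg[i - 1L]
        cycles$hand_target_deg[i] <- cycles$hand_target_deg[i - 1L]
        cycles$cursor_target_deg[i] <- cycles$hand_target_deg[i - 1L]
        cycles$rotation_dir[i] <- cycles$rotation_dir[i - 1L]
      }
    }
  }
  cycles
}

#' Generate the trial-by-trial schedule for one subject
#'
#' Expands an [experiment_config()] into an ordered trial table: within each
#' block, adaptation and washout cycles strictly alternate, each cycle length
#' occurs equally often per cycle type, and the last reach of every cycle is a
#' no-feedback localization reach. In `exp1` the rotation direction reverses
#' between consecutive adaptation cycles, and each washout cycle inherits the
#' preceding adaptation cycle's target and governing rotation direction.
#'
#' @param config a `vmr_config`.
#' @param seed integer seed for the pseudorandom cycle-length order, rotation
#'   start direction, and target jitter; `NULL` uses the current RNG state.
#' @param subject_id subject identifier stored in the table.
#' @return a `data.frame` of class `vmr_schedule`, one row per reach, with
#'   columns `subject_id`, `block`, `cycle_index`, `cycle_type`,
#'   `cycle_length`, `reach_index_in_cycle`, `rotation_dir`,
#'   `rotation_applied_deg` (nominal cycle rotation, + = CCW),
#'   `hand_target_base_deg`, `hand_target_deg`, `cursor_target_deg`,
#'   `feedback`, `is_localization`, `localization_method`, `cue_localization`,
#'   `trial_id`.
#' @examples
#' sched <- make_schedule(experiment_config("exp1"), seed = 1)
#' table(sched$block)         # 108 reaches per rotation block
#' sum(sched$is_localization[sched$block == 1])  # 36
#' @export
make_schedule <- function(config, seed = NULL, subject_id = "S01") {
  stopifnot(inherits(config, "vmr_config"))
  if (!is.null(seed)) set.seed(seed)
  cycles <- build_cycles(config)

  reps <- cycles$cycle_length
  tr <- cycles[rep(seq_len(nrow(cycles)), reps), ]
  tr$reach_index_in_cycle <- unlist(lapply(reps, seq_len), use.names = FALSE)
  tr$is_localization <- tr$reach_index_in_cycle == tr$cycle_length
  tr$feedback <- !tr$is_localization
  tr$rotation_applied_deg <- ifelse(
    tr$cycle_type == "adaptation",
    ifelse(tr$rotation_dir == "ccw", config$rotation_deg, -config$rotation_deg),
    0)
  tr$localization_method <- ifelse(tr$is_localization,
                                   config$localization_method, NA_character_)
  tr$cue_localization <- config$cue_localization & tr$is_localization
  tr$subject_id <- subject_id
  tr$trial_id <- sprintf("%s_b%d_c%03d_r%d", subject_id, tr$block,
                         tr$cycle_index, tr$reach_index_in_cycle)
  rownames(tr) <- NULL
  tr <- tr[, c("subject_id", "trial_id", "block", "cycle_index", "cycle_type",
               "cycle_length", "reach_index_in_cycle", "rotation_dir",
               "rotation_applied_deg", "hand_target_base_deg",
               "hand_target_deg", "cursor_target_deg", "feedback",
               "is_localization", "localization_method", "cue_localization")]
  class(tr) <- c("vmr_schedule", "data.frame")
  attr(tr, "config") <- config
  tr
}
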