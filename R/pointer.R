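#' Angular and radial localization errors of pointer reports
#'
#' The angular error is the angle between the reported and the actual hand
#' position, both measured from the home position, wrapped to (-180, 180]
#' (positive = reported CCW of actual). The radial error is the difference in
#' radial distance.
#'
#' @param reports pointer reports with `reported_x_cm`, `reported_y_cm`,
#'   `actual_x_cm`, `actual_y_cm` relative to home.
#' @return the reports with `angular_error_deg` and `radial_error_cm` added.
#' @section Errors: a report at the home position (zero radius) has no
#'   defined angle and raises a condition of class `vmr_zero_radius`.
#' @export
angular_errors <- function(reports) {
  rep_r <- sqrt(reports$reported_x_cm^2 + reports$reported_y_cm^2)
  act_r <- sqrt(reports$actual_x_cm^2 + reports$actual_y_cm^2)
  if (any(rep_r < 1e-9) || any(act_r < 1e-9)) {
    stop(errorCondition(
      "report or endpoint at home position: angle undefined",
      class = c("vmr_zero_radius", "error", "condition")))
  }
  ang_rep <- xy_to_deg(reports$reported_x_cm, reports$reported_y_cm)
  ang_act <- xy_to_deg(reports$actual_x_cm, reports$actual_y_cm)
  out <- reports
  out$angular_error_deg <- wrap_deg(ang_rep - ang_act)
  out$radial_error_cm <- rep_r - act_r
  out
}

#' Sign-correct angular errors for rotation direction
#'
#' In designs with alternating rotation directions (`exp1`), the sign of
#' angular errors in cycles governed by a CW rotation is reversed, so that
#' positive always means "toward the rotated cursor". Washout cycles carry
#' the direction inherited from the preceding adaptation cycle (stored in the
#' schedule). CCW-only designs pass through unchanged.
#'
#' @param errors_deg numeric vector of angular errors.
#' @param rotation_dir `"cw"`, `"ccw"`, or `"none"` per error.
#' @return corrected errors.
#' @examples
#' sign_correct(c(-2, -2, 3), c("cw", "ccw", "none"))
#' @export
sign_correct <- function(errors_deg, rotation_dir) {
  ifelse(rotation_dir == "cw", -errors_deg, errors_deg)
}

loc_bins <- function(df, by_reach) {
  bins <- list(list(label = "all", rows = seq_len(nrow(df))))
  if (by_reach) {
    for (len in sort(unique(df$cycle_length))) {
      bins[[length(bins) + 1L]] <- list(label = as.character(len),
                                        rows = which(df$cycle_length == len))
    }
  }
  bins
}

#' Localization bias by cycle type and reach number
#'
#' Bias is the mean sign-corrected angular error, per subject, cycle type,
#' and reach number at which the hand was localized (= the cycle length, as
#' localization always follows the cycle's last reach), plus an `"all"` bin
#' pooling reach numbers.
#'
#' @param errors data frame with `subject_id`, `cycle_type`, `cycle_length`,
#'   and `error_deg` (screened, sign-corrected angular errors).
#' @param by_reach also emit per-reach-number bins (`TRUE` for `exp1`/`exp2`;
#'   `exp3` is summarized by cycle type only).
#' @return `data.frame` with `subject_id`, `cycle_type`, `reach_number`,
#'   `bias_deg`, `n_reports`. Empty bins are absent (with a warning).
#' @export
compute_bias <- function(errors, by_reach = TRUE) {
  out <- list()
  for (sid in unique(errors$subject_id)) {
    for (ct in unique(errors$cycle_type[errors$subject_id == sid])) {
      sub <- errors[errors$subject_id == sid & errors$cycle_type == ct, ]
      for (bin in loc_bins(sub, by_reach)) {
        if (length(bin$rows) == 0L) {
          warning("empty bin: ", sid, " ", ct, " reach ", bin$label,
                  call. = FALSE)
          next
        }
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, cycle_type = ct, reach_number = bin$label,
          bias_deg = mean(sub$error_deg[bin$rows]),
          n_reports = length(bin$rows))
      }
    }
  }
  do.call(rbind, out)
}

#' Localization variability (IQR) by cycle type and reach number
#'
#' Within each bin, the per-target bias (mean error for each hand target,
#' needed in `exp1` where the two targets can carry different residual
#' biases) is subtracted, residuals are pooled, and their interquartile range
#' is computed with the configured quartile convention.
#'
#' @param errors as in [compute_bias()], plus `hand_target_base_deg`.
#' @param by_reach see [compute_bias()].
#' @param qtype quartile convention (see [iqr_deg()]).
#' @param min_n bins with fewer reports are flagged `low_n` (default 4).
#' @return `data.frame` with `iqr_deg`, `n_reports`, and `low_n` per bin.
#' @export
compute_iqr <- function(errors, by_reach = TRUE, qtype = 7L, min_n = 4L) {
  out <- list()
  for (sid in unique(errors$subject_id)) {
    for (ct in unique(errors$cycle_type[errors$subject_id == sid])) {
      sub <- errors[errors$subject_id == sid & errors$cycle_type == ct, ]
      for (bin in loc_bins(sub, by_reach)) {
        if (length(bin$rows) == 0L) next
        e <- sub$error_deg[bin$rows]
        tgt <- sub$hand_target_base_deg[bin$rows]
        resid <- e - stats::ave(e, tgt, FUN = mean)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sid, cycle_type = ct, reach_number = bin$label,
          iqr_deg = iqr_deg(resid, qtype = qtype),
          n_reports = length(e), low_n = length(e) < min_n)
      }
    }
  }
  do.call(rbind, out)
}

#' Pointer performance score
#'
#' 100 points for a pointer placed exactly on the hand, 0 points at 10 cm or
#' more, linear in between. Block scores are the sum over the block's 36
#' localizations.
#'
#' @param distance_cm non-negative pointer-to-hand distances.
#' @return scores in points (same length as `distance_cm`).
#' @examples
#' performance_score(c(0, 5, 10, 12))
#' @export
performance_score <- function(distance_cm) {
  if (any(distance_cm < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  pmax(0, 100 * (1 - distance_cm / 10))
}

#' Adaptation aftereffects by preceding cycle length
#'
#' The aftereffect is the mean signed movement direction of the first reach
#' of washout cycles (positive = residual deviation opposite the preceding
#' rotation), split by the length of the immediately preceding adaptation
#' cycle (2, 3, or 4 total reaches, i.e. 1, 2, or 3 rotated feedback
#' reaches). Growth across 2 -> 3 -> 4 is the kinematic signature of gradual
#' implicit learning.
#'
#' @param trials trial table (schedule columns) merged with `direction_deg`
#'   and `kept` (from screening).
#' @return per-subject `data.frame` with `preceding_cycle_length`,
#'   `aftereffect_deg`, `n`; the across-subject means are in the
#'   `"group"` attribute.
#' @export
aftereffect_table <- function(trials) {
  w1 <- trials$cycle_type == "washout" & trials$reach_index_in_cycle == 1L &
    trials$kept
  if (!any(w1)) return(NULL)
  wt <- trials[w1, ]
  # the preceding cycle of a washout cycle is the block's adaptation cycle
  key <- paste(trials$subject_id, trials$cycle_index)
  prev_len <- trials$cycle_length[match(paste(wt$subject_id,
                                              wt$cycle_index - 1L), key)]
  wt$preceding_cycle_length <- prev_len
  agg <- stats::aggregate(direction_deg ~ subject_id + preceding_cycle_length,
                          data = wt, FUN = mean)
  names(agg)[names(agg) == "direction_deg"] <- "aftereffect_deg"
  nagg <- stats::aggregate(direction_deg ~ subject_id + preceding_cycle_length,
                           data = wt, FUN = length)
  agg$n <- nagg$direction_deg
  grp <- stats::aggregate(aftereffect_deg ~ preceding_cycle_length,
                          data = agg, FUN = mean)
  attr(agg, "group") <- grp
  agg
}
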