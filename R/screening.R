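#' Screen reaches on kinematic criteria
#'
#' Applies the study's reach-rejection rules, each evaluated independently so
#' every applicable reason is recorded:
#' * `too_slow` — more than 300 ms from onset to crossing the target-distance
#'   radius (or the radius was never crossed);
#' * `curved` — linearity index strictly greater than 0.2;
#' * `wrong_target` — (`exp1` only, where two targets are displayed) signed
#'   movement direction relative to the instructed aim below -30 deg.
#'
#' @param features reach-features table from [compute_features()] /
#'   [reach_features()] (needs `duration_to_radius_ms`, `linearity_index`,
#'   `direction_deg`).
#' @param experiment experiment id; the wrong-target rule fires only for
#'   `"exp1"`.
#' @param li_max linearity-index threshold (default 0.2).
#' @param max_duration_ms onset-to-radius limit in ms (default 300).
#' @param wrong_target_deg wrong-target threshold (default -30).
#' @return `data.frame` with `trial_id`, logical reason columns, `reasons`
#'   (comma-separated), and `kept` (`TRUE` iff no reason fired).
#' @examples
#' f <- data.frame(trial_id = "t1", duration_to_radius_ms = 320,
#'                 linearity_index = 0.1, direction_deg = 0)
#' screen_reaches(f, "exp2")$reasons
#' @export
screen_reaches <- function(features, experiment, li_max = 0.2,
                           max_duration_ms = 300, wrong_target_deg = -30) {
  too_slow <- is.na(features$duration_to_radius_ms) |
    features$duration_to_radius_ms > max_duration_ms
  curved <- features$linearity_index > li_max
  wrong_target <- if (identical(experiment, "exp1")) {
    !is.na(features$direction_deg) & features$direction_deg < wrong_target_deg
  } else rep(FALSE, nrow(features))

  reasons <- mapply(function(s, c, w) {
    paste(c("too_slow", "curved", "wrong_target")[c(s, c, w)], collapse = ",")
  }, too_slow, curved, wrong_target)
  data.frame(trial_id = features$trial_id,
             too_slow = too_slow, curved = curved,
             wrong_target = wrong_target,
             reasons = reasons,
             kept = !(too_slow | curved | wrong_target))
}

#' Screen pointer localization reports
#'
#' Flags reports whose radial component betrays a premature pedal press or an
#' outlying radial error, in a single pass per subject:
#' * `radial_low` — the reported radial distance is less than half the actual
#'   movement extent (the reported position sits near the start of the reach);
#' * `radial_outlier` — the absolute radial error exceeds twice the standard
#'   deviation of all of that subject's radial errors (SD computed once over
#'   all reports, before any removal, and stored in the result so screening
#'   the kept set again removes nothing).
#'
#' @param reports pointer reports with `subject_id`, `reported_x_cm`,
#'   `reported_y_cm`, `actual_x_cm`, `actual_y_cm` (positions relative to
#'   home).
#' @param sd_scope `"subject"` (default) computes the 2xSD threshold per
#'   subject; `"pooled"` uses one SD across all subjects.
#' @return the reports with `radial_error_cm`, logical reason columns,
#'   `sd_used_cm`, `reasons`, and `kept`.
#' @section Warnings: subjects with fewer than 3 reports get the SD rule
#'   skipped (with a warning); the `radial_low` rule, which needs no SD, is
#'   still applied.
#' @export
screen_pointer_reports <- function(reports, sd_scope = c("subject", "pooled")) {
  sd_scope <- match.arg(sd_scope)
  rep_r <- sqrt(reports$reported_x_cm^2 + reports$reported_y_cm^2)
  act_r <- sqrt(reports$actual_x_cm^2 + reports$actual_y_cm^2)
  radial_error <- rep_r - act_r
  radial_low <- rep_r < 0.5 * act_r

  grp <- if (sd_scope == "subject") reports$subject_id
    else rep("all", nrow(reports))
  sd_used <- stats::ave(radial_error, grp,
                        FUN = function(x) if (length(x) >= 3L) stats::sd(x)
                          else NA_real_)
  skipped <- unique(grp[is.na(sd_used)])
  if (length(skipped) > 0L) {
    warning("fewer than 3 reports for ", paste(skipped, collapse = ", "),
            ": 2xSD outlier screening skipped", call. = FALSE)
  }
  # sd_used == 0 (all radial errors identical) defines no outliers
  radial_outlier <- !is.na(sd_used) & sd_used > 0 &
    abs(radial_error) > 2 * sd_used

  out <- reports
  out$radial_error_cm <- radial_error
  out$radial_low <- radial_low
  out$radial_outlier <- radial_outlier
  out$sd_used_cm <- sd_used
  out$reasons <- mapply(function(l, o) {
    paste(c("radial_low", "radial_outlier")[c(l, o)], collapse = ",")
  }, radial_low, radial_outlier)
  out$kept <- !(radial_low | radial_outlier)
  out
}

#' Tabulate exclusions per subject and reason
#'
#' @param screen a screening result from [screen_reaches()] or
#'   [screen_pointer_reports()].
#' @param subject_id optional subject vector aligned with `screen` (used when
#'   the table has no `subject_id` column).
#' @return `data.frame` of counts per subject and reason, plus totals.
#' @export
exclusion_summary <- function(screen, subject_id = NULL) {
  sid <- screen$subject_id %||% subject_id %||% rep("all", nrow(screen))
  reason_cols <- intersect(c("too_slow", "curved", "wrong_target",
                             "radial_low", "radial_outlier"), names(screen))
  agg <- stats::aggregate(screen[reason_cols], by = list(subject_id = sid),
                          FUN = sum)
  agg$n_input <- as.vector(table(sid)[agg$subject_id])
  agg$n_kept <- stats::aggregate(screen$kept, by = list(sid), FUN = sum)$x
  agg
}
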