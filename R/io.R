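trial_required_cols <- c(
  "subject_id", "trial_id", "block", "cycle_index", "cycle_type",
  "cycle_length", "reach_index_in_cycle", "rotation_dir",
  "rotation_applied_deg", "hand_target_base_deg", "hand_target_deg",
  "cursor_target_deg", "feedback", "is_localization")

#' Write a dataset bundle to plain-text files
#'
#' Persists a [simulate_experiment()] bundle as diffable CSV/YAML: the trial
#' table, the localization reports, one CSV per kinematic trace (with a
#' manifest), the configuration, and a ground-truth sidecar for parameter
#' recovery.
#'
#' @param dataset a `vmr_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "vmr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$reports, file.path(dir, "reports.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  yaml::write_yaml(list(
    config = list(
      experiment = cfg$experiment,
      localization_method = cfg$localization_method,
      n_blocks = cfg$n_blocks, baseline_block = cfg$baseline_block,
      n_targets_on_localization = cfg$n_targets_on_localization,
      cycles_per_type_per_block = cfg$cycles_per_type_per_block,
      cycle_lengths = cfg$cycle_lengths, rotation_deg = cfg$rotation_deg,
      target_jitter_deg = cfg$target_jitter_deg),
    params = unclass(dataset$params)
  ), file.path(dir, "config.yaml"))
  yaml::write_yaml(lapply(dataset$ground_truth, as.list),
                   file.path(dir, "ground_truth.yaml"))
  if (!is.null(dataset$traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    manifest <- data.frame(trial_id = names(dataset$traces),
                           file = file.path("traces",
                                            paste0(names(dataset$traces),
                                                   ".csv")))
    for (id in names(dataset$traces)) {
      utils::write.csv(dataset$traces[[id]]$samples,
                       file.path(tdir, paste0(id, ".csv")), row.names = FALSE)
    }
    utils::write.csv(manifest, file.path(dir, "trace_manifest.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read and validate a dataset bundle
#'
#' Loads a bundle written by [write_dataset()] (or an external dataset in the
#' same layout), validating the trial-table schema (required columns, enum
#' values, with offending row numbers), the report table, and — if a trace
#' manifest is present — the uniform 1 ms sampling of every trace. All
#' violations are collected and reported in a single load error.
#'
#' @param dir directory containing `trials.csv` (and optionally
#'   `reports.csv`, `config.yaml`, `ground_truth.yaml`,
#'   `trace_manifest.csv`).
#' @return a `vmr_dataset`.
#' @export
read_dataset <- function(dir) {
  problems <- character()
  tf <- file.path(dir, "trials.csv")
  if (!file.exists(tf)) stop("load error: missing trials.csv in ", dir,
                             call. = FALSE)
  trials <- utils::read.csv(tf, stringsAsFactors = FALSE)
  missing <- setdiff(trial_required_cols, names(trials))
  if (length(missing)) {
    problems <- c(problems, paste0("trials.csv: missing columns ",
                                   paste(missing, collapse = ", ")))
  } else {
    bad_ct <- which(!trials$cycle_type %in%
                      c("baseline", "adaptation", "washout"))
    if (length(bad_ct)) {
      problems <- c(problems, paste0("trials.csv: unknown cycle_type at rows ",
                                     paste(utils::head(bad_ct, 10),
                                           collapse = ", ")))
    }
    bad_rd <- which(!trials$rotation_dir %in% c("cw", "ccw", "none"))
    if (length(bad_rd)) {
      problems <- c(problems,
                    paste0("trials.csv: unknown rotation_dir at rows ",
                           paste(utils::head(bad_rd, 10), collapse = ", ")))
    }
  }

  rf <- file.path(dir, "reports.csv")
  reports <- if (file.exists(rf) && file.size(rf) > 1) {
    r <- tryCatch(utils::read.csv(rf, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(r)) data.frame() else r
  } else data.frame()

  cf <- file.path(dir, "config.yaml")
  config <- params <- NULL
  if (file.exists(cf)) {
    raw <- yaml::read_yaml(cf)
    config <- tryCatch(do.call(experiment_config, raw$config),
                       error = function(e) {
                         problems <<- c(problems,
                                        paste0("config.yaml: ",
                                               conditionMessage(e)))
                         NULL
                       })
    if (!is.null(raw$params)) {
      pr <- raw$params
      for (nm in c("loc_bias_deg", "loc_sigma_deg", "afc_slope_per_deg")) {
        if (!is.null(pr[[nm]])) pr[[nm]] <- unlist(pr[[nm]])
      }
      pr <- pr[names(pr) %in% names(formals(sim_params))]
      pr$experiment <- NULL
      params <- tryCatch(do.call(sim_params, pr), error = function(e) NULL)
    }
  }

  traces <- NULL
  mf <- file.path(dir, "trace_manifest.csv")
  if (file.exists(mf)) {
    manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
    traces <- list()
    dt_ms <- if (!is.null(params)) 1000 / params$sample_rate_hz else 1
    for (i in seq_len(nrow(manifest))) {
      samp <- utils::read.csv(file.path(dir, manifest$file[i]),
                              stringsAsFactors = FALSE)
      gaps <- which(abs(diff(samp$t_ms) - dt_ms) > 1e-9)
      if (length(gaps)) {
        problems <- c(problems,
                      paste0("trace ", manifest$trial_id[i],
                             ": non-uniform sampling at sample(s) ",
                             paste(utils::head(gaps, 5), collapse = ", ")))
        next
      }
      traces[[manifest$trial_id[i]]] <- structure(
        list(samples = samp, home_xy_cm = c(0, 0),
             trial_id = manifest$trial_id[i]), class = "vmr_trace")
    }
  }

  if (length(problems)) {
    stop("load error:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }

  gf <- file.path(dir, "ground_truth.yaml")
  gt <- if (file.exists(gf)) {
    lapply(yaml::read_yaml(gf), unlist)
  } else NULL
  structure(list(trials = trials, reports = reports, traces = traces,
                 config = config, params = params, ground_truth = gt),
            class = "vmr_dataset")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stage order of the study's analysis: reach features ->
#' kinematic screening -> aftereffect table -> (pointer) angular errors,
#' report screening, sign correction, bias and IQR summaries, performance
#' scores, and per-subject variability matching, or (2AFC) psychometric fits
#' with PSE-alignment pooling. Localization reports of kinematically rejected
#' reaches are excluded from the perceptual analyses.
#'
#' @param x a `vmr_dataset`, or a directory path readable by
#'   [read_dataset()].
#' @param qtype quartile convention for all IQRs.
#' @param by_reach bin localization summaries by reach number; defaults to
#'   `TRUE` except for `exp3` (summarized by cycle type only).
#' @param match run the variability-matching control (pointer designs with
#'   both adaptation and washout reports).
#' @param match_floor minimum trials per cycle type for matching.
#' @param out_dir optional directory to which tidy CSV outputs are written
#'   (summaries, screening results, exclusion log, match results).
#' @return an object of class `vmr_report`; see Details.
#' @details The report bundles `features`, `reach_screen`, `exclusions`,
#'   `aftereffects`, and, depending on the method, `bias`, `iqr`,
#'   `group_localization`, `scores`, `report_screen`, `match`
#'   (per-subject [match_variability()] results plus a summary table), or
#'   `psychometrics` (per-subject PSE/JND with group summary attribute).
#' @examples
#' ds <- simulate_experiment(experiment_config("exp2"),
#'                           sim_params("exp2", seed = 1))
#' rep <- run_pipeline(ds)
#' rep$group_localization
#' @export
run_pipeline <- function(x, qtype = 7L, by_reach = NULL, match = TRUE,
                         match_floor = 8L, out_dir = NULL) {
  ds <- if (inherits(x, "vmr_dataset")) x else read_dataset(x)
  experiment <- ds$config$experiment
  method <- ds$config$localization_method
  if (is.null(by_reach)) by_reach <- experiment != "exp3"

  feats <- compute_features(ds)
  rscreen <- screen_reaches(feats, experiment)
  trials <- ds$trials
  idx <- match(trials$trial_id, feats$trial_id)
  trials$direction_deg <- feats$direction_deg[idx]
  trials$kept <- rscreen$kept[idx]

  aft <- aftereffect_table(trials)
  exclusions <- exclusion_summary(
    cbind(rscreen, subject_id = trials$subject_id[match(rscreen$trial_id,
                                                        trials$trial_id)]))

  out <- list(experiment = experiment, method = method, config = ds$config,
              features = feats, reach_screen = rscreen,
              exclusions = exclusions, aftereffects = aft)

  reports <- ds$reports
  if (nrow(reports) > 0) {
    reports$reach_kept <- trials$kept[match(reports$trial_id,
                                            trials$trial_id)]
    reports <- reports[reports$reach_kept, , drop = FALSE]
  }

  if (method == "pointer" && nrow(reports) > 0) {
    reports <- angular_errors(reports)
    pscreen <- screen_pointer_reports(reports)
    out$report_screen <- pscreen
    out$exclusions_reports <- exclusion_summary(pscreen)
    kept <- pscreen[pscreen$kept, , drop = FALSE]
    kept$error_deg <- sign_correct(kept$angular_error_deg, kept$rotation_dir)

    out$bias <- compute_bias(kept, by_reach = by_reach)
    out$iqr <- compute_iqr(kept, by_reach = by_reach, qtype = qtype)

    allb <- out$bias[out$bias$reach_number == "all", ]
    alli <- out$iqr[out$iqr$reach_number == "all", ]
    out$group_localization <- do.call(rbind, lapply(
      split(allb, allb$cycle_type), function(d) {
        i <- alli[alli$cycle_type == d$cycle_type[1], ]
        data.frame(cycle_type = d$cycle_type[1],
                   bias_mean = mean(d$bias_deg), bias_sd = stats::sd(d$bias_deg),
                   bias_median = stats::median(d$bias_deg),
                   bias_iqr = iqr_deg(d$bias_deg, qtype = qtype),
                   iqr_mean = mean(i$iqr_deg),
                   iqr_median = stats::median(i$iqr_deg),
                   iqr_iqr = iqr_deg(i$iqr_deg, qtype = qtype),
                   n_subjects = nrow(d))
      }))
    rownames(out$group_localization) <- NULL

    dist <- sqrt((pscreen$reported_x_cm - pscreen$actual_x_cm)^2 +
                   (pscreen$reported_y_cm - pscreen$actual_y_cm)^2)
    pscreen$score <- performance_score(dist)
    out$scores <- stats::aggregate(score ~ subject_id + block, data = pscreen,
                                   FUN = sum)

    if (match) {
      out$match <- list()
      msum <- list()
      for (sid in unique(kept$subject_id)) {
        sub <- kept[kept$subject_id == sid, ]
        sub$hand_dir <- trials$direction_deg[match(sub$trial_id,
                                                   trials$trial_id)]
        a <- sub[sub$cycle_type == "adaptation", ]
        w <- sub[sub$cycle_type == "washout", ]
        if (nrow(a) < match_floor || nrow(w) < match_floor) next
        m <- match_variability(a$hand_dir, w$hand_dir,
                               a$error_deg, w$error_deg,
                               floor = match_floor, qtype = qtype)
        out$match[[sid]] <- m
        msum[[sid]] <- data.frame(
          subject_id = sid, converged = m$converged,
          removed = m$removed_adaptation + m$removed_washout,
          remaining = sum(m$remaining), iterations = m$iterations,
          handpos_iqr_adapt = m$handpos_iqr_deg["adaptation"],
          handpos_iqr_wash = m$handpos_iqr_deg["washout"],
          loc_iqr_adapt = m$loc_iqr_deg["adaptation"],
          loc_iqr_wash = m$loc_iqr_deg["washout"])
      }
      out$match_summary <- if (length(msum)) {
        s <- do.call(rbind, msum)
        rownames(s) <- NULL
        s
      } else NULL
    }
  } else if (method == "afc2" && nrow(reports) > 0) {
    out$psychometrics <- psychometric_summary(reports)
  }

  class(out) <- "vmr_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.vmr_report <- function(x, digits = 3, ...) {
  cat("<vmr_report> ", x$experiment, " / ", x$method, "\n", sep = "")
  cat("  reaches: ", nrow(x$features), " (",
      sum(x$reach_screen$kept), " kept)\n", sep = "")
  if (!is.null(x$group_localization)) {
    cat("  localization (pointer), across subjects:\n")
    g <- x$group_localization
    for (i in seq_len(nrow(g))) {
      cat(sprintf("    %-10s bias %s deg (median %s), IQR %s deg (median)\n",
                  g$cycle_type[i], format(g$bias_mean[i], digits = digits),
                  format(g$bias_median[i], digits = digits),
                  format(g$iqr_median[i], digits = digits)))
    }
  }
  if (!is.null(x$psychometrics)) {
    g <- attr(x$psychometrics, "group")
    cat("  psychometrics (2AFC), across subjects:\n")
    for (i in seq_len(nrow(g))) {
      cat(sprintf("    %-10s PSE %s deg, JND %s deg (means)\n",
                  g$cycle_type[i], format(g$pse_mean[i], digits = digits),
                  format(g$jnd_mean[i], digits = digits)))
    }
  }
  if (!is.null(x$aftereffects)) {
    g <- attr(x$aftereffects, "group")
    cat("  aftereffect by preceding cycle length: ",
        paste(sprintf("%s: %s", g$preceding_cycle_length,
                      format(g$aftereffect_deg, digits = digits)),
              collapse = ", "), " deg\n", sep = "")
  }
  if (!is.null(x$match_summary)) {
    cat("  matching: ", sum(x$match_summary$converged), "/",
        nrow(x$match_summary), " subjects matched, median removed ",
        stats::median(x$match_summary$removed), " trials\n", sep = "")
  }
  invisible(x)
}

# tidy CSV export surface for external inferential statistics
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name),
                                       row.names = FALSE)
  }
  w(report$reach_screen, "reach_screen.csv")
  w(report$exclusions, "exclusions_reaches.csv")
  w(report$exclusions_reports, "exclusions_reports.csv")
  w(report$bias, "localization_bias.csv")
  w(report$iqr, "localization_iqr.csv")
  w(report$group_localization, "group_localization.csv")
  w(report$psychometrics, "psychometrics.csv")
  w(report$aftereffects, "aftereffects.csv")
  w(report$match_summary, "match_summary.csv")
  w(report$scores, "block_scores.csv")
  invisible(out_dir)
}
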