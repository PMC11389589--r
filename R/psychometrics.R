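#' Fit a logistic psychometric function to 2AFC reports
#'
#' Maximum-likelihood logistic regression (binomial GLM, logit link) of the
#' probability of reporting the probe "left" (CCW) of the hand as a function
#' of the probe's angular offset. The point of subjective equivalence (PSE)
#' is the offset at which "left" is expected in 50% of trials,
#' `-intercept / slope`; the just noticeable difference (JND) is the distance
#' between the 75% and 25% offsets, `2 ln 3 / slope`.
#'
#' If the responses are perfectly separated (the GLM diverges), the fit is
#' rerun with a weak ridge penalty on the slope and `separation_flag` is
#' raised. A non-positive or vanishing slope yields an infinite JND and the
#' `degenerate_flag`.
#'
#' @param probe_offset_deg signed probe offsets (deg; + = CCW of the hand).
#' @param response_left logical (or 0/1) "left" responses.
#' @param ridge_lambda ridge weight used only under separation.
#' @return an object of class `psychfit` with components `coefficients`
#'   (intercept, slope), `pse_deg`, `jnd_deg`, `n_trials`, `converged`,
#'   `separation_flag`, `degenerate_flag`, `data`, and (when the unpenalized
#'   fit succeeds) the underlying `glm`.
#' @examples
#' set.seed(1)
#' off <- rep(c(-20, -10, -3.33, 3.33, 10, 20), each = 30)
#' y <- runif(length(off)) < plogis(0.22 * off)
#' fit <- fit_psychometric(off, y)
#' coef(fit); fit$pse_deg; fit$jnd_deg
#' @seealso [align_and_pool()], [psychometric_summary()]
#' @export
fit_psychometric <- function(probe_offset_deg, response_left,
                             ridge_lambda = 0.01) {
  stopifnot(length(probe_offset_deg) == length(response_left))
  y <- as.integer(response_left)
  stopifnot(all(y %in% 0:1))
  if (length(unique(probe_offset_deg)) < 2L) {
    stop("need at least 2 distinct probe offsets to fit a psychometric curve",
         call. = FALSE)
  }
  dat <- data.frame(probe_offset_deg = probe_offset_deg, response_left = y)

  separation <- FALSE
  gfit <- withCallingHandlers(
    stats::glm(response_left ~ probe_offset_deg, family = stats::binomial(),
               data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(gfit)
  converged <- gfit$converged
  if (separation || !converged || abs(beta[2]) > 50) {
    separation <- TRUE
    # weak ridge on the slope keeps the likelihood proper under separation
    nll <- function(b) {
      eta <- b[1] + b[2] * dat$probe_offset_deg
      -sum(stats::dbinom(dat$response_left, 1, stats::plogis(eta), log = TRUE)) +
        ridge_lambda * b[2]^2
    }
    opt <- stats::optim(c(0, 0.1), nll, method = "BFGS")
    beta <- opt$par
    converged <- opt$convergence == 0L
    gfit <- NULL
  }
  names(beta) <- c("(Intercept)", "probe_offset_deg")
  slope <- unname(beta[2])
  pse <- -unname(beta[1]) / slope
  jnd <- if (slope > 0) 2 * log(3) / slope else Inf

  structure(list(
    coefficients = beta,
    pse_deg = pse,
    jnd_deg = jnd,
    n_trials = nrow(dat),
    converged = converged,
    separation_flag = separation,
    degenerate_flag = !is.finite(jnd) || jnd > 140,  # arc spans 140 deg
    data = dat,
    glm = gfit
  ), class = "psychfit")
}

#' @export
print.psychfit <- function(x, digits = 3, ...) {
  cat("Psychometric fit (logistic, ", x$n_trials, " trials)\n", sep = "")
  cat("  PSE: ", format(x$pse_deg, digits = digits),
      " deg   JND: ", format(x$jnd_deg, digits = digits), " deg\n", sep = "")
  cat("  slope: ", format(x$coefficients[2], digits = digits),
      " /deg   intercept: ", format(x$coefficients[1], digits = digits),
      "\n", sep = "")
  flags <- c("separation"[x$separation_flag], "degenerate"[x$degenerate_flag],
             "not converged"[!x$converged])
  if (length(flags)) cat("  flags: ", paste(flags, collapse = ", "), "\n",
                         sep = "")
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
summary.psychfit <- function(object, ...) {
  se <- if (!is.null(object$glm)) {
    sqrt(diag(stats::vcov(object$glm)))
  } else c(NA_real_, NA_real_)
  structure(list(
    coefficients = cbind(Estimate = object$coefficients, `Std. Error` = se),
    pse_deg = object$pse_deg, jnd_deg = object$jnd_deg,
    n_trials = object$n_trials, converged = object$converged,
    separation_flag = object$separation_flag,
    degenerate_flag = object$degenerate_flag
  ), class = "summary.psychfit")
}

#' @export
print.summary.psychfit <- function(x, digits = 3, ...) {
  cat("Logistic psychometric function,", x$n_trials, "trials\n")
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "-")
  cat("PSE:", format(x$pse_deg, digits = digits), "deg;  JND:",
      format(x$jnd_deg, digits = digits), "deg\n")
  invisible(x)
}

#' @rdname fit_psychometric
#' @param object,x a `psychfit`.
#' @param newdata probe offsets at which to evaluate the curve; defaults to
#'   the fitted offsets.
#' @param ... unused.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  off <- if (is.null(newdata)) object$data$probe_offset_deg
    else as.numeric(newdata)
  stats::plogis(object$coefficients[1] + object$coefficients[2] * off)
}

#' @export
residuals.psychfit <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  p <- predict(object)
  y <- object$data$response_left
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p)))
}

#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  out <- as.data.frame(replicate(nsim, stats::runif(length(p)) < p))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
logLik.psychfit <- function(object, ...) {
  p <- predict(object)
  y <- object$data$response_left
  structure(sum(y * log(p) + (1 - y) * log1p(-p)),
            df = 2L, nobs = object$n_trials, class = "logLik")
}

#' @export
plot.psychfit <- function(x, ...) {
  agg <- stats::aggregate(response_left ~ probe_offset_deg, data = x$data,
                          FUN = mean)
  xs <- seq(min(agg$probe_offset_deg) - 2, max(agg$probe_offset_deg) + 2,
            length.out = 200)
  graphics::plot(agg$probe_offset_deg, agg$response_left, ylim = c(0, 1),
                 xlab = "probe offset (deg, + = CCW)",
                 ylab = "P(report 'left')", pch = 19, ...)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = c(0.25, 0.5, 0.75), lty = 3, col = "grey")
  graphics::abline(v = x$pse_deg, lty = 2)
  invisible(x)
}

#' Align two per-target psychometric curves and pool them
#'
#' For designs with two targets (one per rotation direction), the per-target
#' PSE is first subtracted from that target's probe offsets, shifting both
#' psychometric curves to cross 50% at zero; the shifted data are pooled and
#' a joint curve is fit, whose JND is the reported localization variability
#' (the joint PSE is ~0 by construction). With a single set of reports the
#' function is a pass-through fit.
#'
#' @param reports1,reports2 data frames with `probe_offset_deg` and
#'   `response_left`; `reports2 = NULL` for single-target designs.
#' @param ... passed to [fit_psychometric()].
#' @return a list of class `psychfit_pool`: `per_target` (list of
#'   `psychfit`), `shifts_deg`, and `joint` (a `psychfit`, or `NULL` with a
#'   `reason` if a per-target fit failed).
#' @export
align_and_pool <- function(reports1, reports2 = NULL, ...) {
  fits <- list()
  f1 <- tryCatch(fit_psychometric(reports1$probe_offset_deg,
                                  reports1$response_left, ...),
                 error = function(e) e)
  if (inherits(f1, "error")) {
    return(structure(list(per_target = list(), shifts_deg = numeric(),
                          joint = NULL, reason = conditionMessage(f1)),
                     class = "psychfit_pool"))
  }
  fits[[1]] <- f1
  if (is.null(reports2)) {
    return(structure(list(per_target = fits, shifts_deg = 0, joint = f1,
                          reason = NULL), class = "psychfit_pool"))
  }
  f2 <- tryCatch(fit_psychometric(reports2$probe_offset_deg,
                                  reports2$response_left, ...),
                 error = function(e) e)
  if (inherits(f2, "error")) {
    return(structure(list(per_target = fits, shifts_deg = f1$pse_deg,
                          joint = NULL, reason = conditionMessage(f2)),
                     class = "psychfit_pool"))
  }
  fits[[2]] <- f2
  off <- c(reports1$probe_offset_deg - f1$pse_deg,
           reports2$probe_offset_deg - f2$pse_deg)
  y <- c(reports1$response_left, reports2$response_left)
  joint <- fit_psychometric(off, y, ...)
  structure(list(per_target = fits,
                 shifts_deg = c(f1$pse_deg, f2$pse_deg),
                 joint = joint, reason = NULL),
            class = "psychfit_pool")
}

#' @export
print.psychfit_pool <- function(x, digits = 3, ...) {
  cat("Aligned/pooled psychometric fit (", length(x$per_target),
      " target(s))\n", sep = "")
  if (!is.null(x$joint)) {
    cat("  per-target PSEs: ",
        paste(format(x$shifts_deg, digits = digits), collapse = ", "),
        " deg\n  joint JND: ", format(x$joint$jnd_deg, digits = digits),
        " deg\n", sep = "")
  } else {
    cat("  joint fit skipped: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Per-subject PSE and JND by cycle type
#'
#' Fits one psychometric curve per subject, cycle type, and (for two-target
#' designs) target, pooling reports across blocks. The reported bias is the
#' mean sign-corrected per-target PSE (the sign of the PSE from the target
#' governed by CW rotation is reversed, so positive means toward the
#' cursor); the reported JND comes from the PSE-aligned pooled fit.
#'
#' @param reports 2AFC reports with `subject_id`, `cycle_type`,
#'   `hand_target_base_deg`, `rotation_dir`, `probe_offset_deg`,
#'   `response_left`.
#' @param ... passed to [fit_psychometric()].
#' @return tidy `data.frame` with one row per subject x cycle type
#'   (`pse_deg`, `jnd_deg`, `n_trials`, flags); group-level mean/SD and
#'   median/IQR per cycle type in the `"group"` attribute.
#' @export
psychometric_summary <- function(reports, ...) {
  out <- list()
  for (sid in unique(reports$subject_id)) {
    for (ct in unique(reports$cycle_type[reports$subject_id == sid])) {
      sub <- reports[reports$subject_id == sid & reports$cycle_type == ct, ]
      targets <- sort(unique(sub$hand_target_base_deg))
      if (length(targets) >= 2L) {
        r1 <- sub[sub$hand_target_base_deg == targets[1], ]
        r2 <- sub[sub$hand_target_base_deg == targets[2], ]
        pool <- align_and_pool(r1, r2, ...)
        if (is.null(pool$joint)) next
        s1 <- cursor_sign(r1$rotation_dir[1])
        s2 <- cursor_sign(r2$rotation_dir[1])
        pse <- mean(c(s1 * pool$per_target[[1]]$pse_deg,
                      s2 * pool$per_target[[2]]$pse_deg))
        jnd <- pool$joint$jnd_deg
        flags <- any(vapply(pool$per_target, function(f) f$separation_flag,
                            logical(1))) || pool$joint$separation_flag
        degen <- pool$joint$degenerate_flag
      } else {
        fit <- tryCatch(fit_psychometric(sub$probe_offset_deg,
                                         sub$response_left, ...),
                        error = function(e) NULL)
        if (is.null(fit)) next
        pse <- cursor_sign(sub$rotation_dir[1]) * fit$pse_deg
        jnd <- fit$jnd_deg
        flags <- fit$separation_flag
        degen <- fit$degenerate_flag
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, cycle_type = ct, pse_deg = pse, jnd_deg = jnd,
        n_trials = nrow(sub), separation_flag = flags,
        degenerate_flag = degen)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  grp <- do.call(rbind, lapply(split(res, res$cycle_type), function(d) {
    data.frame(cycle_type = d$cycle_type[1],
               pse_mean = mean(d$pse_deg), pse_sd = stats::sd(d$pse_deg),
               pse_median = stats::median(d$pse_deg),
               pse_iqr = iqr_deg(d$pse_deg),
               jnd_mean = mean(d$jnd_deg), jnd_sd = stats::sd(d$jnd_deg),
               jnd_median = stats::median(d$jnd_deg),
               jnd_iqr = iqr_deg(d$jnd_deg),
               n_subjects = nrow(d))
  }))
  rownames(grp) <- NULL
  attr(res, "group") <- grp
  res
}
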