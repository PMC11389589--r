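#' Match hand-position variability between adaptation and washout
#'
#' Control analysis that equates the variability of actual hand positions
#' (target-relative signed directions of the localization reaches) between
#' cycle types before re-estimating localization variability. Per iteration,
#' one adaptation trial with the most extreme hand position (largest absolute
#' deviation from the adaptation median) and one washout trial with the most
#' average hand position (smallest absolute deviation from the washout
#' median) are removed; medians and IQRs are recomputed, and the loop stops
#' at the first iteration at which the adaptation hand-position IQR is
#' strictly below the washout one ("just below"). Ties in deviation are
#' broken by the earlier trial index, making the procedure deterministic.
#'
#' @param hand_adapt,hand_wash signed hand directions (deg) of the
#'   localization reaches in adaptation and washout cycles.
#' @param loc_adapt,loc_wash optional localization errors aligned with the
#'   hand vectors; the post-match localization IQRs are computed on the
#'   surviving trials.
#' @param floor minimum number of trials that must remain per cycle type
#'   (default 8); reaching it before the criterion yields a failure result
#'   with diagnostics rather than an error.
#' @param qtype quartile convention (see [iqr_deg()]).
#' @return an object of class `vmr_match`: removal counts, remaining counts,
#'   logical keep masks, post-match hand-position and localization IQRs per
#'   cycle type, the iteration count, `converged`, and a per-iteration
#'   `trace` data frame (pre-removal IQRs and removed indices) for audit.
#' @examples
#' m <- match_variability(c(0, 2, -2, 20, -20), c(0, 1, -1, 1.5, -1.5),
#'                        floor = 2)
#' m$iterations
#' @export
match_variability <- function(hand_adapt, hand_wash,
                              loc_adapt = NULL, loc_wash = NULL,
                              floor = 8L, qtype = 7L) {
  na <- length(hand_adapt)
  nw <- length(hand_wash)
  if (!is.null(loc_adapt)) stopifnot(length(loc_adapt) == na)
  if (!is.null(loc_wash)) stopifnot(length(loc_wash) == nw)
  if (na < floor || nw < floor) {
    stop("need at least `floor` (", floor, ") trials per cycle type",
         call. = FALSE)
  }

  keep_a <- rep(TRUE, na)
  keep_w <- rep(TRUE, nw)
  iter <- 0L
  converged <- FALSE
  trace <- list()
  repeat {
    iqr_a <- iqr_deg(hand_adapt[keep_a], qtype = qtype)
    iqr_w <- iqr_deg(hand_wash[keep_w], qtype = qtype)
    if (iqr_a < iqr_w) {
      converged <- TRUE
      break
    }
    if (sum(keep_a) <= floor || sum(keep_w) <= floor) break
    dev_a <- abs(hand_adapt - stats::median(hand_adapt[keep_a]))
    dev_a[!keep_a] <- -Inf
    rm_a <- which.max(dev_a)   # first index on ties
    dev_w <- abs(hand_wash - stats::median(hand_wash[keep_w]))
    dev_w[!keep_w] <- Inf
    rm_w <- which.min(dev_w)
    keep_a[rm_a] <- FALSE
    keep_w[rm_w] <- FALSE
    iter <- iter + 1L
    trace[[iter]] <- data.frame(iteration = iter, iqr_adapt_pre = iqr_a,
                                iqr_wash_pre = iqr_w,
                                removed_adapt_index = rm_a,
                                removed_wash_index = rm_w)
  }

  structure(list(
    removed_adaptation = na - sum(keep_a),
    removed_washout = nw - sum(keep_w),
    remaining = c(adaptation = sum(keep_a), washout = sum(keep_w)),
    keep_adaptation = keep_a,
    keep_washout = keep_w,
    handpos_iqr_deg = c(adaptation = iqr_deg(hand_adapt[keep_a], qtype = qtype),
                        washout = iqr_deg(hand_wash[keep_w], qtype = qtype)),
    loc_iqr_deg = c(
      adaptation = if (is.null(loc_adapt)) NA_real_
        else iqr_deg(loc_adapt[keep_a], qtype = qtype),
      washout = if (is.null(loc_wash)) NA_real_
        else iqr_deg(loc_wash[keep_w], qtype = qtype)),
    iterations = iter,
    converged = converged,
    trace = if (iter > 0L) do.call(rbind, trace) else NULL
  ), class = "vmr_match")
}

#' @export
print.vmr_match <- function(x, digits = 3, ...) {
  cat("<vmr_match> ", if (x$converged) "criterion met" else
      "floor reached before criterion", " after ", x$iterations,
      " iteration(s)\n", sep = "")
  cat("  removed: ", x$removed_adaptation, " adaptation, ",
      x$removed_washout, " washout;  remaining: ",
      x$remaining["adaptation"], "/", x$remaining["washout"], "\n", sep = "")
  cat("  hand-position IQR (deg): adaptation ",
      format(x$handpos_iqr_deg["adaptation"], digits = digits), ", washout ",
      format(x$handpos_iqr_deg["washout"], digits = digits), "\n", sep = "")
  if (!all(is.na(x$loc_iqr_deg))) {
    cat("  localization IQR (deg): adaptation ",
        format(x$loc_iqr_deg["adaptation"], digits = digits), ", washout ",
        format(x$loc_iqr_deg["washout"], digits = digits), "\n", sep = "")
  }
  invisible(x)
}
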