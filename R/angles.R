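#' Angle and dispersion conventions
#'
#' All angles in the package are in degrees, measured counterclockwise (CCW,
#' positive) from straight ahead (the +y axis of the workspace), with the home
#' position at the origin. Positions are in cm, time in ms.
#'
#' @name vmrloc-conventions
#' @keywords internal
NULL

#' Wrap angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_deg(c(190, -190, 180, -180, 540))
#' @export
wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180 & !is.na(w)] <- 180
  w
}

#' Convert a workspace direction to a unit displacement
#'
#' 0 deg is straight ahead (+y); positive angles rotate CCW.
#'
#' @param theta_deg direction in degrees.
#' @param r radial distance (cm), recycled.
#' @return two-column matrix of x/y displacements from home.
#' @export
deg_to_xy <- function(theta_deg, r = 1) {
  th <- theta_deg * pi / 180
  cbind(x = -r * sin(th), y = r * cos(th))
}

#' Direction of a displacement from home
#'
#' @param x,y displacement components (cm), relative to home.
#' @return angle in degrees CCW from straight ahead, in (-180, 180].
#' @export
xy_to_deg <- function(x, y) {
  wrap_deg(atan2(-x, y) * 180 / pi)
}

#' Interquartile range with an explicit quantile convention
#'
#' Thin wrapper around [stats::quantile()] so the quartile convention used for
#' all dispersion summaries in the package is a single, documented choice
#' (default: type 7, linear interpolation). The convention matters at the
#' per-subject bin sizes typical for this paradigm (n around 36).
#'
#' @param x numeric vector.
#' @param qtype quantile algorithm type passed to [stats::quantile()].
#' @param na.rm drop missing values first.
#' @return the 75th minus the 25th percentile of `x`.
#' @export
iqr_deg <- function(x, qtype = 7L, na.rm = FALSE) {
  q <- stats::quantile(x, c(0.25, 0.75), type = qtype, na.rm = na.rm,
                       names = FALSE)
  q[2] - q[1]
}

# Gaussian IQR factor: IQR = iqr_norm_factor * sigma for a normal sample.
iqr_norm_factor <- 2 * stats::qnorm(0.75)
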