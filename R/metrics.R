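#' Sustained-activation threshold
#'
#' A response is classified as "sustained" when the activation level at the
#' reference time (600 min unless stated otherwise) is at least this
#' fraction of its peak. All qualitative sustained/transient checks in the
#' package share this single definition.
#'
#' @export
SUSTAINED_RATIO_THRESHOLD <- 0.5

#' Activation time series of a trajectory
#'
#' The activation level of the GTPase is defined as the concentration of
#' the GTP-Rho/effector complex; this extracts that readout pointwise,
#' without smoothing.
#'
#' @param traj A `rho_trajectory`.
#' @return Numeric vector, uM, aligned with `traj$times`.
#' @export
activation_series <- function(traj) {
  stopifnot(inherits(traj, "rho_trajectory"))
  unname(traj$states[, traj$network$readout])
}

#' Summarise Rho activation dynamics
#'
#' Scalar summaries of an activation time course:
#' \describe{
#'   \item{peak, time_to_peak}{Maximum of the readout and its time.}
#'   \item{value_at}{Readout linearly interpolated at each requested
#'     reference time.}
#'   \item{half_decay_time}{First time after the peak at which the readout
#'     falls to half the peak, linearly interpolated between grid points;
#'     `NA` ("not reached") if it never does within the horizon.}
#'   \item{auc}{Trapezoid area under the readout, uM * min.}
#'   \item{sustained_ratio}{`value_at` the first reference time divided by
#'     the peak; 0 for an identically-zero series.}
#' }
#'
#' @param traj A `rho_trajectory`.
#' @param reference_times Times (min) at which to report the readout; must
#'   lie within the simulated horizon. Default 600.
#' @return Object of class `activation_summary` (a list of the above).
#' @export
summarize_activation <- function(traj, reference_times = 600) {
  stopifnot(inherits(traj, "rho_trajectory"))
  if (length(traj$times) == 0) {
    stop("usage error: empty trajectory", call. = FALSE)
  }
  if (any(reference_times < 0) || any(reference_times > max(traj$times))) {
    stop("usage error: reference times must lie within [0, ",
         max(traj$times), "] min", call. = FALSE)
  }
  y <- activation_series(traj)
  t <- traj$times
  ipeak <- which.max(y)
  peak <- y[ipeak]
  value_at <- vapply(reference_times, function(tr) {
    stats::approx(t, y, xout = tr, ties = "ordered")$y
  }, numeric(1))
  names(value_at) <- as.character(reference_times)
  half <- peak / 2
  half_decay <- NA_real_
  if (peak > 0 && ipeak < length(y)) {
    below <- which(y[(ipeak + 1):length(y)] <= half) + ipeak
    if (length(below)) {
      j <- below[1]
      # linear interpolation between the last point above half and j
      half_decay <- t[j - 1] + (t[j] - t[j - 1]) *
        (y[j - 1] - half) / (y[j - 1] - y[j])
    }
  }
  sustained_ratio <- if (peak > 0) unname(value_at[1]) / peak else 0
  structure(list(peak = peak, time_to_peak = t[ipeak], value_at = value_at,
                 half_decay_time = half_decay,
                 auc = sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2),
                 sustained_ratio = sustained_ratio),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("Activation summary: peak %.4g uM at t = %.4g min\n",
              x$peak, x$time_to_peak))
  for (nm in names(x$value_at)) {
    cat(sprintf("  at %s min: %.4g uM\n", nm, x$value_at[[nm]]))
  }
  cat(sprintf("  half-decay: %s; AUC %.4g uM*min; sustained ratio %.3f\n",
              if (is.na(x$half_decay_time)) "not reached" else
                paste(format(signif(x$half_decay_time, 5)), "min"),
              x$auc, x$sustained_ratio))
  invisible(x)
}
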