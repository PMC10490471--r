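# Pupil light reflex kinematics: velocity/acceleration derivatives and
# extraction of onset latency, constriction amplitude and velocities.

#' Velocity and acceleration of a uniformly sampled trace
#'
#' Velocity uses central differences at interior samples and one-sided
#' differences at the edges.  Acceleration is the direct second central
#' difference, with the nearest interior three-point estimate replicated at
#' the edges, so polynomial traces up to degree two are differentiated
#' exactly everywhere.
#'
#' @param x numeric vector (cleaned, uniformly sampled).
#' @param dt sampling interval in seconds.
#' @return list with `velocity` and `acceleration`, same length as `x`.
#' @export
trace_derivatives <- function(x, dt) {
  n <- length(x)
  if (n < 3L) stop("trace_derivatives() needs at least 3 samples")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  a <- numeric(n)
  a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  a[1] <- a[2]
  a[n] <- a[n - 1]
  list(velocity = v, acceleration = a)
}

#' Extract pupil light reflex kinematics
#'
#' From a (typically trial-averaged) constriction trace: the peak
#' constriction amplitude is the most negative value after stimulus onset;
#' the constriction onset is the time of the most negative acceleration in
#' the first period of the second derivative, taken as the interval from
#' stimulus onset to the peak constriction; peak/average constriction
#' velocities are computed between onset and peak, and peak/average
#' redilation velocities after the peak.
#'
#' @param x numeric trace (baseline-corrected so pre-flash level is near
#'   zero), or a one-row slice of an averaged epoch set.
#' @param time time axis in seconds, stimulus onset at 0.
#' @param onset_s stimulus onset (s), default 0.
#' @param smooth_ms optional moving-average smoothing before
#'   differentiation (0 = off, so analytic templates are recovered
#'   exactly).
#' @return a one-row data frame of class `plr_metrics`: `onset_latency_ms`,
#'   `t_peak_constriction_ms`, `peak_constriction_amplitude`,
#'   `peak_constriction_velocity`, `avg_constriction_velocity`,
#'   `peak_dilation_velocity`, `avg_dilation_velocity`.
#' @export
extract_plr <- function(x, time, onset_s = 0, smooth_ms = 0) {
  stopifnot(length(x) == length(time))
  dt <- stats::median(diff(time))
  if (smooth_ms > 0) x <- moving_average(x, round(smooth_ms / 1000 / dt))
  post <- which(time >= onset_s)
  if (length(post) < 5L) stop("trace too short after stimulus onset")
  i0 <- post[1]
  xp <- x[post]
  i_peak_rel <- which.min(xp)
  i_peak <- post[i_peak_rel]
  if (!(x[i_peak] < x[i0]) || i_peak_rel == 1L)
    stop("no PLR detected: no post-stimulus minimum below onset level")
  d <- trace_derivatives(x, dt)
  win <- i0:i_peak
  i_on <- win[which.min(d$acceleration[win])]
  con <- i_on:i_peak
  dil <- if (i_peak < length(x)) (i_peak + 1L):length(x) else integer(0)
  out <- data.frame(
    onset_latency_ms = (time[i_on] - onset_s) * 1000,
    t_peak_constriction_ms = (time[i_peak] - onset_s) * 1000,
    peak_constriction_amplitude = x[i_peak],
    peak_constriction_velocity = min(d$velocity[con]),
    avg_constriction_velocity = mean(d$velocity[con]),
    peak_dilation_velocity = if (length(dil)) max(d$velocity[dil]) else NA,
    avg_dilation_velocity = if (length(dil)) mean(d$velocity[dil]) else NA)
  class(out) <- c("plr_metrics", "data.frame")
  out
}

#' PLR kinematics per subject and stimulation condition
#'
#' Averages retained epochs within subject x stimulation and extracts
#' [extract_plr()] metrics from each averaged trace.
#'
#' @param epochs a normalized `epoch_set` from the light-reflex task.
#' @param smooth_ms passed to [extract_plr()].
#' @return data frame with one row per subject x stimulation condition.
#' @export
plr_metrics_table <- function(epochs, smooth_ms = 0) {
  avg <- average_epochs(epochs, by = c("subject", "stimulation"))
  res <- vector("list", nrow(avg$data))
  for (i in seq_len(nrow(avg$data))) {
    m <- tryCatch(extract_plr(avg$data[i, ], avg$time,
                              smooth_ms = smooth_ms),
                  error = function(e) NULL)
    if (is.null(m)) next
    res[[i]] <- cbind(avg$groups[i, , drop = FALSE], m)
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
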