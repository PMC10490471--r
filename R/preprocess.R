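# Pupil-trace cleaning and epoching: two-pass dilation-speed / MAD outlier
# rejection, trial and subject exclusion, interpolation, z-scoring, baseline
# correction and downsampling.

#' Cleaning configuration
#'
#' @param mad_constant multiplier on the median absolute deviation for
#'   outlier thresholds (default 2.5).
#' @param smooth_ms moving-average window for the second-pass trend line
#'   (ms).
#' @param baseline_ms pre-stimulus baseline window length (ms).
#' @param out_rate output rate after decimation (Hz).
#' @param trial_missing_max maximal tolerated missing fraction per trial;
#'   trials strictly above it are rejected.
#' @param subject_excluded_max maximal tolerated rejected-trial fraction
#'   per subject within one condition; subjects strictly above it are
#'   excluded.
#' @param epoch_est,epoch_plrt epoch windows (s) around stimulus onset.
#' @return a `clean_config` list.
#' @export
clean_config <- function(mad_constant = 2.5, smooth_ms = 100,
                         baseline_ms = 200, out_rate = 100,
                         trial_missing_max = 0.5, subject_excluded_max = 0.5,
                         epoch_est = c(-2, 5), epoch_plrt = c(-2, 7)) {
  stopifnot_scalar_pos(mad_constant, "mad_constant")
  for (f in c(trial_missing_max, subject_excluded_max))
    if (f <= 0 || f > 1) stop("exclusion fractions must lie in (0, 1]")
  structure(list(mad_constant = mad_constant, smooth_ms = smooth_ms,
                 baseline_ms = baseline_ms, out_rate = out_rate,
                 trial_missing_max = trial_missing_max,
                 subject_excluded_max = subject_excluded_max,
                 epoch_est = epoch_est, epoch_plrt = epoch_plrt),
            class = "clean_config")
}

#' Cut a continuous trace into stimulus-locked epochs
#'
#' The onset sample is the recorded sample nearest each event onset; the
#' epoch spans `window[1]` to `window[2]` seconds around it inclusive, so a
#' (-2, 5) s window at 500 Hz yields 3501 samples.  Events whose window
#' falls outside the recording are flagged (`rejected` with reason
#' `"edge"`), never silently dropped.
#'
#' @param trace a [pupil_trace()].
#' @param events data frame with an `onset_s` column plus condition labels.
#' @param window numeric pair, epoch window in seconds.
#' @return an `epoch_set`: list with `data` (trials x time matrix),
#'   `missing` (same shape), `time` (s relative to onset), `rate`,
#'   `labels`, `rejected`, `reject_reason`.
#' @export
epoch_trials <- function(trace, events, window) {
  stopifnot(inherits(trace, "pupil_trace"), "onset_s" %in% names(events))
  rate <- 1 / stats::median(diff(trace$time))
  rel_idx <- round(window[1] * rate):round(window[2] * rate)
  n_time <- length(rel_idx)
  n_ev <- nrow(events)
  dat <- matrix(NA_real_, n_ev, n_time)
  mis <- matrix(TRUE, n_ev, n_time)
  rejected <- logical(n_ev)
  reason <- character(n_ev)
  n <- nrow(trace)
  for (i in seq_len(n_ev)) {
    onset_idx <- round((events$onset_s[i] - trace$time[1]) * rate) + 1L
    idx <- onset_idx + rel_idx
    if (idx[1] < 1L || idx[n_time] > n) {
      rejected[i] <- TRUE
      reason[i] <- "edge"
      next
    }
    dat[i, ] <- trace$pupil[idx]
    mis[i, ] <- trace$missing[idx]
  }
  structure(list(data = dat, missing = mis,
                 time = rel_idx / rate, rate = rate,
                 labels = events[setdiff(names(events), "onset_s")],
                 rejected = rejected, reject_reason = reason),
            class = "epoch_set")
}

#' Reject missing-data trials and over-excluded subjects
#'
#' Trials with strictly more than `cfg$trial_missing_max` missing samples
#' are rejected; subjects with strictly more than
#' `cfg$subject_excluded_max` rejected trials in any single condition are
#' wholly excluded.  Conditions are the crossing of the `stimulation` and
#' (if present) `congruency` label columns.
#'
#' @param epochs an `epoch_set`.
#' @param cfg a [clean_config()].
#' @return the `epoch_set` with updated rejection flags and an attached
#'   `report` (per-condition rejection counts and excluded subjects).
#' @export
reject_missing <- function(epochs, cfg = clean_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  frac <- rowMeans(epochs$missing | is.na(epochs$data))
  newly <- !epochs$rejected & frac > cfg$trial_missing_max
  epochs$rejected[newly] <- TRUE
  epochs$reject_reason[newly] <- "missing"
  lab <- epochs$labels
  cond_cols <- intersect(c("stimulation", "congruency"), names(lab))
  excluded_subjects <- integer(0)
  if (length(cond_cols) && "subject" %in% names(lab) && nrow(lab)) {
    cond <- interaction(lab[cond_cols], drop = TRUE)
    tab <- tapply(epochs$rejected, list(lab$subject, cond), mean)
    over <- apply(tab, 1, function(x) any(x > cfg$subject_excluded_max,
                                          na.rm = TRUE))
    excluded_subjects <- as.integer(names(over)[over & !is.na(over)])
    kill <- lab$subject %in% excluded_subjects & !epochs$rejected
    epochs$rejected[kill] <- TRUE
    epochs$reject_reason[kill] <- "subject"
  }
  rep_df <- if (length(cond_cols) && nrow(lab)) {
    stats::aggregate(epochs$rejected,
                     by = lab[c("subject", cond_cols)[c("subject", cond_cols)
                                                      %in% names(lab)]],
                     FUN = sum)
  } else data.frame()
  attr(epochs, "report") <- list(rejected_per_condition = rep_df,
                                 excluded_subjects = excluded_subjects,
                                 n_rejected = sum(epochs$rejected))
  epochs
}

#' Dilation speed series
#'
#' Per-sample dilation speed: the larger of the backward and forward
#' absolute difference quotients computed with the actual timestamps.
#' Endpoints use their single available neighbour; missing samples
#' propagate as missing.
#'
#' @param trace a [pupil_trace()] (or data frame with `time`, `pupil`,
#'   `missing`).
#' @return numeric vector of speeds (units/s), NA at missing samples.
#' @export
dilation_speed <- function(trace) {
  p <- trace$pupil
  p[trace$missing] <- NA
  if (sum(is.finite(p)) < 3L)
    stop("dilation_speed() needs at least 3 valid samples")
  t <- trace$time
  dq <- abs(diff(p)) / diff(t)
  back <- c(NA, dq)
  fwd <- c(dq, NA)
  sp <- pmax(back, fwd, na.rm = TRUE)
  sp[is.na(p)] <- NA
  sp
}

#' Robust outlier threshold from median and MAD
#'
#' `median(x) + c * median(|x - median(x)|)` over the finite values of the
#' series (the MAD here is unscaled, not consistency-corrected).
#'
#' @param series numeric vector.
#' @param c threshold constant (default 2.5).
#' @return threshold scalar.
#' @export
mad_threshold <- function(series, c = 2.5) {
  x <- series[is.finite(series)]
  if (!length(x)) stop("mad_threshold(): no finite values in series")
  med <- stats::median(x)
  med + c * stats::median(abs(x - med))
}

#' Two-pass dilation-speed / trend-deviation cleaning
#'
#' Pass 1 removes samples whose dilation speed exceeds the MAD threshold of
#' the speed series.  A trend line is then formed by linearly interpolating
#' the resulting gaps and smoothing with a centered `smooth_ms` moving
#' average; pass 2 removes samples whose absolute deviation from that trend
#' exceeds a MAD threshold computed on the deviation series (same
#' constant).  Removed samples are marked missing and interior gaps are
#' linearly interpolated; leading/trailing missing runs are preserved.
#'
#' @param trace a [pupil_trace()].
#' @param cfg a [clean_config()].
#' @return list with `trace` (cleaned [pupil_trace()]), `removed` (logical:
#'   samples newly flagged by either pass), and the two `thresholds`.
#' @export
two_pass_clean <- function(trace, cfg = clean_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  rate <- 1 / stats::median(diff(trace$time))
  p <- trace$pupil
  p[trace$missing] <- NA
  sp <- dilation_speed(trace)
  thr1 <- mad_threshold(sp, cfg$mad_constant)
  rej1 <- !is.na(sp) & sp > thr1
  p1 <- p
  p1[rej1] <- NA
  trend <- moving_average(interp_interior(p1),
                          round(cfg$smooth_ms / 1000 * rate))
  dev <- abs(p1 - trend)
  thr2 <- mad_threshold(dev, cfg$mad_constant)
  rej2 <- !is.na(dev) & dev > thr2
  p2 <- p1
  p2[rej2] <- NA
  if (!any(is.finite(p2)))
    stop("two_pass_clean(): cleaning removed the entire trace ",
         sprintf("(pass 1: %d, pass 2: %d of %d samples)",
                 sum(rej1), sum(rej2), length(p)))
  filled <- interp_interior(p2)
  list(trace = pupil_trace(trace$time, filled, missing = !is.finite(filled)),
       removed = rej1 | rej2,
       thresholds = c(speed = thr1, deviation = thr2))
}

#' z-score, baseline-correct and downsample epochs
#'
#' z-scoring pools mean and SD per subject (and per `session` label, if
#' present) over all retained epochs' non-missing samples; each epoch's
#' mean over the closed-open baseline window `[-baseline_ms, 0)` is then
#' subtracted, and the epochs are decimated to `out_rate`.
#'
#' @param epochs an `epoch_set` of cleaned epochs.
#' @param cfg a [clean_config()].
#' @return the transformed `epoch_set` (z-units, baseline-corrected,
#'   decimated).
#' @export
normalize_epochs <- function(epochs, cfg = clean_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  lab <- epochs$labels
  scope <- if ("subject" %in% names(lab)) {
    cols <- intersect(c("subject", "session"), names(lab))
    interaction(lab[cols], drop = TRUE)
  } else factor(rep(1, nrow(epochs$data)))
  dat <- epochs$data
  for (g in levels(scope)) {
    rows <- which(scope == g & !epochs$rejected)
    if (!length(rows)) next
    vals <- dat[rows, , drop = FALSE]
    vals <- vals[!epochs$missing[rows, , drop = FALSE] & is.finite(vals)]
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0)
      stop("normalize_epochs(): zero variance in z-scoring scope ", g)
    dat[scope == g, ] <- (dat[scope == g, , drop = FALSE] - mean(vals)) / s
  }
  bl_cols <- which(epochs$time >= -cfg$baseline_ms / 1000 & epochs$time < 0)
  bl <- rowMeans(dat[, bl_cols, drop = FALSE], na.rm = TRUE)
  dat <- dat - bl
  fac <- epochs$rate / cfg$out_rate
  if (abs(fac - round(fac)) > 1e-8)
    stop("normalize_epochs(): rate must be an integer multiple of out_rate")
  keep <- seq(1L, ncol(dat), by = as.integer(round(fac)))
  epochs$data <- dat[, keep, drop = FALSE]
  epochs$missing <- epochs$missing[, keep, drop = FALSE]
  epochs$time <- epochs$time[keep]
  epochs$rate <- cfg$out_rate
  epochs$baseline <- bl
  epochs
}

#' Average retained epochs within subject and condition
#'
#' @param epochs an `epoch_set`.
#' @param by label columns to average within (default subject and
#'   stimulation).
#' @return list with `data` (group x time matrix of means), `groups`
#'   (data frame of the label combinations), `time`.
#' @export
average_epochs <- function(epochs, by = c("subject", "stimulation")) {
  stopifnot(inherits(epochs, "epoch_set"), all(by %in% names(epochs$labels)))
  keep <- !epochs$rejected
  lab <- epochs$labels[keep, by, drop = FALSE]
  dat <- epochs$data[keep, , drop = FALSE]
  key <- interaction(lab, drop = TRUE)
  means <- rowsum(dat, key, na.rm = TRUE) /
    rowsum((!is.na(dat)) * 1, key)
  groups <- unique(cbind(key = as.character(key), lab))
  groups <- groups[match(rownames(means), groups$key), , drop = FALSE]
  list(data = unname(means), groups = groups[, by, drop = FALSE],
       time = epochs$time)
}

#' Bind epoch sets sharing one time axis
#'
#' Concatenates the trials of several `epoch_set` objects (e.g. one per
#' subject-session) into a single set.
#'
#' @param eps list of `epoch_set` objects with identical time axes.
#' @return the combined `epoch_set`.
#' @export
bind_epochs <- function(eps) {
  stopifnot(length(eps) >= 1L,
            all(vapply(eps, inherits, logical(1), "epoch_set")))
  t0 <- eps[[1]]$time
  for (e in eps)
    if (!isTRUE(all.equal(e$time, t0)))
      stop("bind_epochs(): epoch sets must share one time axis")
  structure(list(
    data = do.call(rbind, lapply(eps, `[[`, "data")),
    missing = do.call(rbind, lapply(eps, `[[`, "missing")),
    time = t0, rate = eps[[1]]$rate,
    labels = do.call(rbind, lapply(eps, `[[`, "labels")),
    rejected = unlist(lapply(eps, `[[`, "rejected"), use.names = FALSE),
    reject_reason = unlist(lapply(eps, `[[`, "reject_reason"),
                           use.names = FALSE)),
    class = "epoch_set")
}
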