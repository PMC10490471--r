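# Stimulation-artifact removal from electrophysiological signals:
# pulse-locked blanking, autoregressive gap filling, zero-phase Butterworth
# filter chain, epoching with retained baselines.

#' Artifact-cleaning configuration
#'
#' @param blank_ms samples in `[marker, marker + blank_ms)` are blanked.
#' @param ar_context_ms context length on each side of a gap used to fit
#'   the autoregressive predictor.
#' @param hp_hz,lp_hz high-/low-pass corner frequencies (Hz).
#' @param notch band-stop edges (Hz) for line-noise suppression.
#' @param epoch epoch window (s) around stimulus onset.
#' @param out_rate output rate after decimation (Hz).
#' @param baseline_ms pre-stimulus baseline length (ms).
#' @param ar_order AR model order; default `floor(context samples / 2)`
#'   capped at 16.
#' @return an `artifact_config` list.
#' @export
artifact_config <- function(blank_ms = 10, ar_context_ms = 25,
                            hp_hz = 1, lp_hz = 60, notch = c(49, 51),
                            epoch = c(-2, 5), out_rate = 250,
                            baseline_ms = 200, ar_order = NULL) {
  if (hp_hz >= lp_hz || notch[1] >= notch[2])
    stop("filter edges must be ordered")
  structure(list(blank_ms = blank_ms, ar_context_ms = ar_context_ms,
                 hp_hz = hp_hz, lp_hz = lp_hz, notch = notch,
                 epoch = epoch, out_rate = out_rate,
                 baseline_ms = baseline_ms, ar_order = ar_order),
            class = "artifact_config")
}

#' Blank samples after each stimulation pulse marker
#'
#' Samples in `[marker, marker + blank_ms)` are replaced with NA on every
#' channel; overlapping blank windows merge naturally.
#'
#' @param sig a [cont_signal()].
#' @param cfg an [artifact_config()].
#' @return the signal with blanked (NA) runs.
#' @export
blank_pulses <- function(sig, cfg = artifact_config()) {
  stopifnot(inherits(sig, "cont_signal"))
  if (!length(sig$markers)) return(sig)
  n <- nrow(sig$data)
  w <- ceiling(cfg$blank_ms / 1000 * sig$rate)
  for (m in sig$markers) {
    i0 <- round((m - sig$time[1]) * sig$rate) + 1L
    idx <- i0:(i0 + w - 1L)
    idx <- idx[idx >= 1L & idx <= n]
    sig$data[idx, ] <- NA
  }
  sig
}

# Fit an AR model on a context segment and predict `h` steps ahead.
# Returns NULL if the context is unusable.
ar_predict <- function(ctx, h, order) {
  if (length(ctx) < max(order + 2L, 5L)) return(NULL)
  if (stats::sd(ctx) < .Machine$double.eps^0.5)
    return(rep(mean(ctx), h))
  fit <- tryCatch(
    stats::ar.burg(ctx, aic = FALSE,
                   order.max = min(order, length(ctx) - 2L)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.numeric(stats::predict(fit, n.ahead = h, se.fit = FALSE))
}

#' Fill blanked gaps by bidirectional autoregressive prediction
#'
#' For each NA run on each channel an AR model (Burg) is fitted on up to
#' `ar_context_ms` of valid data on each side; the forward prediction from
#' the left context and the time-reversed prediction from the right context
#' are cross-faded with a linear ramp across the gap.  If only one side
#' provides context, that side's prediction is used alone; if neither does,
#' the gap is linearly interpolated with a warning.  Non-gap samples are
#' never touched.
#'
#' @param sig a [cont_signal()] with NA gaps.
#' @param cfg an [artifact_config()].
#' @return the gap-free signal.
#' @export
ar_fill <- function(sig, cfg = artifact_config()) {
  stopifnot(inherits(sig, "cont_signal"))
  ctx_n <- round(cfg$ar_context_ms / 1000 * sig$rate)
  order <- cfg$ar_order %||% min(max(2L, floor(ctx_n / 2)), 16L)
  for (ch in seq_len(ncol(sig$data))) {
    x <- sig$data[, ch]
    runs <- na_runs(is.na(x))
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      s <- runs$start[r]; e <- runs$end[r]; h <- e - s + 1L
      left <- x[seq.int(max(1L, s - ctx_n), s - 1L)]
      left <- left[is.finite(left)]
      right <- x[seq.int(e + 1L, min(length(x), e + ctx_n))]
      right <- right[is.finite(right)]
      fwd <- ar_predict(left, h, order)
      bwd <- ar_predict(rev(right), h, order)
      if (!is.null(bwd)) bwd <- rev(bwd)
      fill <- if (!is.null(fwd) && !is.null(bwd)) {
        wgt <- if (h == 1L) 0.5 else seq(1, 0, length.out = h)
        wgt * fwd + (1 - wgt) * bwd
      } else if (!is.null(fwd)) fwd else if (!is.null(bwd)) bwd else {
        warning("ar_fill(): gap without usable context, linear fill")
        lo <- if (s > 1L) x[s - 1L] else if (length(right)) right[1] else 0
        hi <- if (e < length(x)) x[e + 1L] else lo
        seq(lo, hi, length.out = h + 2L)[2:(h + 1L)]
      }
      x[s:e] <- fill
    }
    sig$data[, ch] <- x
  }
  sig
}

#' Zero-phase Butterworth filter chain
#'
#' Forward-backward (zero-phase) 4th-order Butterworth filters applied in
#' order: high-pass `hp_hz`, low-pass `lp_hz`, band-stop `notch`.
#'
#' @param sig a gap-free [cont_signal()].
#' @param cfg an [artifact_config()].
#' @return the filtered signal.
#' @export
filter_chain <- function(sig, cfg = artifact_config()) {
  stopifnot(inherits(sig, "cont_signal"))
  if (sig$rate < 2 * cfg$lp_hz)
    stop("sampling rate below twice the low-pass corner")
  if (anyNA(sig$data))
    stop("filter_chain() requires a gap-free signal; run ar_fill() first")
  nyq <- sig$rate / 2
  hp <- signal::butter(4, cfg$hp_hz / nyq, type = "high")
  lp <- signal::butter(4, cfg$lp_hz / nyq, type = "low")
  bs <- signal::butter(4, cfg$notch / nyq, type = "stop")
  for (ch in seq_len(ncol(sig$data))) {
    x <- sig$data[, ch]
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    x <- signal::filtfilt(bs, x)
    sig$data[, ch] <- x
  }
  sig
}

#' Epoch, decimate and baseline-correct a continuous signal
#'
#' Epochs of `cfg$epoch` seconds around each event onset are decimated to
#' `cfg$out_rate` and baseline-corrected to the mean of the `baseline_ms`
#' before stimulus onset; the per-channel per-trial baseline means are
#' retained for baseline-comparison analyses.
#'
#' @param sig a filtered [cont_signal()].
#' @param events data frame with `onset_s` plus condition labels.
#' @param cfg an [artifact_config()].
#' @return a `meg_epoch_set`: list with `data` (trial x time x channel
#'   array), `time`, `rate`, `channels`, `labels`, `baselines`
#'   (trial x channel), `rejected`, `reject_reason`.
#' @export
epoch_and_baseline <- function(sig, events, cfg = artifact_config()) {
  stopifnot(inherits(sig, "cont_signal"), "onset_s" %in% names(events))
  rate <- sig$rate
  fac <- rate / cfg$out_rate
  if (abs(fac - round(fac)) > 1e-8)
    stop("rate must be an integer multiple of out_rate")
  fac <- as.integer(round(fac))
  rel_idx <- round(cfg$epoch[1] * rate):round(cfg$epoch[2] * rate)
  keep <- seq(1L, length(rel_idx), by = fac)
  n_time <- length(keep)
  n_ev <- nrow(events)
  n_ch <- ncol(sig$data)
  dat <- array(NA_real_, c(n_ev, n_time, n_ch),
               dimnames = list(NULL, NULL, sig$channels))
  baselines <- matrix(NA_real_, n_ev, n_ch,
                      dimnames = list(NULL, sig$channels))
  rejected <- logical(n_ev)
  reason <- character(n_ev)
  n <- nrow(sig$data)
  for (i in seq_len(n_ev)) {
    onset_idx <- round((events$onset_s[i] - sig$time[1]) * rate) + 1L
    idx <- onset_idx + rel_idx
    if (idx[1] < 1L || idx[length(idx)] > n) {
      rejected[i] <- TRUE
      reason[i] <- "edge"
      next
    }
    bl_idx <- onset_idx + seq.int(-round(cfg$baseline_ms / 1000 * rate), -1L)
    for (ch in seq_len(n_ch)) {
      bl <- mean(sig$data[bl_idx, ch])
      baselines[i, ch] <- bl
      dat[i, , ch] <- sig$data[idx[keep], ch] - bl
    }
  }
  structure(list(data = dat, time = rel_idx[keep] / rate,
                 rate = cfg$out_rate, channels = sig$channels,
                 labels = events[setdiff(names(events), "onset_s")],
                 baselines = baselines,
                 rejected = rejected, reject_reason = reason),
            class = "meg_epoch_set")
}
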