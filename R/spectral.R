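# Spectral estimation: Hanning-tapered FFT power on the early post-stimulus
# window and Morlet time-frequency representations with decibel baselining.

#' Hanning-tapered FFT power spectra
#'
#' Power in the `window` (default the first 500 ms after stimulus onset) of
#' each epoch and channel, from a Hann-windowed, zero-padded FFT.  The
#' padding places bins exactly on the requested frequency grid (0.5 Hz
#' steps by default, finer than the window's native Rayleigh resolution:
#' spectral interpolation, documented in the methods vignette).
#'
#' @param epochs a `meg_epoch_set`.
#' @param window analysis window (s) relative to stimulus onset.
#' @param freqs frequency grid (Hz); must be equally spaced.
#' @return a `spectrum_set`: list with `freqs`, `power` (trial x frequency
#'   x channel array), `labels`, `channels`.
#' @export
fft_power <- function(epochs, window = c(0, 0.5), freqs = seq(2, 14, 0.5)) {
  stopifnot(inherits(epochs, "meg_epoch_set"))
  step <- unique(round(diff(freqs), 10))
  if (length(step) != 1L) stop("`freqs` must be equally spaced")
  idx <- which(epochs$time >= window[1] & epochs$time < window[2])
  if (!length(idx) || max(epochs$time) < window[2] - 1 / epochs$rate)
    stop("analysis window exceeds the epoch")
  nwin <- length(idx)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  nfft <- round(epochs$rate / step)
  if (nfft < nwin) stop("frequency step too coarse for the window")
  bins <- round(freqs / step) + 1L
  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[3]
  pow <- array(NA_real_, c(n_tr, length(freqs), n_ch),
               dimnames = list(NULL, NULL, epochs$channels))
  for (i in seq_len(n_tr)) {
    if (epochs$rejected[i]) next
    for (ch in seq_len(n_ch)) {
      x <- epochs$data[i, idx, ch] * hann
      X <- stats::fft(c(x, numeric(nfft - nwin)))
      pow[i, , ch] <- (Mod(X[bins])^2) / nwin^2
    }
  }
  structure(list(freqs = freqs, power = pow, labels = epochs$labels,
                 channels = epochs$channels, rejected = epochs$rejected),
            class = "spectrum_set")
}

#' Average power across a named sensor group
#'
#' Sensor-group averaging is applied before statistics: power is averaged
#' over the channels of each group, per trial and frequency (or
#' time-frequency cell).
#'
#' @param spec a `spectrum_set` or `tfr_set`.
#' @param groups named list of channel-name vectors (e.g. FM, OM).
#' @return the object with the channel dimension replaced by groups.
#' @export
group_average <- function(spec, groups) {
  d <- spec$power
  nd <- length(dim(d))
  out <- array(NA_real_, c(dim(d)[-nd], length(groups)))
  for (g in seq_along(groups)) {
    sel <- match(groups[[g]], spec$channels)
    if (anyNA(sel)) stop("unknown channel in group ", names(groups)[g])
    sub <- if (nd == 3L) d[, , sel, drop = FALSE] else
      d[, , , sel, drop = FALSE]
    if (nd == 3L) out[, , g] <- apply(sub, c(1, 2), mean)
    else out[, , , g] <- apply(sub, c(1, 2, 3), mean)
  }
  dimnames(out)[[nd]] <- names(groups)
  spec$power <- out
  spec$channels <- names(groups)
  spec
}

#' Morlet wavelet time-frequency representation
#'
#' Complex Morlet convolution (fixed number of cycles) squared-magnitude
#' power, sampled in `tbin` time bins over `times`.  Bins closer to an
#' epoch edge than half the wavelet support at a given frequency are
#' flagged as edge-contaminated.
#'
#' @param epochs a `meg_epoch_set`.
#' @param freqs frequency grid (Hz).
#' @param n_cycles wavelet cycles (default 5).
#' @param tbin time-bin width (s).
#' @param times analysis time span (s) relative to stimulus onset.
#' @return a `tfr_set`: list with `times`, `freqs`, `power` (trial x
#'   frequency x time x channel), `edge` (frequency x time logical),
#'   `labels`, `channels`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(2, 14, 0.5), n_cycles = 5,
                       tbin = 0.04, times = c(-1, 5)) {
  stopifnot(inherits(epochs, "meg_epoch_set"))
  rate <- epochs$rate
  t_ax <- epochs$time
  bin_t <- seq(times[1], times[2], by = tbin)
  bin_idx <- round((bin_t - t_ax[1]) * rate) + 1L
  if (any(bin_idx < 1L | bin_idx > length(t_ax)))
    stop("requested times outside the epoch")
  n_samp <- length(t_ax)
  nfft <- 2^ceiling(log2(2 * n_samp))
  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[3]
  pow <- array(NA_real_, c(n_tr, length(freqs), length(bin_t), n_ch),
               dimnames = list(NULL, NULL, NULL, epochs$channels))
  edge <- matrix(FALSE, length(freqs), length(bin_t))
  # precompute wavelet FFTs
  wl_fft <- vector("list", length(freqs))
  half_n <- integer(length(freqs))
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_t <- n_cycles / (2 * pi * f)
    hw <- ceiling(3 * sigma_t * rate)
    if (2 * hw + 1 > n_samp)
      stop(sprintf("insufficient padding for %.1f Hz wavelet", f))
    half_n[k] <- hw
    tt <- seq(-hw, hw) / rate
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sum(abs(w))
    wl_fft[[k]] <- stats::fft(c(w, complex(real = numeric(nfft - length(w)))))
    edge[k, ] <- bin_t < t_ax[1] + hw / rate | bin_t > t_ax[n_samp] - hw / rate
  }
  for (i in seq_len(n_tr)) {
    if (epochs$rejected[i]) next
    for (ch in seq_len(n_ch)) {
      x <- epochs$data[i, , ch]
      X <- stats::fft(c(x, numeric(nfft - n_samp)))
      for (k in seq_along(freqs)) {
        conv <- stats::fft(X * wl_fft[[k]], inverse = TRUE) / nfft
        # valid alignment: wavelet center over sample j is at j + half_n
        centered <- conv[half_n[k] + seq_len(n_samp)]
        pow[i, k, , ch] <- Mod(centered[bin_idx])^2
      }
    }
  }
  structure(list(times = bin_t, freqs = freqs, power = pow, edge = edge,
                 labels = epochs$labels, channels = epochs$channels,
                 rejected = epochs$rejected),
            class = "tfr_set")
}

#' Decibel baseline correction of a TFR
#'
#' `power_db = 10 * log10(power / mean(power in the baseline window))`,
#' per trial, frequency and channel.
#'
#' @param tfr a `tfr_set`.
#' @param window baseline window (s) relative to stimulus onset.
#' @return the `tfr_set` with `power` replaced by decibel values
#'   (`power_db = TRUE` flag set).
#' @export
db_baseline <- function(tfr, window = c(-0.5, -0.2)) {
  stopifnot(inherits(tfr, "tfr_set"))
  bl_idx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (!length(bl_idx)) stop("baseline window outside the TFR support")
  d <- tfr$power
  for (i in seq_len(dim(d)[1])) {
    for (ch in seq_len(dim(d)[4])) {
      bl <- rowMeans(matrix(d[i, , bl_idx, ch], nrow = length(tfr$freqs)))
      if (any(is.finite(bl) & bl <= 0))
        stop("zero baseline power at frequency ",
             paste(tfr$freqs[which(bl <= 0)], collapse = ", "), " Hz")
      d[i, , , ch] <- 10 * log10(d[i, , , ch] / bl)
    }
  }
  tfr$power <- d
  tfr$power_db <- TRUE
  tfr
}
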