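# Seeded synthetic-data generators emulating a two-task phasic-stimulation
# experiment: trial-level behaviour, monocular pupil traces, and multi-channel
# MEG-like signals with stimulation-artifact pulse trains.
#
# Coding conventions used throughout: stimulation 1 = active (taVNS),
# 0 = sham; congruency 1 = congruent, 0 = incongruent; face 1 = fearful,
# 0 = happy.

# ---- deterministic response templates -------------------------------------

#' Parametric pupil light reflex template
#'
#' Piecewise-smooth constriction/redilation template: flat at zero until the
#' onset latency, then an exponential-approach constriction with time
#' constant `constrict_tau_s`, multiplied by an exponential redilation with
#' time constant `redilate_tau_s`.  The template is scaled so that its
#' minimum equals `-amplitude`; the peak constriction occurs at
#' `latency + constrict_tau * log(1 + redilate_tau / constrict_tau)`.
#' The onset is a slope discontinuity, so the most negative acceleration of
#' the trace marks the latency sharply.
#'
#' @param t_s time axis in seconds (stimulus onset at 0).
#' @param latency_ms onset latency in ms.
#' @param amplitude peak constriction depth (positive; template minimum is
#'   `-amplitude`).
#' @param constrict_tau_s,redilate_tau_s time constants in seconds.
#' @return numeric vector: template values (<= 0) along `t_s`.
#' @export
plr_template <- function(t_s, latency_ms, amplitude,
                         constrict_tau_s = 0.7, redilate_tau_s = 2.5) {
  a <- constrict_tau_s
  b <- redilate_tau_s
  x <- t_s - latency_ms / 1000
  x[x < 0] <- NA
  raw <- (1 - exp(-x / a)) * exp(-x / b)
  peak <- plr_template_peak(a, b)
  out <- -amplitude * raw / peak$value
  out[is.na(out)] <- 0
  out
}

# Closed-form location/value of the template's unnormalized minimum.
plr_template_peak <- function(constrict_tau_s, redilate_tau_s) {
  a <- constrict_tau_s
  b <- redilate_tau_s
  xstar <- a * log(1 + b / a)
  list(x = xstar, value = (1 - exp(-xstar / a)) * exp(-xstar / b))
}

# Gamma-shaped task-evoked dilation kernel, unit peak at `peak_s`.
dilation_kernel <- function(t_s, peak_s = 1.3, shape = 4) {
  x <- t_s / peak_s
  out <- ifelse(t_s <= 0, 0,
                x^(shape - 1) * exp((shape - 1) * (1 - x)))
  out
}

# Raised-cosine constriction/recovery evoked by picture luminance in the
# conflict task: down over `dur_s`, back up over `dur_s`.
est_reflex_kernel <- function(t_s, dur_s = 1) {
  out <- numeric(length(t_s))
  inwin <- t_s > 0 & t_s < 2 * dur_s
  out[inwin] <- -(1 - cos(pi * t_s[inwin] / dur_s)) / 2
  out
}

# ---- pupil trace container -------------------------------------------------

#' Pupil sample trace
#'
#' @param time sample times in seconds (strictly increasing).
#' @param pupil pupil diameter in arbitrary recorder units; NA where
#'   `missing` is TRUE.
#' @param missing logical missing-data mask (defaults to `is.na(pupil)`).
#' @return a `pupil_trace` data frame with columns `time`, `pupil`,
#'   `missing`.
#' @export
pupil_trace <- function(time, pupil, missing = is.na(pupil)) {
  stopifnot(length(time) == length(pupil), length(missing) == length(pupil))
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing")
  if (any(!missing & !is.finite(pupil)))
    stop("`pupil` must be finite wherever `missing` is FALSE")
  structure(data.frame(time = time, pupil = pupil,
                       missing = as.logical(missing)),
            class = c("pupil_trace", "data.frame"))
}

# ---- shared session-timeline helpers --------------------------------------

est_trial_onsets <- function(design) {
  n_trials <- design$n_blocks_est * design$trials_per_block
  isi <- stats::runif(n_trials, design$isi_range_est[1],
                      design$isi_range_est[2])
  # trial: 2 s fixation, 1 s stimulus, est_post_s fixation, then ISI
  step <- 1 + design$est_post_s + isi + 2
  onsets <- 2 + c(0, cumsum(step[-n_trials]))
  # stimulus onsets are time-stamped at the recorder's sample resolution
  onsets <- round(onsets * design$pupil_rate) / design$pupil_rate
  list(onsets = onsets, n_trials = n_trials,
       total_s = onsets[n_trials] + 1 + design$est_post_s + 1)
}

plrt_trial_onsets <- function(design) {
  n_trials <- design$n_trials_plrt
  isi <- stats::runif(n_trials, design$isi_range_plrt[1],
                      design$isi_range_plrt[2])
  step <- 0.5 + design$plrt_post_s + isi + 2
  onsets <- 2 + c(0, cumsum(step[-n_trials]))
  onsets <- round(onsets * design$pupil_rate) / design$pupil_rate
  list(onsets = onsets, n_trials = n_trials,
       total_s = onsets[n_trials] + 0.5 + design$plrt_post_s + 1)
}

subject_intensities <- function(design) {
  # per-subject per-condition stimulation intensity (mA), clipped to [1, 2]
  tav <- pmin(pmax(stats::rnorm(design$n_subjects, 1.91, 0.23), 1), 2)
  sham <- pmin(pmax(stats::rnorm(design$n_subjects, 1.87, 0.25), 1), 2)
  cbind(sham = sham, taVNS = tav)
}

session_order <- function(design, subject) {
  if (design$counterbalance && subject %% 2 == 0) c(0L, 1L) else c(1L, 0L)
}

# Slow drift + hippus-like band-limited noise for one session.
pupil_background <- function(time, effects) {
  drift <- effects$drift_amp *
    sin(2 * pi * stats::runif(1, effects$drift_freq_hz[1],
                              effects$drift_freq_hz[2]) * time +
          stats::runif(1, 0, 2 * pi))
  hip <- effects$noise_sd * sqrt(2) *
    sin(2 * pi * stats::runif(1, effects$osc_freq_hz[1],
                              effects$osc_freq_hz[2]) * time +
          stats::runif(1, 0, 2 * pi))
  effects$baseline_au + drift + hip
}

# Inject one blink into `p` (numeric) near trial onset; returns list with the
# modified series plus indices of spike and missing samples.
inject_blink <- function(p, rate, onset_idx, window_n, effects) {
  dur_n <- round(stats::runif(1, 0.1, 0.4) * rate)
  start <- onset_idx + sample.int(max(window_n - dur_n, 1L), 1L) - 1L
  end <- min(start + dur_n - 1L, length(p))
  gap <- start:end
  n_spk <- 3L
  pre <- (start - n_spk):(start - 1L)
  post <- (end + 1L):(end + n_spk)
  pre <- pre[pre >= 1L]
  post <- post[post <= length(p)]
  spikes <- c(pre, post)
  signs <- rep_len(c(-1, 1), length(spikes))
  p[spikes] <- p[spikes] + signs *
    stats::runif(length(spikes), effects$blink_spike_amp[1],
                 effects$blink_spike_amp[2])
  p[gap] <- NA
  list(p = p, spikes = spikes, missing = gap)
}

# ---- generators ------------------------------------------------------------

#' Generate trial-level conflict-task behaviour
#'
#' Correctness is drawn from a logistic mixed model with subject random
#' intercepts and random slopes for stimulation and congruency at the
#' coefficients in `effects$behavior_betas` (stimulation intensity is
#' centered at 1.89 mA in the linear predictor).  Reaction times follow a
#' linear mixed model with a congruency shift and a per-trial slope.
#'
#' @param design a [study_design()].
#' @param effects an [effect_spec()].
#' @param seed integer RNG seed.
#' @return a data frame with one row per trial: `subject`, `trialnumber`,
#'   `block`, `congruency`, `stimulation`, `face`, `intensity`, `correct`,
#'   `rt_ms`; generative random effects are attached as
#'   `attr(, "ranef_truth")`.
#' @export
gen_behavior <- function(design, effects, seed) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  set.seed(seed)
  b <- effects$behavior_betas
  rsd <- effects$behavior_ranef_sd
  intens <- subject_intensities(design)
  per_block <- design$trials_per_block
  n_sess_trials <- design$n_blocks_est * per_block
  rows <- vector("list", design$n_subjects)
  ran <- data.frame(subject = seq_len(design$n_subjects),
                    u_intercept = stats::rnorm(design$n_subjects, 0,
                                               rsd[["intercept"]]),
                    u_stimulation = stats::rnorm(design$n_subjects, 0,
                                                 rsd[["stimulation"]]),
                    u_congruency = stats::rnorm(design$n_subjects, 0,
                                                rsd[["congruency"]]))
  for (s in seq_len(design$n_subjects)) {
    ord <- session_order(design, s)
    tn <- 0L
    sess <- vector("list", 2L)
    for (k in 1:2) {
      stim <- ord[k]
      cong <- unlist(lapply(seq_len(design$n_blocks_est), function(bl)
        sample(rep(0:1, per_block / 2))))
      face <- stats::rbinom(n_sess_trials, 1, 0.5)
      tns <- tn + seq_len(n_sess_trials)
      tn <- tn + n_sess_trials
      sess[[k]] <- data.frame(
        subject = s,
        trialnumber = tns,
        block = (k - 1L) * design$n_blocks_est +
          rep(seq_len(design$n_blocks_est), each = per_block),
        congruency = cong, stimulation = stim, face = face,
        intensity = unname(intens[s, stim + 1L]))
    }
    rows[[s]] <- rbind(sess[[1]], sess[[2]])
  }
  dat <- do.call(rbind, rows)
  eta <- b[["intercept"]] +
    b[["trialnumber"]] * dat$trialnumber +
    b[["face"]] * dat$face +
    b[["intensity"]] * (dat$intensity - 1.89) +
    b[["stimulation"]] * dat$stimulation +
    b[["congruency"]] * dat$congruency +
    b[["interaction"]] * dat$stimulation * dat$congruency +
    ran$u_intercept[dat$subject] +
    ran$u_stimulation[dat$subject] * dat$stimulation +
    ran$u_congruency[dat$subject] * dat$congruency
  dat$correct <- stats::rbinom(nrow(dat), 1, stats::plogis(eta))
  rt_subj <- stats::rnorm(design$n_subjects, 0, effects$rt_subject_sd)
  dat$rt_ms <- effects$rt_mean_ms +
    effects$rt_effect_congruency * dat$congruency +
    effects$rt_effect_trial * dat$trialnumber +
    rt_subj[dat$subject] +
    stats::rnorm(nrow(dat), 0, effects$rt_resid_sd)
  dat$rt_ms <- pmax(dat$rt_ms, 150)
  attr(dat, "ranef_truth") <- ran
  dat
}

# Shared body for the two pupil-task generators.
gen_pupil_task <- function(design, effects, seed, task) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  set.seed(seed)
  rate <- design$pupil_rate
  dt <- 1 / rate
  intens <- subject_intensities(design)
  traces <- list()
  events <- list()
  truth <- list()
  artifacts <- list()
  for (s in seq_len(design$n_subjects)) {
    for (stim in session_order(design, s)) {
      id <- sprintf("s%02d_%s", s, if (stim == 1) "taVNS" else "sham")
      tl <- if (task == "EST") est_trial_onsets(design) else
        plrt_trial_onsets(design)
      n <- ceiling(tl$total_s * rate) + 1L
      time <- (seq_len(n) - 1L) * dt
      p <- pupil_background(time, effects)
      ev <- data.frame(trace_id = id, subject = s, task = task,
                       onset_s = tl$onsets, trial = seq_len(tl$n_trials),
                       stimulation = stim,
                       intensity = unname(intens[s, stim + 1L]))
      if (task == "EST") {
        ev$congruency <- unlist(lapply(seq_len(design$n_blocks_est),
                                       function(bl)
                                         sample(rep(0:1,
                                                    design$trials_per_block / 2))))
        ev$face <- stats::rbinom(tl$n_trials, 1, 0.5)
        amp <- effects$dilation_amp +
          effects$pupil_effect_congruency * (1 - ev$congruency) +
          effects$pupil_effect_stimulation * stim +
          effects$pupil_effect_interaction * stim * (1 - ev$congruency)
        tr <- data.frame(ev, amp_dilation = amp)
      } else {
        lat <- effects$plr_latency_ms + effects$plr_latency_shift_ms * stim
        amp <- effects$plr_amplitude *
          ifelse(stim == 1, effects$plr_amplitude_scale, 1)
        pk <- plr_template_peak(effects$plr_constrict_tau_s,
                                effects$plr_redilate_tau_s)
        tr <- data.frame(ev, latency_ms = lat, amplitude = amp,
                         t_peak_ms = lat + 1000 * pk$x)
      }
      for (i in seq_len(tl$n_trials)) {
        rel <- time - tl$onsets[i]
        if (task == "EST") {
          p <- p + effects$est_reflex_amp *
            est_reflex_kernel(rel, effects$est_reflex_dur_s) +
            tr$amp_dilation[i] *
            dilation_kernel(rel, effects$dilation_peak_s)
        } else {
          p <- p + plr_template(rel, tr$latency_ms[i], tr$amplitude[i],
                                effects$plr_constrict_tau_s,
                                effects$plr_redilate_tau_s)
        }
      }
      spikes <- integer(0)
      miss <- integer(0)
      post_n <- round((if (task == "EST") 1 + design$est_post_s else
        0.5 + design$plrt_post_s / 4) * rate)
      for (i in seq_len(tl$n_trials)) {
        if (stats::runif(1) < effects$blink_rate) {
          onset_idx <- round(tl$onsets[i] * rate) + 1L
          bl <- inject_blink(p, rate, onset_idx, post_n, effects)
          p <- bl$p
          spikes <- c(spikes, bl$spikes)
          miss <- c(miss, bl$missing)
        }
      }
      ok <- !is.na(p)
      p[ok] <- round(p[ok] / effects$quantum) * effects$quantum
      traces[[id]] <- pupil_trace(time, p)
      events[[id]] <- ev
      truth[[id]] <- tr
      if (length(spikes) || length(miss))
        artifacts[[id]] <- data.frame(
          trace_id = id,
          sample = c(spikes, miss),
          type = rep(c("spike", "missing"),
                     c(length(spikes), length(miss))))
    }
  }
  structure(list(traces = traces,
                 events = do.call(rbind, c(events, make.row.names = FALSE)),
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 artifacts = if (length(artifacts))
                   do.call(rbind, c(artifacts, make.row.names = FALSE))
                 else data.frame(trace_id = character(0), sample = integer(0),
                                 type = character(0)),
                 task = task, rate = rate),
            class = "sim_pupil")
}

#' Generate conflict-task pupil traces
#'
#' Each session trace is the sum of a slow drift, a hippus-like band-limited
#' oscillation, a picture-evoked light-reflex constriction, and a
#' gamma-shaped dilation whose amplitude carries the congruency and
#' stimulation effects, plus blink artifacts (missing runs flanked by spike
#' samples) and recorder quantization.  Ground-truth per-trial dilation
#' amplitudes and artifact sample indices are returned for recovery tests.
#'
#' @inheritParams gen_behavior
#' @return a `sim_pupil` list: `traces` (named [pupil_trace()] per
#'   subject-session), `events`, `truth`, `artifacts`.
#' @export
gen_pupil_est <- function(design, effects, seed) {
  gen_pupil_task(design, effects, seed, "EST")
}

#' Generate passive light-reflex-task pupil traces
#'
#' Each trial carries a parametric light reflex ([plr_template()]) whose
#' latency and amplitude depend on the stimulation condition; ground-truth
#' latency, amplitude and peak-constriction time are returned per trial.
#'
#' @inheritParams gen_behavior
#' @return a `sim_pupil` list as in [gen_pupil_est()].
#' @export
gen_plrt <- function(design, effects, seed) {
  gen_pupil_task(design, effects, seed, "PLRT")
}

#' Continuous multi-channel signal container
#'
#' @param time sample times (s), uniform rate.
#' @param data numeric matrix, samples x channels.
#' @param channels channel names.
#' @param rate sampling rate (Hz).
#' @param markers stimulation pulse onset times (s).
#' @return a `cont_signal` object.
#' @export
cont_signal <- function(time, data, channels = colnames(data), rate,
                        markers = numeric(0)) {
  data <- as.matrix(data)
  stopifnot(length(time) == nrow(data))
  if (length(markers) && (min(markers) < time[1] || max(markers) > time[length(time)]))
    stop("markers must lie within the recording")
  colnames(data) <- channels
  structure(list(time = time, data = data, channels = channels,
                 rate = rate, markers = sort(markers)),
            class = "cont_signal")
}

# 1/f ("pink") background noise via spectral shaping.
pink_noise <- function(n, sd = 1) {
  nf <- 2^ceiling(log2(max(n, 2)))
  f <- c(1, seq_len(nf / 2), rev(seq_len(nf / 2 - 1)))
  x <- stats::rnorm(nf)
  sp <- stats::fft(x) / sqrt(f)
  out <- Re(stats::fft(sp, inverse = TRUE))[seq_len(n)]
  out * sd / stats::sd(out)
}

#' Generate MEG-like signals with stimulation-artifact pulse trains
#'
#' Per subject-session continuous signals at `design$meg_rate`: a 1/f
#' background plus trial-locked band-limited oscillations (theta on
#' frontal-midline channels, alpha on occipital-midline channels) whose
#' post-stimulus power carries the condition effects, and a large biphasic
#' artifact transient after each stimulation pulse onset.  Pulse markers
#' (15 per 500 ms train at 30 Hz) are listed exactly.
#'
#' @inheritParams gen_behavior
#' @param n_trials trials per session; defaults to one conflict-task
#'   block's worth per stimulation condition.
#' @param channel_groups named list of channel names for the
#'   frontal-midline (`FM`) and occipital-midline (`OM`) groups.
#' @return list with `signals` (named [cont_signal()] per subject-session),
#'   `events`, `markers`, `truth`, `groups`.
#' @export
gen_meg <- function(design, effects, seed,
                    n_trials = design$trials_per_block,
                    channel_groups = list(FM = c("fm1", "fm2", "fm3"),
                                          OM = c("om1", "om2", "om3"))) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  if (!all(c("FM", "OM") %in% names(channel_groups)))
    stop("`channel_groups` must name FM and OM channel sets")
  set.seed(seed)
  rate <- design$meg_rate
  chans <- unlist(channel_groups, use.names = FALSE)
  intens <- subject_intensities(design)
  npulse <- n_pulses(design$stim_train)
  pulse_step <- 1 / design$stim_train$frequency
  signals <- list()
  events <- list()
  markers_all <- list()
  truth <- list()
  for (s in seq_len(design$n_subjects)) {
    for (stim in session_order(design, s)) {
      id <- sprintf("s%02d_%s", s, if (stim == 1) "taVNS" else "sham")
      isi <- stats::runif(n_trials, design$isi_range_est[1],
                          design$isi_range_est[2])
      step <- 1 + design$est_post_s + isi + 2
      onsets <- 2.5 + c(0, cumsum(step[-n_trials]))
      onsets <- round(onsets * rate) / rate
      total <- onsets[n_trials] + 1 + design$est_post_s + 1
      n <- ceiling(total * rate) + 1L
      time <- (seq_len(n) - 1L) / rate
      cong <- sample(rep(0:1, ceiling(n_trials / 2)))[seq_len(n_trials)]
      theta_f <- stats::runif(n_trials, 4.5, 7.5)
      alpha_f <- stats::runif(n_trials, 9, 12.5)
      theta_post <- effects$osc_base_amp[["theta"]] *
        sqrt(if (stim == 1) effects$theta_effect else 1) *
        sqrt(ifelse(cong == 0, effects$congruency_theta_effect, 1))
      alpha_post <- rep(effects$osc_base_amp[["alpha"]] *
                          sqrt(if (stim == 1) effects$alpha_effect else 1),
                        n_trials)
      theta_sig <- numeric(n)
      alpha_sig <- numeric(n)
      for (i in seq_len(n_trials)) {
        rel <- time - onsets[i]
        win <- rel >= -2 & rel <= 5
        amp_t <- ifelse(rel[win] < 0, effects$osc_base_amp[["theta"]],
                        theta_post[i])
        amp_a <- ifelse(rel[win] < 0, effects$osc_base_amp[["alpha"]],
                        alpha_post[i])
        ph_t <- stats::runif(1, 0, 2 * pi)
        ph_a <- stats::runif(1, 0, 2 * pi)
        theta_sig[win] <- theta_sig[win] +
          amp_t * sin(2 * pi * theta_f[i] * rel[win] + ph_t)
        alpha_sig[win] <- alpha_sig[win] +
          amp_a * sin(2 * pi * alpha_f[i] * rel[win] + ph_a)
      }
      dat <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
      for (ch in chans) {
        bg <- pink_noise(n, effects$meg_noise_sd)
        dat[, ch] <- bg + if (ch %in% channel_groups$FM) theta_sig else
          alpha_sig
      }
      mk <- as.vector(outer(seq_len(npulse) - 1L, onsets,
                            function(k, o) o + k * pulse_step))
      mk <- sort(mk)
      sd_clean <- stats::sd(dat[, 1])
      art_shape <- effects$artifact_scale * sd_clean * c(0.5, 1, -1, -0.5)
      for (m in mk) {
        i0 <- round(m * rate) + 1L
        idx <- i0:(i0 + 3L)
        idx <- idx[idx <= n]
        dat[idx, ] <- dat[idx, ] + art_shape[seq_along(idx)]
      }
      signals[[id]] <- cont_signal(time, dat, chans, rate, mk)
      events[[id]] <- data.frame(trace_id = id, subject = s, task = "EST",
                                 onset_s = onsets, trial = seq_len(n_trials),
                                 congruency = cong, stimulation = stim,
                                 intensity = unname(intens[s, stim + 1L]))
      markers_all[[id]] <- data.frame(trace_id = id, onset_s = mk,
                                      trial = rep(seq_len(n_trials),
                                                  each = npulse))
      truth[[id]] <- data.frame(trace_id = id, trial = seq_len(n_trials),
                                congruency = cong, stimulation = stim,
                                theta_amp = theta_post,
                                alpha_amp = alpha_post)
    }
  }
  list(signals = signals,
       events = do.call(rbind, c(events, make.row.names = FALSE)),
       markers = do.call(rbind, c(markers_all, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       groups = channel_groups)
}
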