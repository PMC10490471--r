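# Study design and effect-size containers for the synthetic-data generator.

#' Stimulation train parameters
#'
#' Describes one phasic stimulation train: short pulse trains delivered at
#' stimulus onset.  Defaults follow the standard phasic taVNS protocol:
#' 500 ms trains of 30 Hz monophasic square-wave pulses, 200 microsecond
#' pulse width, 2 mA amplitude.
#'
#' @param frequency pulse frequency in Hz.
#' @param duration_ms train duration in milliseconds.
#' @param pulse_width_us single pulse width in microseconds.
#' @param amplitude_ma stimulation amplitude in milliampere.
#' @return an object of class `stim_train`.
#' @seealso [n_pulses()]
#' @export
stim_train <- function(frequency = 30, duration_ms = 500,
                       pulse_width_us = 200, amplitude_ma = 2) {
  stopifnot_scalar_pos(frequency, "frequency")
  stopifnot_scalar_pos(duration_ms, "duration_ms")
  stopifnot_scalar_pos(pulse_width_us, "pulse_width_us")
  stopifnot_scalar_pos(amplitude_ma, "amplitude_ma")
  structure(list(frequency = frequency, duration_ms = duration_ms,
                 pulse_width_us = pulse_width_us,
                 amplitude_ma = amplitude_ma),
            class = "stim_train")
}

#' Number of pulses per train
#'
#' Integer-truncated product of train frequency and duration
#' (e.g. 30 Hz x 500 ms gives 15 pulses).
#'
#' @param train a [stim_train()] object.
#' @return integer pulse count.
#' @export
n_pulses <- function(train) {
  stopifnot(inherits(train, "stim_train"))
  as.integer(floor(train$frequency * train$duration_ms / 1000))
}

#' Study design for the two-task stimulation experiment
#'
#' Captures the structural parameters of the paradigm: a conflict
#' (emotional Stroop) task of `n_blocks_est` blocks of `trials_per_block`
#' trials (half congruent, half incongruent) per stimulation condition, and
#' a passive pupil light reflex task of `n_trials_plrt` flash trials per
#' stimulation condition.  Each subject performs both tasks under active
#' and sham stimulation, with the order counterbalanced across subjects.
#'
#' @param n_subjects number of subjects.
#' @param n_blocks_est conflict-task blocks per stimulation condition.
#' @param trials_per_block trials per block; must be even (50/50
#'   congruent/incongruent split).
#' @param n_trials_plrt flash trials per stimulation condition.
#' @param pupil_rate pupil sampling rate in Hz.
#' @param meg_rate electrophysiology sampling rate in Hz.
#' @param isi_range_est inter-stimulus interval range (s) in the conflict
#'   task.
#' @param isi_range_plrt inter-stimulus interval range (s) in the light
#'   reflex task.
#' @param stim_train a [stim_train()] object.
#' @param counterbalance logical; alternate stimulation order across
#'   subjects.
#' @param est_post_s fixation period after conflict-task stimulus offset (s).
#' @param plrt_post_s fixation period after the flash (s).
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_subjects = 29, n_blocks_est = 6,
                         trials_per_block = 20, n_trials_plrt = 20,
                         pupil_rate = 500, meg_rate = 1000,
                         isi_range_est = c(1, 4), isi_range_plrt = c(8, 12),
                         stim_train = phasicpupil::stim_train(),
                         counterbalance = TRUE,
                         est_post_s = 5, plrt_post_s = 20) {
  stopifnot_scalar_pos(n_subjects, "n_subjects")
  stopifnot_scalar_pos(n_blocks_est, "n_blocks_est")
  stopifnot_scalar_pos(trials_per_block, "trials_per_block")
  stopifnot_scalar_pos(n_trials_plrt, "n_trials_plrt")
  stopifnot_scalar_pos(pupil_rate, "pupil_rate")
  stopifnot_scalar_pos(meg_rate, "meg_rate")
  if (trials_per_block %% 2 != 0)
    stop("`trials_per_block` must be even for a 50/50 congruency split")
  for (r in list(isi_range_est, isi_range_plrt))
    if (length(r) != 2L || r[1] > r[2] || any(r < 0))
      stop("ISI ranges must be ordered non-negative pairs")
  stopifnot(inherits(stim_train, "stim_train"))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_blocks_est = as.integer(n_blocks_est),
                 trials_per_block = as.integer(trials_per_block),
                 n_trials_plrt = as.integer(n_trials_plrt),
                 pupil_rate = pupil_rate, meg_rate = meg_rate,
                 isi_range_est = isi_range_est,
                 isi_range_plrt = isi_range_plrt,
                 stim_train = stim_train,
                 counterbalance = isTRUE(counterbalance),
                 est_post_s = est_post_s, plrt_post_s = plrt_post_s),
            class = "study_design")
}

#' Generative effect sizes for the synthetic data
#'
#' All behavioural coefficients are on the log-odds scale and default to the
#' fixed effects of the trial-level accuracy model (congruency 0.92,
#' stimulation 0.44, trial number 0.005, corresponding to odds ratios 2.51,
#' 1.55 and 1.005).  Pupil quantities are in arbitrary recorder units
#' (a.u.); the light-reflex defaults place the sham onset latency at
#' 170.83 ms with a +27.09 ms active-stimulation delay and a 0.925
#' constriction-amplitude scaling.  Oscillatory effects are power ratios
#' applied to the post-stimulus band-limited components (frontal-midline
#' theta up, occipital-midline alpha down under active stimulation).
#'
#' The pupil noise model is deliberately band-limited: a slow drift plus a
#' hippus-like oscillation (`noise_sd`, `osc_freq_hz`), with the trace
#' quantized to `quantum` a.u. as eye trackers do.  See the methods
#' vignette for why broadband white noise is not simulated.
#'
#' @param behavior_betas named log-odds coefficients (intercept,
#'   trialnumber, face, intensity, stimulation, congruency, interaction).
#' @param behavior_ranef_sd named SDs of subject random intercept and
#'   slopes for stimulation and congruency.
#' @param rt_mean_ms mean reaction time in incongruent trials (ms).
#' @param rt_effect_congruency RT shift for congruent trials (ms, negative
#'   means faster).
#' @param rt_effect_trial RT slope per trial (ms).
#' @param rt_subject_sd,rt_resid_sd between-subject and residual RT SDs (ms).
#' @param pupil_effect_congruency extra dilation amplitude for incongruent
#'   trials (a.u.).
#' @param pupil_effect_stimulation extra dilation amplitude under active
#'   stimulation (a.u.).
#' @param pupil_effect_interaction amplitude for the
#'   stimulation-by-congruency interaction (a.u.).
#' @param dilation_amp baseline task-evoked dilation amplitude (a.u.).
#' @param dilation_peak_s peak latency of the gamma-shaped dilation
#'   component (s).
#' @param est_reflex_amp,est_reflex_dur_s amplitude (a.u.) and constriction
#'   duration (s) of the picture-evoked light reflex in the conflict task.
#' @param plr_latency_ms sham light-reflex onset latency (ms).
#' @param plr_latency_shift_ms latency delay added under active
#'   stimulation (ms).
#' @param plr_amplitude sham peak constriction depth (a.u., positive).
#' @param plr_amplitude_scale multiplicative amplitude factor under active
#'   stimulation.
#' @param plr_constrict_tau_s,plr_redilate_tau_s constriction and
#'   redilation time constants (s).
#' @param baseline_au mean pupil size (a.u.).
#' @param drift_amp,drift_freq_hz slow drift amplitude (a.u.) and frequency
#'   range (Hz).
#' @param noise_sd SD of the band-limited hippus-like pupil noise (a.u.).
#' @param osc_freq_hz frequency range of that noise component (Hz).
#' @param quantum quantization step of the recorded pupil signal (a.u.).
#' @param blink_rate per-trial blink probability in `[0, 1]`.
#' @param blink_spike_amp amplitude range of the spikes flanking a blink
#'   (a.u.).
#' @param theta_effect frontal-midline theta power ratio (active / sham).
#' @param alpha_effect occipital-midline alpha power ratio (active / sham).
#' @param congruency_theta_effect frontal theta power ratio
#'   (incongruent / congruent).
#' @param osc_base_amp named baseline oscillation amplitudes (theta, alpha)
#'   in field units.
#' @param meg_noise_sd SD of the 1/f background (field units).
#' @param artifact_scale stimulation-artifact amplitude as a multiple of
#'   the signal SD.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(
    behavior_betas = c(intercept = 2, trialnumber = 0.005, face = 0.06,
                       intensity = -0.24, stimulation = 0.44,
                       congruency = 0.92, interaction = 0.02),
    behavior_ranef_sd = c(intercept = 0.5, stimulation = 0.2,
                          congruency = 0.3),
    rt_mean_ms = 753.69, rt_effect_congruency = -53.81,
    rt_effect_trial = -0.49, rt_subject_sd = 120, rt_resid_sd = 230,
    pupil_effect_congruency = 7, pupil_effect_stimulation = 13.5,
    pupil_effect_interaction = 0,
    dilation_amp = 40, dilation_peak_s = 1.3,
    est_reflex_amp = 30, est_reflex_dur_s = 1,
    plr_latency_ms = 170.83, plr_latency_shift_ms = 27.09,
    plr_amplitude = 200, plr_amplitude_scale = 0.925,
    plr_constrict_tau_s = 0.7, plr_redilate_tau_s = 2.5,
    baseline_au = 1000, drift_amp = 30, drift_freq_hz = c(0.05, 0.15),
    noise_sd = 15, osc_freq_hz = c(3, 4), quantum = 0.1,
    blink_rate = 0.3, blink_spike_amp = c(100, 400),
    theta_effect = 1.3, alpha_effect = 0.75,
    congruency_theta_effect = 1.15,
    osc_base_amp = c(theta = 1.5, alpha = 2),
    meg_noise_sd = 1, artifact_scale = 50) {
  if (blink_rate < 0 || blink_rate > 1)
    stop("`blink_rate` must lie in [0, 1]")
  if (plr_amplitude_scale <= 0)
    stop("`plr_amplitude_scale` must be positive")
  for (nm in c("theta_effect", "alpha_effect", "congruency_theta_effect",
               "quantum", "plr_constrict_tau_s", "plr_redilate_tau_s"))
    stopifnot_scalar_pos(get(nm), nm)
  if (noise_sd < 0 || drift_amp < 0 || meg_noise_sd < 0)
    stop("noise scales must be non-negative")
  structure(mget(names(formals(effect_spec))), class = "effect_spec")
}
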