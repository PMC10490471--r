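# Shared fixtures: small study designs and an epoch-preparation helper that
# mirrors the preprocessing order (clean continuous trace, epoch, reject,
# normalize).

small_design <- function(...) {
  study_design(n_subjects = 2, n_blocks_est = 1, n_trials_plrt = 4,
               plrt_post_s = 8, ...)
}

quiet_effects <- function(...) {
  # deterministic trace: no noise, drift, or blinks
  effect_spec(noise_sd = 0, drift_amp = 0, blink_rate = 0, ...)
}

prep_epochs <- function(sim, window, cfg = clean_config(), clean = TRUE) {
  eps <- lapply(names(sim$traces), function(id) {
    tr <- sim$traces[[id]]
    if (clean) tr <- two_pass_clean(tr, cfg)$trace
    epoch_trials(tr, sim$events[sim$events$trace_id == id, , drop = FALSE],
                 window)
  })
  normalize_epochs(reject_missing(bind_epochs(eps), cfg), cfg)
}

make_meg_epochs <- function(trials, rate = 250, window = c(-2, 5),
                            channels = "ch") {
  # trials: list of matrices (time x channel) or vectors
  time <- seq(window[1], window[2], by = 1 / rate)
  n_ch <- length(channels)
  dat <- array(NA_real_, c(length(trials), length(time), n_ch),
               dimnames = list(NULL, NULL, channels))
  for (i in seq_along(trials)) {
    m <- trials[[i]]
    if (is.null(dim(m))) m <- matrix(m, ncol = n_ch)
    dat[i, , ] <- m
  }
  structure(list(data = dat, time = time, rate = rate, channels = channels,
                 labels = data.frame(trial = seq_along(trials)),
                 baselines = matrix(0, length(trials), n_ch),
                 rejected = logical(length(trials)),
                 reject_reason = character(length(trials))),
            class = "meg_epoch_set")
}
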