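# Deterministic end-to-end orchestration over synthetic data: simulate both
# tasks, preprocess, extract light-reflex kinematics, fit the behaviour
# models, clean and spectrally analyze the electrophysiology, run the
# cluster permutation tests, and relate stimulation deltas across tasks.

#' Default (desk-scale) pipeline configuration
#'
#' A scaled-down version of the full study design so the complete pipeline
#' runs in minutes: fewer subjects and trials, reduced permutation counts.
#' All stage configurations can be overridden.
#'
#' @param n_subjects subjects to simulate.
#' @param n_perm permutations for the cluster tests.
#' @return a `run_config` list.
#' @export
default_config <- function(n_subjects = 8, n_perm = 500) {
  list(
    design = study_design(n_subjects = n_subjects, n_blocks_est = 1,
                          n_trials_plrt = 6, plrt_post_s = 7.5),
    effects = effect_spec(),
    clean = clean_config(),
    artifact = artifact_config(),
    meg_trials = 6,
    n_perm = n_perm,
    stages = c("simulate", "pupil", "plr", "behavior", "meg", "cbpt",
               "crosstask"))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages run in dependency order; each stage draws its randomness from a
#' seed derived deterministically from the top-level `seed`, so a rerun
#' with the same configuration reproduces every output bit-identically.
#' Stage outputs (epoch sets, metrics tables, cluster reports) are written
#' under `out_dir` together with a JSON manifest recording the seed,
#' configuration summary and bookkeeping counts.
#'
#' @param config a [default_config()]-style list.
#' @param seed top-level integer seed.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = NULL) {
  design <- config$design
  effects <- config$effects
  cfg <- config$clean
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list()
  counts <- list()

  # --- simulate -------------------------------------------------------
  behav <- gen_behavior(design, effects, derive_seed(seed, "behavior"))
  est <- gen_pupil_est(design, effects, derive_seed(seed, "pupil_est"))
  plrt <- gen_plrt(design, effects, derive_seed(seed, "plrt"))
  meg <- gen_meg(design, effects, derive_seed(seed, "meg"),
                 n_trials = config$meg_trials)

  # --- pupil preprocessing -------------------------------------------
  prep_task <- function(sim, window) {
    eps <- lapply(names(sim$traces), function(id) {
      cleaned <- two_pass_clean(sim$traces[[id]], cfg)$trace
      ev <- sim$events[sim$events$trace_id == id, , drop = FALSE]
      epoch_trials(cleaned, ev, window)
    })
    normalize_epochs(reject_missing(bind_epochs(eps), cfg), cfg)
  }
  ep_est <- prep_task(est, cfg$epoch_est)
  ep_plrt <- prep_task(plrt, cfg$epoch_plrt)
  counts$est_rejected <- sum(ep_est$rejected)
  counts$plrt_rejected <- sum(ep_plrt$rejected)

  # --- light reflex kinematics ---------------------------------------
  plr_tab <- plr_metrics_table(ep_plrt, smooth_ms = 20)
  lat_fit <- fit_mixed(onset_latency_ms ~ stimulation + (1 | subject),
                       plr_tab, lrt = TRUE)
  res$plr <- list(metrics = plr_tab, latency_fit = lat_fit)

  # --- behaviour ------------------------------------------------------
  behav$intensity_c <- behav$intensity - mean(behav$intensity)
  acc_fit <- fit_mixed(
    correct ~ trialnumber + face + intensity_c +
      stimulation * congruency +
      (1 + stimulation + congruency || subject),
    behav, family = "binomial", lrt = FALSE, nagq = 0L)
  rt_fit <- fit_mixed(
    rt_ms ~ trialnumber + face + intensity_c + stimulation * congruency +
      (1 + stimulation + congruency || subject),
    behav[behav$correct == 1, ], lrt = TRUE)
  res$behavior <- list(
    accuracy_fit = acc_fit,
    odds_ratios = if (acc_fit$converged) odds_ratio(acc_fit$beta) else NULL,
    rt_fit = rt_fit)

  # --- MEG cleaning and spectra --------------------------------------
  acfg <- config$artifact
  spec_rows <- list()
  for (id in names(meg$signals)) {
    sig <- meg$signals[[id]]
    sig <- ar_fill(blank_pulses(sig, acfg), acfg)
    sig <- filter_chain(sig, acfg)
    ev <- meg$events[meg$events$trace_id == id, , drop = FALSE]
    mep <- epoch_and_baseline(sig, ev, acfg)
    sp <- group_average(fft_power(mep), meg$groups)
    spec_rows[[id]] <- list(spec = sp, labels = mep$labels)
  }
  # subject x condition mean spectra per group
  spec_mean <- do.call(rbind, lapply(spec_rows, function(r) {
    keep <- !r$spec$rejected
    data.frame(subject = r$labels$subject[1],
               stimulation = r$labels$stimulation[1],
               group = rep(c("FM", "OM"),
                           each = length(r$spec$freqs)),
               freq = rep(r$spec$freqs, 2),
               power = c(colMeans(r$spec$power[keep, , "FM",
                                               drop = FALSE][, , 1]),
                         colMeans(r$spec$power[keep, , "OM",
                                               drop = FALSE][, , 1])))
  }))
  res$spectra <- spec_mean

  # --- cluster permutation tests -------------------------------------
  scheme <- perm_scheme(n_perm = config$n_perm,
                        seed = derive_seed(seed, "cbpt"))
  paired_from_avg <- function(avg) {
    wide <- split(seq_len(nrow(avg$groups)), avg$groups$subject)
    D <- t(vapply(wide, function(ix) {
      a <- avg$data[ix[avg$groups$stimulation[ix] == 1][1], ]
      r <- avg$data[ix[avg$groups$stimulation[ix] == 0][1], ]
      a - r
    }, numeric(ncol(avg$data))))
    D[stats::complete.cases(D), , drop = FALSE]
  }
  avg_est <- average_epochs(ep_est, by = c("subject", "stimulation"))
  avg_plrt <- average_epochs(ep_plrt, by = c("subject", "stimulation"))
  D_est <- paired_from_avg(avg_est)
  D_plrt <- paired_from_avg(avg_plrt)
  res$cbpt <- list(
    pupil_est = paired_cbpt(D_est, scheme, axis = avg_est$time),
    pupil_plrt = paired_cbpt(D_plrt, scheme, axis = avg_plrt$time))
  spec_delta <- function(group) {
    sub <- spec_mean[spec_mean$group == group, ]
    wide <- stats::reshape(sub, idvar = c("subject", "stimulation"),
                           timevar = "freq", direction = "wide")
    vals <- as.matrix(wide[, grep("^power", names(wide))])
    compute_deltas(vals, wide$subject, wide$stimulation,
                   axis = sort(unique(sub$freq)))
  }
  d_fm <- spec_delta("FM")
  d_om <- spec_delta("OM")
  res$cbpt$psd_fm <- paired_cbpt(d_fm$delta, scheme, axis = d_fm$axis)
  res$cbpt$psd_om <- paired_cbpt(d_om$delta, scheme, axis = d_om$axis)
  counts$significant_clusters <- sum(vapply(res$cbpt, function(r)
    sum(r$clusters$p <= 0.05), numeric(1)))

  # --- cross-task deltas ---------------------------------------------
  cl_om <- res$cbpt$psd_om$clusters
  if (nrow(cl_om) && nrow(d_fm$delta) >= 5) {
    biggest <- cl_om[which.max(abs(cl_om$mass)), ]
    pred <- data.frame(om_cluster = cluster_average_delta(d_om, biggest))
    res$crosstask <- predict_across(
      structure(list(delta = d_fm$delta, subjects = d_fm$subjects,
                     axis = d_fm$axis), class = "delta_series"),
      pred, scheme)
  }

  # --- outputs and manifest ------------------------------------------
  if (!is.null(out_dir)) {
    write_epoch_set(ep_est, file.path(out_dir, "epochs_est"))
    write_epoch_set(ep_plrt, file.path(out_dir, "epochs_plrt"))
    write_tsv(plr_tab, file.path(out_dir, "plr_metrics.tsv"),
              "PLR kinematics per subject x stimulation")
    write_tsv(spec_mean, file.path(out_dir, "spectra.tsv"),
              "FFT power per subject x condition x sensor group")
    for (nm in names(res$cbpt))
      write_cluster_report(res$cbpt[[nm]],
                           file.path(out_dir, paste0("cbpt_", nm, ".json")))
    manifest <- list(seed = seed,
                     package = as.character(utils::packageVersion("phasicpupil")),
                     n_subjects = design$n_subjects,
                     stages = config$stages, counts = counts)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  res$counts <- counts
  invisible(res)
}
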