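# Synthetic-data generators: determinism, design conservation, and the
# statistical structure the downstream analyses assume.

test_that("generators are deterministic under a fixed seed", {
  des <- small_design()
  eff <- effect_spec()
  expect_identical(gen_behavior(des, eff, 7), gen_behavior(des, eff, 7))
  a <- gen_pupil_est(des, eff, 7)
  b <- gen_pupil_est(des, eff, 7)
  expect_identical(a$traces, b$traces)
  expect_identical(a$events, b$events)
  m1 <- gen_meg(des, eff, 7, n_trials = 4)
  m2 <- gen_meg(des, eff, 7, n_trials = 4)
  expect_identical(m1$signals[[1]]$data, m2$signals[[1]]$data)
})

test_that("behaviour generator conserves the design and hits the null", {
  des <- study_design(n_subjects = 10, n_blocks_est = 2)
  dat <- gen_behavior(des, effect_spec(), 3)
  # one row per subject x stimulation x block x trial
  expect_equal(nrow(dat), 10 * 2 * 2 * 20)
  expect_true(all(table(dat$subject, dat$stimulation) == 40))
  # 50/50 congruency split within each block
  split_ok <- tapply(dat$congruency,
                     interaction(dat$subject, dat$stimulation, dat$block,
                                 drop = TRUE), mean)
  expect_true(all(split_ok == 0.5))
  # null model: all betas and random SDs zero -> accuracy ~ 0.5
  eff0 <- effect_spec(
    behavior_betas = c(intercept = 0, trialnumber = 0, face = 0,
                       intensity = 0, stimulation = 0, congruency = 0,
                       interaction = 0),
    behavior_ranef_sd = c(intercept = 0, stimulation = 0, congruency = 0))
  des2 <- study_design(n_subjects = 20, n_blocks_est = 1)
  null <- gen_behavior(des2, eff0, 5)
  expect_lt(abs(mean(null$correct) - 0.5),
            4 * sqrt(0.25 / nrow(null)))
  expect_error(study_design(n_subjects = 0), "positive")
})

test_that("conflict-task pupil traces carry the generative structure", {
  des <- small_design()
  # deterministic: identical trials within condition
  sim0 <- gen_pupil_est(des, quiet_effects(), 2)
  ep <- prep_epochs(sim0, c(-2, 5), clean = FALSE)
  for (cg in 0:1) {
    rows <- which(ep$labels$congruency == cg & ep$labels$subject == 1 &
                    ep$labels$stimulation == 1)
    base <- ep$data[rows[1], ]
    for (r in rows[-1])
      expect_lt(max(abs(ep$data[r, ] - base)), 1e-6)
  }
  # stimulation effect: active-minus-sham condition mean positive in the
  # dilation window
  eff <- quiet_effects(pupil_effect_stimulation = 20)
  sim <- gen_pupil_est(des, eff, 2)
  ep2 <- prep_epochs(sim, c(-2, 5), clean = FALSE)
  win <- ep2$time > 0.5 & ep2$time < 3
  m1 <- colMeans(ep2$data[ep2$labels$stimulation == 1, win, drop = FALSE])
  m0 <- colMeans(ep2$data[ep2$labels$stimulation == 0, win, drop = FALSE])
  expect_gt(mean(m1 - m0), 0)
  # blink_rate 1: every trial contains at least one missing run
  simb <- gen_pupil_est(des, effect_spec(blink_rate = 1), 2)
  epb <- lapply(names(simb$traces), function(id)
    epoch_trials(simb$traces[[id]],
                 simb$events[simb$events$trace_id == id, ], c(0, 6)))
  miss_per_trial <- unlist(lapply(epb, function(e)
    rowSums(e$missing)[!e$rejected]))
  expect_true(all(miss_per_trial > 0))
  expect_error(effect_spec(blink_rate = 1.5), "blink_rate")
})

test_that("light-reflex generator reproduces its parametric ground truth", {
  des <- small_design()
  eff <- quiet_effects(plr_latency_ms = 170, plr_latency_shift_ms = 27)
  sim <- gen_plrt(des, eff, 4)
  expect_true(all(sim$truth$latency_ms[sim$truth$stimulation == 1] == 197))
  expect_true(all(sim$truth$latency_ms[sim$truth$stimulation == 0] == 170))
  # zero noise: trace equals baseline + template exactly (up to quantum)
  id <- "s01_sham"
  tr <- sim$traces[[id]]
  ev <- sim$events[sim$events$trace_id == id, ]
  t_rel <- tr$time - ev$onset_s[1]
  tmpl <- plr_template(t_rel, 170, eff$plr_amplitude)
  win <- t_rel > -1 & t_rel < 5
  expect_lt(max(abs((tr$pupil - eff$baseline_au - tmpl)[win])),
            eff$quantum)
  # amplitude scale 0.9 -> active peak constriction 10% shallower
  eff9 <- quiet_effects(plr_amplitude_scale = 0.9)
  sim9 <- gen_plrt(des, eff9, 4)
  depth <- function(id) {
    tr <- sim9$traces[[id]]
    eff9$baseline_au - min(tr$pupil, na.rm = TRUE)
  }
  expect_equal(depth("s01_taVNS") / depth("s01_sham"), 0.9,
               tolerance = 0.01)
  expect_error(effect_spec(plr_amplitude_scale = 0), "positive")
})

test_that("MEG generator emits exact pulse trains and condition power", {
  expect_equal(n_pulses(stim_train(30, 500)), 15L)
  expect_equal(n_pulses(stim_train(25, 500)), 12L)  # integer truncation
  des <- small_design()
  eff <- effect_spec(alpha_effect = 0.5)
  meg <- gen_meg(des, eff, 6, n_trials = 4)
  mk <- meg$markers[meg$markers$trace_id == names(meg$signals)[1], ]
  expect_equal(as.vector(table(mk$trial)), rep(15L, 4))
  # marker spacing exactly 1/30 s within a train
  expect_equal(diff(mk$onset_s[mk$trial == 1]), rep(1 / 30, 14))
  # artifact amplitude 0 -> signal equals clean oscillation mixture
  eff0 <- effect_spec(artifact_scale = 0)
  m0 <- gen_meg(des, eff0, 6, n_trials = 4)
  m1 <- gen_meg(des, effect_spec(artifact_scale = 50), 6, n_trials = 4)
  d <- m1$signals[[1]]$data - m0$signals[[1]]$data
  expect_gt(max(abs(d)), 0)
  # differences confined to 4 ms after markers
  bad <- which(abs(d[, 1]) > 0)
  mk1 <- m1$signals[[1]]$markers
  near <- vapply(bad, function(i) {
    t <- m1$signals[[1]]$time[i]
    # marker times are rounded to the sample grid when the transient is
    # placed, so allow one sample of slack on each side
    any(t >= mk1 - 0.001 & t < mk1 + 0.004)
  }, logical(1))
  expect_true(all(near))
  # alpha_effect < 1: occipital alpha band power lower in active trials
  band_var <- function(sig, ev) {
    bp <- signal::butter(4, c(8.5, 13) / (sig$rate / 2), type = "pass")
    x <- signal::filtfilt(bp, sig$data[, "om1"])
    idx <- unlist(lapply(ev$onset_s, function(o)
      which(sig$time > o + 0.1 & sig$time < o + 4.9)))
    stats::var(x[idx])
  }
  ids <- names(m0$signals)
  v_act <- band_var(m0$signals[["s01_taVNS"]],
                    m0$events[m0$events$trace_id == "s01_taVNS", ])
  v_sham <- band_var(m0$signals[["s01_sham"]],
                     m0$events[m0$events$trace_id == "s01_sham", ])
  expect_lt(v_act, v_sham)
  expect_error(gen_meg(des, eff, 1, channel_groups = list(A = "x")), "FM")
})
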