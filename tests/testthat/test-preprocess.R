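# Pupil preprocessing: epoching arithmetic, rejection rules, the two-pass
# dilation-speed/MAD cleaning, and normalization.

make_trace <- function(p, rate = 500) {
  pupil_trace((seq_along(p) - 1) / rate, p)
}

test_that("epoch_trials cuts the documented sample counts and flags edges", {
  rate <- 500
  tr <- make_trace(rep(5, 210 * rate))
  ev <- data.frame(onset_s = seq(5, 195, by = 10)[1:20])
  ep <- epoch_trials(tr, ev, c(-2, 5))
  expect_equal(dim(ep$data), c(20L, 3501L))  # (5 - (-2)) * 500 + 1
  expect_equal(ep$time[1], -2)
  expect_equal(ep$time[3501], 5)
  expect_false(any(ep$rejected))
  # empty event table
  ep0 <- epoch_trials(tr, data.frame(onset_s = numeric(0)), c(-2, 5))
  expect_equal(nrow(ep0$data), 0L)
  # onset too close to the recording edge is flagged, not dropped
  tr5 <- make_trace(rep(5, 5 * rate))
  epe <- epoch_trials(tr5, data.frame(onset_s = 1), c(-2, 5))
  expect_true(epe$rejected[1])
  expect_equal(epe$reject_reason[1], "edge")
})

test_that("missing-data rejection applies the strict >50% rules", {
  n_t <- 100
  mk_ep <- function(miss_frac, n_trials, subject = 1, congruency = 0) {
    data <- matrix(0, n_trials, n_t)
    miss <- matrix(FALSE, n_trials, n_t)
    for (i in seq_len(n_trials))
      if (miss_frac[i] > 0) miss[i, seq_len(round(miss_frac[i] * n_t))] <- TRUE
    structure(list(data = data, missing = miss, time = seq_len(n_t) / 100,
                   rate = 100,
                   labels = data.frame(subject = subject,
                                       stimulation = 0,
                                       congruency = congruency,
                                       trial = seq_len(n_trials)),
                   rejected = logical(n_trials),
                   reject_reason = character(n_trials)),
              class = "epoch_set")
  }
  ep <- reject_missing(mk_ep(c(0.51, 0.50, 0), 3))
  expect_equal(ep$rejected, c(TRUE, FALSE, FALSE))   # strictly above 50%
  expect_equal(ep$reject_reason[1], "missing")
  # 11 of 20 trials rejected in one condition -> subject wholly excluded
  ep2 <- reject_missing(mk_ep(c(rep(0.6, 11), rep(0, 9)), 20))
  expect_true(all(ep2$rejected))
  expect_equal(attr(ep2, "report")$excluded_subjects, 1L)
  # 10 of 20 (exactly 50%) does not exclude the subject
  ep3 <- reject_missing(mk_ep(c(rep(0.6, 10), rep(0, 10)), 20))
  expect_equal(sum(ep3$rejected), 10L)
  expect_length(attr(ep3, "report")$excluded_subjects, 0L)
})

test_that("dilation speed is the max absolute difference quotient", {
  expect_equal(dilation_speed(make_trace(rep(3, 10))), rep(0, 10))
  # linear ramp of slope k
  k <- 7
  tr <- make_trace(k * (0:9) / 500)
  expect_equal(dilation_speed(tr), rep(k, 10))
  # unit spike, dt = 2 ms: speed 500 at the spike and its neighbours
  p <- rep(1, 7); p[4] <- 2
  sp <- dilation_speed(make_trace(p))
  expect_equal(sp, c(0, 0, 500, 500, 500, 0, 0))
  # missing samples propagate
  p2 <- c(1, 1, NA, 1, 1)
  sp2 <- dilation_speed(pupil_trace((0:4) / 500, p2))
  expect_true(is.na(sp2[3]))
  expect_error(dilation_speed(pupil_trace(0:4 / 500, c(1, NA, NA, NA, 2))),
               "3 valid")
})

test_that("MAD threshold matches hand arithmetic", {
  expect_equal(mad_threshold(c(1, 2, 3, 4, 5), 2.5), 5.5)  # 3 + 2.5 * 1
  expect_equal(mad_threshold(rep(4.2, 10)), 4.2)           # MAD 0
  thr <- mad_threshold(c(1, 1, 1, 1, 10), 2.5)
  expect_equal(thr, 1)
  expect_true(10 > thr)   # the outlier is flagged by this threshold
  expect_error(mad_threshold(rep(NA_real_, 3)), "finite")
})

test_that("two-pass cleaning flags injected artifacts, spares the signal", {
  des <- study_design(n_subjects = 3, n_blocks_est = 1)
  sim <- gen_pupil_est(des, effect_spec(), seed = 11)
  sens_n <- sens_d <- fp_n <- fp_d <- extra <- tot <- 0
  for (id in names(sim$traces)) {
    tr <- sim$traces[[id]]
    cl <- two_pass_clean(tr)
    art <- sim$artifacts[sim$artifacts$trace_id == id, ]
    spikes <- art$sample[art$type == "spike"]
    clean_idx <- setdiff(which(!tr$missing), art$sample)
    sens_n <- sens_n + sum(cl$removed[spikes])
    sens_d <- sens_d + length(spikes)
    fp_n <- fp_n + sum(cl$removed[clean_idx])
    fp_d <- fp_d + length(clean_idx)
    # cleaning never alters samples it does not flag
    keep <- !cl$removed & !tr$missing
    expect_identical(cl$trace$pupil[keep], tr$pupil[keep])
    # idempotence: a second pass removes almost nothing
    cl2 <- two_pass_clean(cl$trace)
    extra <- extra + sum(cl2$removed)
    tot <- tot + nrow(tr)
  }
  expect_gte(sens_n / sens_d, 0.95)
  expect_lte(fp_n / fp_d, 0.01)
  expect_lt(extra / tot, 0.001)
})

test_that("leading gaps stay missing (no extrapolation)", {
  p <- c(rep(NA, 3), rep(5, 7))
  cl <- two_pass_clean(pupil_trace((0:9) / 500, p))
  expect_true(all(cl$trace$missing[1:3]))
  expect_false(any(cl$trace$missing[4:10]))
})

test_that("normalization z-scores, baselines and decimates", {
  rate <- 500
  n_t <- 3501
  time <- seq(-2, 5, by = 1 / rate)
  set.seed(1)
  dat <- matrix(rnorm(4 * n_t, mean = 100, sd = 10), 4)
  ep <- structure(list(data = dat, missing = matrix(FALSE, 4, n_t),
                       time = time, rate = rate,
                       labels = data.frame(subject = c(1, 1, 2, 2),
                                           stimulation = c(0, 1, 0, 1)),
                       rejected = logical(4), reject_reason = character(4)),
                  class = "epoch_set")
  out <- normalize_epochs(ep, clean_config())
  expect_equal(ncol(out$data), 701L)   # 3501 samples decimated by 5
  expect_equal(out$rate, 100)
  # z-units: pooled SD within subject ~ 1
  expect_equal(stats::sd(out$data[1:2, ]), 1, tolerance = 0.1)
  # baseline window mean is exactly zero on the undecimated grid
  # (closed-open [-200, 0) ms)
  out_full <- normalize_epochs(ep, clean_config(out_rate = 500))
  bl <- out_full$time >= -0.2 & out_full$time < 0
  expect_lt(max(abs(rowMeans(out_full$data[, bl]))), 1e-10)
  # constant epochs have zero variance in scope
  epc <- ep
  epc$data[] <- 3
  expect_error(normalize_epochs(epc, clean_config()), "zero variance")
})

test_that("z-scoring then baselining preserves condition differences", {
  # affine order check: between-condition mean differences scale by 1/sd
  rate <- 100
  time <- seq(-0.5, 2, by = 1 / rate)
  n_t <- length(time)
  shape <- exp(-(time - 1)^2)
  dat <- rbind(100 + 5 * shape, 100 + 8 * shape)
  ep <- structure(list(data = dat, missing = matrix(FALSE, 2, n_t),
                       time = time, rate = rate,
                       labels = data.frame(subject = c(1, 1),
                                           stimulation = c(0, 1)),
                       rejected = logical(2), reject_reason = character(2)),
                  class = "epoch_set")
  cfg <- clean_config(out_rate = 100)
  out <- normalize_epochs(ep, cfg)
  d <- out$data[2, ] - out$data[1, ]
  raw_d <- dat[2, ] - dat[1, ]
  # profiles proportional: correlation 1 with positive slope
  expect_equal(stats::cor(d, raw_d), 1, tolerance = 1e-6)
})
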