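# Stimulation-artifact removal: blanking arithmetic, autoregressive gap
# filling, the zero-phase filter chain, and epoching.

sine_signal <- function(f, rate = 1000, dur = 2, markers = numeric(0)) {
  t <- seq(0, dur, by = 1 / rate)
  cont_signal(t, matrix(sin(2 * pi * f * t)), "ch", rate, markers)
}

test_that("pulse blanking removes the documented windows and merges", {
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)
  mk <- 0.5 + (0:14) / 30           # one 30 Hz train
  sig <- cont_signal(t, matrix(rnorm(length(t))), "ch", rate, mk)
  bl <- blank_pulses(sig, artifact_config(blank_ms = 10))
  expect_equal(sum(is.na(bl$data)), 150L)   # 15 x 10 ms, non-overlapping
  # zero markers: unchanged
  sig0 <- cont_signal(t, matrix(rnorm(length(t))), "ch", rate)
  expect_identical(blank_pulses(sig0)$data, sig0$data)
  # two markers 5 ms apart merge into one 15 ms gap
  sig2 <- cont_signal(t, matrix(rnorm(length(t))), "ch", rate,
                      c(1, 1.005))
  bl2 <- blank_pulses(sig2, artifact_config(blank_ms = 10))
  runs <- phasicpupil:::na_runs(is.na(bl2$data[, 1]))
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$end - runs$start + 1L, 15L)
})

test_that("AR gap filling reconstructs band-limited signals", {
  set.seed(2)
  # 10 Hz unit sinusoid, one 10 ms gap: NRMSE < 0.1
  sig <- sine_signal(10)
  truth <- sig$data[1000:1009, 1]
  sig$data[1000:1009, 1] <- NA
  filled <- ar_fill(sig)$data[1000:1009, 1]
  expect_lt(sqrt(mean((filled - truth)^2)) / stats::sd(sine_signal(10)$data),
            0.1)
  # zero-length gap list: identity
  sig2 <- sine_signal(7)
  expect_identical(ar_fill(sig2)$data, sig2$data)
  # constant signal with gap: constant fill
  t <- seq(0, 1, by = 0.001)
  sigc <- cont_signal(t, matrix(rep(4, length(t))), "ch", 1000)
  sigc$data[300:320, 1] <- NA
  expect_equal(ar_fill(sigc)$data[, 1], rep(4, length(t)))
  # non-gap samples untouched
  sig3 <- sine_signal(10)
  before <- sig3$data[, 1]
  sig3$data[500:509, 1] <- NA
  after <- ar_fill(sig3)$data[, 1]
  expect_identical(after[-(500:509)], before[-(500:509)])
})

test_that("blank+fill removes injected artifact energy, leaves the rest", {
  des <- small_design()
  meg1 <- gen_meg(des, effect_spec(artifact_scale = 50), 6, n_trials = 3)
  meg0 <- gen_meg(des, effect_spec(artifact_scale = 0), 6, n_trials = 3)
  id <- names(meg1$signals)[1]
  dirty <- meg1$signals[[id]]
  clean <- meg0$signals[[id]]$data
  e_before <- sum((dirty$data - clean)^2)
  filled <- ar_fill(blank_pulses(dirty))
  e_after <- sum((filled$data - clean)^2)
  expect_lt(e_after / e_before, 0.05)
  # samples outside the blank windows are bit-identical
  blanked <- blank_pulses(dirty)
  ok <- !is.na(blanked$data[, 1])
  expect_identical(filled$data[ok, 1], dirty$data[ok, 1])
})

test_that("the filter chain passes, stops and zeroes as specified", {
  mid <- 1000:3000
  f50 <- filter_chain(sine_signal(50, dur = 4))$data[mid, 1]
  atten_db <- 20 * log10(sqrt(0.5) / stats::sd(f50))
  expect_gte(atten_db, 20)
  f10 <- filter_chain(sine_signal(10, dur = 4))$data[mid, 1]
  expect_equal(stats::sd(f10) / sqrt(0.5), 1, tolerance = 0.05)
  t <- seq(0, 4, by = 1e-3)
  dc <- filter_chain(cont_signal(t, matrix(rep(1, length(t))), "ch",
                                 1000))$data[mid, 1]
  expect_lt(max(abs(dc)), 0.05)
  expect_error(filter_chain(sine_signal(10, rate = 100)), "twice")
  signa <- sine_signal(10)
  signa$data[5, 1] <- NA
  expect_error(filter_chain(signa), "gap-free")
})

test_that("epoching decimates to 250 Hz and retains baselines", {
  rate <- 1000
  t <- seq(0, 30, by = 1 / rate)
  dat <- cbind(a = rep(3.5, length(t)), b = sin(2 * pi * 2 * t))
  sig <- cont_signal(t, dat, c("a", "b"), rate)
  ev <- data.frame(onset_s = c(5, 15), subject = 1)
  ep <- epoch_and_baseline(sig, ev, artifact_config(epoch = c(-2, 5)))
  expect_equal(dim(ep$data)[2], 1751L)  # 7 s at 1000 Hz decimated by 4
  # constant channel: zero after baseline subtraction, stored baseline 3.5
  expect_equal(max(abs(ep$data[, , "a"])), 0)
  expect_equal(unname(ep$baselines[, "a"]), c(3.5, 3.5))
  # no events
  ep0 <- epoch_and_baseline(sig, data.frame(onset_s = numeric(0)),
                            artifact_config())
  expect_equal(dim(ep0$data)[1], 0L)
  # event near the edge flagged
  epe <- epoch_and_baseline(sig, data.frame(onset_s = 0.5),
                            artifact_config())
  expect_true(epe$rejected[1])
})
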