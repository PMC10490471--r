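# Cluster-based permutation testing: worked-example arithmetic, p-value
# conventions, the exhaustive sign-flip oracle, effect sizes, and the
# time-frequency generalization.

test_that("cluster formation matches hand arithmetic", {
  cl <- form_clusters(c(0.1, 3.2, 4.1, 0.3, 5.0), 2)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$mass, c(7.3, 5.0))
  expect_equal(cl$start, c(2L, 5L))
  expect_equal(cl$end, c(3L, 5L))
  # all subthreshold / all suprathreshold
  expect_equal(nrow(form_clusters(c(0.1, 0.5), 2)), 0L)
  all_sup <- form_clusters(c(3, 4, 5), 2)
  expect_equal(nrow(all_sup), 1L)
  expect_equal(all_sup$mass, 12)
  # signed statistics form separate positive and negative clusters
  cls <- form_clusters(c(3, -3, -4, 3), 2)
  expect_equal(cls$sign, c(1L, -1L, 1L))
  expect_equal(cls$mass[2], -7)
  # missing statistics are subthreshold
  clm <- form_clusters(c(3, NA, 3), 2)
  expect_equal(nrow(clm), 2L)
})

test_that("permutation p-values use >= counting with a 1/n_perm floor", {
  null <- seq_len(10000) / 10   # max 1000
  cl <- data.frame(mass = c(2000, stats::median(null), 0.01))
  p <- cluster_p(cl, null)$p
  expect_equal(p[1], 1e-4)          # exceeds all null masses
  expect_equal(p[2], 0.5, tolerance = 0.001)
  expect_equal(p[3], 1)
})

test_that("sampled permutation equals exhaustive sign-flip enumeration", {
  for (n in c(3, 4)) {
    set.seed(n)
    D <- matrix(rnorm(n * 12, 0.8), n)
    thr <- stats::qt(0.975, n - 1)
    expect_warning(
      null <- permutation_null(D, perm_scheme(n_perm = 500, seed = 1), thr),
      "exhaustive")
    expect_length(null, 2^n)
    # independent oracle: direct enumeration with t.test per point
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    oracle <- apply(flips, 1, function(s) {
      tt <- apply(s * D, 2, function(x) stats::t.test(x)$statistic)
      cl <- form_clusters(tt, thr)
      if (nrow(cl)) max(abs(cl$mass)) else 0
    })
    expect_equal(sort(null), sort(unname(oracle)))
    # p values agree with the enumerated null (ties compared with one-ulp
    # tolerance: t.test and the vectorized t differ in the last digit)
    suppressWarnings(
      obs <- paired_cbpt(D, perm_scheme(n_perm = 500, seed = 1)))
    p_oracle <- vapply(obs$clusters$mass, function(m)
      max(mean(oracle >= abs(m) - 1e-8), 1 / length(oracle)), numeric(1))
    expect_equal(obs$clusters$p, p_oracle)
  }
})

test_that("the null distribution is reproducible under a fixed seed", {
  D <- matrix(rnorm(12 * 20), 12)
  n1 <- permutation_null(D, perm_scheme(n_perm = 300, seed = 9))
  n2 <- permutation_null(D, perm_scheme(n_perm = 300, seed = 9))
  expect_identical(n1, n2)
})

test_that("cluster effect sizes follow the paired Cohen's d definitions", {
  # identical conditions: d = 0
  D0 <- matrix(0, 6, 10)
  es0 <- cluster_effect_sizes(D0, 1, 10)
  expect_equal(es0$d_avg, 0)
  expect_equal(es0$d_max, 0)
  # constant shift with between-subject SD, no within-cluster variation:
  # d_avg = d_max = mean/sd exactly
  v <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  D <- matrix(v, 5, 8)
  es <- cluster_effect_sizes(D, 2, 6)
  expect_equal(es$d_avg, mean(v) / stats::sd(v))
  expect_equal(es$d_max, mean(v) / stats::sd(v))
  # time-varying effect: d_max located at the generated peak
  set.seed(4)
  prof <- exp(-(1:40 - 25)^2 / 20)
  D2 <- matrix(rnorm(30 * 40, sd = 0.4), 30) +
    matrix(prof, 30, 40, byrow = TRUE)
  es2 <- cluster_effect_sizes(D2, 1, 40)
  expect_lte(abs(es2$d_max_at - 25), 2)
  expect_error(cluster_effect_sizes(D[1, , drop = FALSE], 1, 2), "2 subjects")
})

test_that("paired CBPT localizes an injected effect and reports d", {
  set.seed(11)
  D <- matrix(rnorm(20 * 60), 20)
  D[, 20:40] <- D[, 20:40] + 0.9
  res <- paired_cbpt(D, perm_scheme(n_perm = 500, seed = 2),
                     axis = seq(0, 5.9, by = 0.1))
  sig <- res$clusters[res$clusters$p <= 0.05, ]
  expect_gte(nrow(sig), 1L)
  top <- sig[which.max(abs(sig$mass)), ]
  expect_lte(top$start, 25)
  expect_gte(top$end, 35)
  expect_gt(top$d_avg, 0)
  expect_equal(top$axis_start, res$axis[top$start])
})

test_that("per-point mixed-model statistics track a localized effect", {
  set.seed(6)
  ns <- 12
  np <- 15
  long <- expand.grid(subject = seq_len(ns), cond = 0:1,
                      point = seq_len(np))
  eff <- ifelse(long$point %in% 6:10, 0.9, 0)
  long$y <- eff * long$cond + rnorm(ns)[long$subject] +
    rnorm(nrow(long), 0, 0.5)
  # identical outcome at all points -> identical statistic
  flat <- long
  flat$y <- rep(long$y[long$point == 1], np)
  st_flat <- pointwise_lmm(flat, y ~ cond + (1 | subject), "cond")
  expect_equal(stats::sd(st_flat$stat), 0, tolerance = 1e-6)
  st <- pointwise_lmm(long, y ~ cond + (1 | subject), "cond")
  expect_gt(mean(st$stat[6:10]), 2 * mean(st$stat[-(6:10)]))
  r <- lmm_cbpt(long, y ~ cond + (1 | subject), "cond",
                perm_scheme(n_perm = 100, seed = 1))
  sig <- r$clusters[r$clusters$p <= 0.05, ]
  expect_gte(nrow(sig), 1L)
  expect_true(any(sig$start <= 10 & sig$end >= 6))
  expect_gt(sig$beta_avg[which.max(abs(sig$mass))], 0)
})

test_that("TFR clustering reduces to 1-D and detects an injected region", {
  # degenerate adjacency: single sensor, single frequency
  set.seed(7)
  D <- matrix(rnorm(10 * 30, 0.3), 10)
  arr <- array(D, c(10, 1, 1, 30))
  r1 <- paired_cbpt(D, perm_scheme(n_perm = 200, seed = 3))
  r2 <- tfr_cbpt(arr, perm_scheme(n_perm = 200, seed = 3))
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass))
  expect_equal(sort(r1$clusters$p), sort(r2$clusters$p))
  # injected negative effect at sensors 1-2, freqs 3-5, times 10-20
  set.seed(8)
  arr2 <- array(rnorm(14 * 3 * 6 * 25, 0, 1), c(14, 3, 6, 25))
  arr2[, 1:2, 3:5, 10:20] <- arr2[, 1:2, 3:5, 10:20] - 1.2
  adj <- matrix(TRUE, 3, 3)
  r3 <- tfr_cbpt(arr2, perm_scheme(n_perm = 300, seed = 4),
                 sensor_adj = adj,
                 freqs = seq(2, 4.5, 0.5), times = seq(0.6, 5, length.out = 25))
  sig <- r3$clusters[r3$clusters$p <= 0.05 & r3$clusters$sign < 0, ]
  expect_gte(nrow(sig), 1L)
  top <- sig[which.max(abs(sig$mass)), ]
  expect_lte(top$freq_min, 3)
  expect_gte(top$freq_max, 3.5)
  expect_lt(top$d_avg, 0)
  # time-window restriction drops early cells
  r4 <- tfr_cbpt(arr2, perm_scheme(n_perm = 100, seed = 4),
                 times = seq(0.6, 5, length.out = 25), window = c(2, 5))
  expect_true(all(r4$times >= 2))
})

test_that("detection rate grows monotonically with effect size", {
  rates <- vapply(c(0, 0.5, 1), function(delta) {
    hits <- vapply(1:8, function(s) {
      set.seed(100 + s)
      D <- matrix(rnorm(15 * 40), 15)
      D[, 10:25] <- D[, 10:25] + delta
      r <- paired_cbpt(D, perm_scheme(n_perm = 200, seed = s))
      nrow(r$clusters) > 0 && any(r$clusters$p <= 0.05)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
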