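# Cluster-based permutation testing over 1-D series (time or frequency) and
# time-frequency maps with sensor adjacency: per-point statistics (paired t
# or mixed-model likelihood-ratio chi-square), contiguous suprathreshold
# clustering, max-cluster permutation null, and paired Cohen's d cluster
# effect sizes.

#' Permutation scheme
#'
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draw.
#' @param threshold_alpha per-point cluster-forming alpha on the
#'   statistic's asymptotic null.
#' @param statistic per-point statistic name (`"t"` paired t,
#'   `"lmm_lrt"` mixed-model likelihood-ratio chi-square).
#' @return a `perm_scheme` list.
#' @export
perm_scheme <- function(n_perm = 10000, seed = NULL,
                        threshold_alpha = 0.05,
                        statistic = c("t", "lmm_lrt")) {
  if (n_perm < 100) stop("`n_perm` must be at least 100")
  if (threshold_alpha <= 0 || threshold_alpha >= 0.5)
    stop("`threshold_alpha` must lie in (0, 0.5)")
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 threshold_alpha = threshold_alpha,
                 statistic = match.arg(statistic)),
            class = "perm_scheme")
}

#' Per-point paired t statistics
#'
#' @param D numeric matrix of within-subject condition differences,
#'   subjects x points.
#' @return list with `stat` (t per point) and `df`.
#' @export
pointwise_t <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 subjects")
  m <- colMeans(D)
  s <- sqrt(pmax((colSums(D^2) - n * m^2) / (n - 1), 0))
  st <- m / (s / sqrt(n))
  st[!is.finite(st)] <- NA
  list(stat = st, df = n - 1L)
}

#' Per-point mixed-model likelihood-ratio statistics
#'
#' Fits the mixed model at each point and tests `predictor` by an ML
#' likelihood-ratio chi-square (removing the predictor and any interaction
#' containing it).  Points whose fit fails carry a missing statistic
#' (treated as subthreshold downstream); more than `max_failures` failed
#' points abort with a diagnostic.
#'
#' @param data long-format data with a point-index column.
#' @param formula mixed-model formula for the outcome.
#' @param predictor name of the tested fixed-effect term.
#' @param point_col name of the point-index column.
#' @param family model family.
#' @param max_failures tolerated fraction of non-converged points.
#' @return list with `stat` (chi-square per point), `df`, `beta`
#'   (per-point predictor estimate), `points` (sorted unique point values).
#' @export
pointwise_lmm <- function(data, formula, predictor, point_col = "point",
                          family = "gaussian", max_failures = 0.2) {
  pts <- sort(unique(data[[point_col]]))
  stat <- rep(NA_real_, length(pts))
  beta <- rep(NA_real_, length(pts))
  df_pred <- NA_integer_
  for (i in seq_along(pts)) {
    d <- data[data[[point_col]] == pts[i], , drop = FALSE]
    fit <- fit_mixed(formula, d, family = family, reml = FALSE)
    if (!fit$converged) next
    tab <- tryCatch(lrt_table(fit), error = function(e) NULL)
    if (is.null(tab) || !predictor %in% tab$term) next
    row <- tab[tab$term == predictor, ]
    stat[i] <- row$chisq
    df_pred <- row$df
    bn <- grep(paste0("^", predictor), names(fit$beta), value = TRUE)
    if (length(bn)) beta[i] <- fit$beta[[bn[1]]]
  }
  fail <- mean(is.na(stat))
  if (fail > max_failures)
    stop(sprintf("pointwise_lmm(): %.0f%% of points failed to converge",
                 100 * fail))
  list(stat = stat, df = df_pred, beta = beta, points = pts)
}

#' Form contiguous suprathreshold clusters in a 1-D statistic series
#'
#' Adjacent points exceeding the threshold are clustered; for signed
#' statistics, positive and negative excursions form separate clusters.
#' Missing statistics are subthreshold.  The cluster mass is the sum of
#' the statistics in the cluster.
#'
#' @param stats numeric statistic series.
#' @param threshold cluster-forming threshold on the statistic's scale.
#' @param signed treat the statistic as signed (default: TRUE when any
#'   value is negative).
#' @return data frame with `start`, `end` (indices), `mass`, `sign`.
#' @export
form_clusters <- function(stats, threshold, signed = any(stats < 0,
                                                         na.rm = TRUE)) {
  key <- integer(length(stats))
  key[which(stats > threshold)] <- 1L
  if (signed) key[which(stats < -threshold)] <- -1L
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values != 0L)
  if (!length(sel))
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0), sign = integer(0)))
  cs <- c(0, cumsum(ifelse(is.na(stats), 0, stats)))
  data.frame(start = starts[sel], end = ends[sel],
             mass = cs[ends[sel] + 1L] - cs[starts[sel]],
             sign = r$values[sel])
}

# Largest absolute cluster mass of a statistic series (0 if none).
max_cluster_mass <- function(stats, threshold, signed = TRUE) {
  cl <- form_clusters(stats, threshold, signed = signed)
  if (!nrow(cl)) 0 else max(abs(cl$mass))
}

# Sign-flip matrix for a paired design: exhaustive enumeration when the
# full set is no larger than n_perm (with a warning), random otherwise.
sign_flips <- function(n, n_perm) {
  if (n <= 25 && 2^n <= n_perm) {
    warning(sprintf(paste("only %d distinct sign flips for %d subjects;",
                          "using exhaustive enumeration"), 2^n, n),
            call. = FALSE)
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
  }
}

#' Max-cluster permutation null for a paired 1-D design
#'
#' Within-subject condition labels are flipped (sign flips of the
#' difference matrix); each permutation contributes the largest absolute
#' cluster mass of its t series (0 when no cluster forms).  For designs
#' with no more distinct flips than `n_perm`, the full set is enumerated.
#'
#' @param D subjects x points difference matrix.
#' @param scheme a [perm_scheme()].
#' @param threshold cluster-forming threshold (default from
#'   `scheme$threshold_alpha` and the t null).
#' @return numeric vector of null max-cluster masses (one per permutation).
#' @export
permutation_null <- function(D, scheme = perm_scheme(),
                             threshold = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(threshold))
    threshold <- stats::qt(1 - scheme$threshold_alpha / 2, n - 1)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  S <- sign_flips(n, scheme$n_perm)
  ss <- colSums(D^2)
  M <- (S %*% D) / n
  V <- pmax(sweep(-n * M^2, 2, ss, "+") / (n - 1), 0)
  Tm <- M / sqrt(V / n)
  Tm[!is.finite(Tm)] <- NA
  apply(Tm, 1, max_cluster_mass, threshold = threshold)
}

#' Permutation p-values for observed clusters
#'
#' `p = max(count(null >= |mass|) / n_perm, 1 / n_perm)`; ties count
#' against the observed cluster (conservative), and the floor matches the
#' smallest attainable p at the chosen permutation count.
#'
#' @param clusters cluster data frame from [form_clusters()].
#' @param null null max-mass distribution from [permutation_null()].
#' @return the cluster data frame with a `p` column.
#' @export
cluster_p <- function(clusters, null) {
  if (!length(null)) stop("empty null distribution")
  n_perm <- length(null)
  clusters$p <- vapply(clusters$mass, function(m) {
    # ties count against the observed cluster; the comparison carries a
    # relative tolerance so that floating-point ties (e.g. the identity
    # permutation reproducing the observed mass through a different
    # arithmetic path) are counted as ties
    tol <- 1e-8 * max(abs(m), 1)
    max(sum(null >= abs(m) - tol) / n_perm, 1 / n_perm)
  }, numeric(1))
  clusters
}

#' Paired Cohen's d effect sizes for a cluster
#'
#' `d_avg` is the paired Cohen's d of the per-subject means across the
#' cluster's points; `d_max` is the per-point paired d largest in
#' magnitude, with its point index.  No ordering between the two is
#' implied.
#'
#' @param D subjects x points difference matrix.
#' @param start,end cluster extent (point indices, inclusive).
#' @return list with `d_avg`, `d_max`, `d_max_at`.
#' @export
cluster_effect_sizes <- function(D, start, end) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 subjects")
  idx <- start:end
  m_i <- rowMeans(D[, idx, drop = FALSE])
  d_avg <- if (stats::sd(m_i) == 0) 0 else mean(m_i) / stats::sd(m_i)
  d_pt <- vapply(idx, function(j) {
    s <- stats::sd(D[, j])
    if (s == 0) 0 else mean(D[, j]) / s
  }, numeric(1))
  k <- which.max(abs(d_pt))
  list(d_avg = d_avg, d_max = d_pt[k], d_max_at = idx[k])
}

#' Cluster-based permutation test for a paired 1-D design
#'
#' Per-point paired t statistics are thresholded at the two-sided
#' `threshold_alpha` t quantile, contiguous excursions are clustered, and
#' cluster masses are compared against the sign-flip max-cluster null.
#'
#' @param D subjects x points matrix of condition differences
#'   (active minus reference).
#' @param scheme a [perm_scheme()].
#' @param axis optional axis values (time s or frequency Hz) per point.
#' @return a `cbpt_result`: list with `clusters` (start/end indices, axis
#'   extent, mass, sign, p, d_avg, d_max, d_max_at), `stat`, `threshold`,
#'   `null`, `axis`, `n`, `n_perm`.
#' @export
paired_cbpt <- function(D, scheme = perm_scheme(), axis = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  tt <- pointwise_t(D)
  threshold <- stats::qt(1 - scheme$threshold_alpha / 2, tt$df)
  cl <- form_clusters(tt$stat, threshold, signed = TRUE)
  null <- permutation_null(D, scheme, threshold)
  cl <- cluster_p(cl, null)
  if (nrow(cl)) {
    es <- lapply(seq_len(nrow(cl)), function(i)
      cluster_effect_sizes(D, cl$start[i], cl$end[i]))
    cl$d_avg <- vapply(es, `[[`, numeric(1), "d_avg")
    cl$d_max <- vapply(es, `[[`, numeric(1), "d_max")
    cl$d_max_at <- vapply(es, `[[`, numeric(1), "d_max_at")
  } else {
    cl$d_avg <- cl$d_max <- cl$d_max_at <- numeric(0)
  }
  if (!is.null(axis) && nrow(cl)) {
    cl$axis_start <- axis[cl$start]
    cl$axis_end <- axis[cl$end]
  }
  structure(list(clusters = cl, stat = tt$stat, threshold = threshold,
                 null = null, axis = axis, n = n,
                 n_perm = length(null)),
            class = "cbpt_result")
}

#' Cluster-based permutation test with per-point mixed models
#'
#' Per-point likelihood-ratio chi-square statistics for `predictor` are
#' thresholded at the `threshold_alpha` chi-square quantile and clustered;
#' the null shuffles the predictor's values within each exchange unit
#' (subject), keeping covariates fixed, and collects the largest cluster
#' mass per permutation.
#'
#' @param data long-format data (one row per unit x condition x point).
#' @param formula mixed-model formula.
#' @param predictor tested fixed-effect term.
#' @param scheme a [perm_scheme()].
#' @param point_col point-index column name.
#' @param unit exchange-unit column name (default `"subject"`).
#' @param family model family.
#' @return a `cbpt_result` (clusters additionally carry `beta_avg`, the
#'   mean per-point predictor estimate inside the cluster).
#' @export
lmm_cbpt <- function(data, formula, predictor, scheme = perm_scheme(),
                     point_col = "point", unit = "subject",
                     family = "gaussian") {
  obs <- pointwise_lmm(data, formula, predictor, point_col, family)
  threshold <- stats::qchisq(1 - scheme$threshold_alpha, obs$df)
  cl <- form_clusters(obs$stat, threshold, signed = FALSE)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  split_idx <- split(seq_len(nrow(data)), data[[unit]])
  null <- numeric(scheme$n_perm)
  for (b in seq_len(scheme$n_perm)) {
    d2 <- data
    for (ix in split_idx)
      d2[[predictor]][ix] <- d2[[predictor]][ix][sample.int(length(ix))]
    st <- tryCatch(
      pointwise_lmm(d2, formula, predictor, point_col, family,
                    max_failures = 1)$stat,
      error = function(e) rep(NA_real_, length(obs$stat)))
    null[b] <- max_cluster_mass(st, threshold, signed = FALSE)
  }
  cl <- cluster_p(cl, null)
  cl$beta_avg <- if (nrow(cl))
    vapply(seq_len(nrow(cl)), function(i)
      mean(obs$beta[cl$start[i]:cl$end[i]], na.rm = TRUE), numeric(1))
  else numeric(0)
  structure(list(clusters = cl, stat = obs$stat, threshold = threshold,
                 null = null, axis = obs$points, n = length(split_idx),
                 n_perm = scheme$n_perm, beta = obs$beta),
            class = "cbpt_result")
}

# ---- time-frequency (x sensor) clustering ---------------------------------

# Connected components over suprathreshold cells of an S x F x T lattice:
# 8-neighbourhood in the frequency-time plane within a sensor, plus declared
# sensor neighbours at the same (f, t) cell.
clusters_nd <- function(supra_idx, S, F_n, adj) {
  if (!length(supra_idx)) return(list())
  SF <- S * F_n
  supra <- new.env(hash = TRUE, size = length(supra_idx))
  for (c0 in supra_idx) assign(as.character(c0), TRUE, envir = supra)
  seen <- new.env(hash = TRUE, size = length(supra_idx))
  out <- list()
  for (c0 in supra_idx) {
    if (!is.null(seen[[as.character(c0)]])) next
    members <- integer(0)
    queue <- c0
    seen[[as.character(c0)]] <- TRUE
    while (length(queue)) {
      cc <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, cc)
      s <- (cc - 1L) %% S + 1L
      f <- ((cc - 1L) %/% S) %% F_n + 1L
      t <- (cc - 1L) %/% SF + 1L
      nbr <- integer(0)
      for (df in -1:1) for (dt in -1:1) {
        if (df == 0L && dt == 0L) next
        f2 <- f + df; t2 <- t + dt
        if (f2 < 1L || f2 > F_n || t2 < 1L) next
        nbr <- c(nbr, s + (f2 - 1L) * S + (t2 - 1L) * SF)
      }
      if (S > 1L) {
        sn <- which(adj[s, ])
        sn <- sn[sn != s]
        nbr <- c(nbr, sn + (f - 1L) * S + (t - 1L) * SF)
      }
      for (nb in nbr) {
        k <- as.character(nb)
        if (!is.null(supra[[k]]) && is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    out[[length(out) + 1L]] <- sort(members)
  }
  out
}

#' Cluster-based permutation test on time-frequency representations
#'
#' Paired (dependent-sample) t statistics per sensor x frequency x time
#' cell; suprathreshold cells are clustered using 8-neighbourhood adjacency
#' in the frequency-time plane plus declared sensor neighbours, and cluster
#' masses are compared against a within-subject condition-flip max-cluster
#' null.  The analysis can be restricted to a time window (e.g. after
#' stimulation offset, to avoid comparing interpolated with
#' non-interpolated periods).
#'
#' @param D array of per-subject condition differences, subjects x sensors
#'   x frequencies x times.
#' @param scheme a [perm_scheme()].
#' @param sensor_adj logical sensors x sensors adjacency matrix (default:
#'   all sensors adjacent).
#' @param times,freqs axis values for the last two dimensions.
#' @param window optional time window restriction (s).
#' @return a `cbpt_result` whose clusters carry cell counts and
#'   sensor/frequency/time extents; cluster cell indices are attached as
#'   the `cells` element.
#' @export
tfr_cbpt <- function(D, scheme = perm_scheme(), sensor_adj = NULL,
                     times = NULL, freqs = NULL, window = NULL) {
  stopifnot(length(dim(D)) == 4L)
  if (!is.null(window)) {
    if (is.null(times)) stop("`window` requires `times`")
    keep <- which(times >= window[1] & times <= window[2])
    if (!length(keep)) stop("analysis window outside the TFR support")
    D <- D[, , , keep, drop = FALSE]
    times <- times[keep]
  }
  n <- dim(D)[1]; S <- dim(D)[2]; F_n <- dim(D)[3]; T_n <- dim(D)[4]
  if (is.null(sensor_adj)) sensor_adj <- matrix(TRUE, S, S)
  Dm <- matrix(D, n, S * F_n * T_n)
  tt <- pointwise_t(Dm)
  threshold <- stats::qt(1 - scheme$threshold_alpha / 2, tt$df)
  stat <- tt$stat
  observed <- list()
  for (sgn in c(1, -1)) {
    supra <- which(!is.na(stat) & sgn * stat > threshold)
    for (cells in clusters_nd(supra, S, F_n, sensor_adj))
      observed[[length(observed) + 1L]] <-
        list(cells = cells, mass = sum(stat[cells]), sign = sgn)
  }
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  Sf <- sign_flips(n, scheme$n_perm)
  ss <- colSums(Dm^2)
  M <- (Sf %*% Dm) / n
  V <- pmax(sweep(-n * M^2, 2, ss, "+") / (n - 1), 0)
  Tm <- M / sqrt(V / n)
  Tm[!is.finite(Tm)] <- NA
  null <- apply(Tm, 1, function(st) {
    best <- 0
    for (sgn in c(1, -1)) {
      supra <- which(!is.na(st) & sgn * st > threshold)
      for (cells in clusters_nd(supra, S, F_n, sensor_adj))
        best <- max(best, abs(sum(st[cells])))
    }
    best
  })
  n_perm <- length(null)
  cl <- do.call(rbind, lapply(observed, function(o) {
    m_i <- rowMeans(Dm[, o$cells, drop = FALSE])
    d_avg <- if (stats::sd(m_i) == 0) 0 else mean(m_i) / stats::sd(m_i)
    d_pt <- vapply(o$cells, function(j) {
      s <- stats::sd(Dm[, j])
      if (s == 0) 0 else mean(Dm[, j]) / s
    }, numeric(1))
    k <- which.max(abs(d_pt))
    cell <- o$cells
    sens <- (cell - 1L) %% S + 1L
    fr <- ((cell - 1L) %/% S) %% F_n + 1L
    ti <- (cell - 1L) %/% (S * F_n) + 1L
    tol <- 1e-8 * max(abs(o$mass), 1)
    data.frame(mass = o$mass, sign = o$sign, n_cells = length(cell),
               p = max(sum(null >= abs(o$mass) - tol) / n_perm, 1 / n_perm),
               d_avg = d_avg, d_max = d_pt[k],
               sensor_min = min(sens), sensor_max = max(sens),
               freq_min = if (is.null(freqs)) min(fr) else freqs[min(fr)],
               freq_max = if (is.null(freqs)) max(fr) else freqs[max(fr)],
               time_min = if (is.null(times)) min(ti) else times[min(ti)],
               time_max = if (is.null(times)) max(ti) else times[max(ti)])
  }))
  if (is.null(cl))
    cl <- data.frame(mass = numeric(0), sign = integer(0),
                     n_cells = integer(0), p = numeric(0))
  structure(list(clusters = cl, cells = lapply(observed, `[[`, "cells"),
                 stat = array(stat, c(S, F_n, T_n)), threshold = threshold,
                 null = null, times = times, freqs = freqs, n = n,
                 n_perm = n_perm),
            class = "cbpt_result")
}
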