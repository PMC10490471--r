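# Cross-task analysis of stimulation-specific deltas: per-subject
# active-minus-sham differences of series, cluster-averaged scalars, and
# per-point prediction of one task's delta profile from the other task's
# cluster averages under CBPT.

#' Per-subject stimulation deltas of a series
#'
#' Pointwise active-minus-reference subtraction per subject; subjects
#' missing either condition are excluded with a message.  No averaging
#' across subjects is performed.
#'
#' @param values rows x points matrix of per-subject condition series.
#' @param subjects subject id per row.
#' @param condition condition label per row.
#' @param active,reference condition labels to subtract
#'   (active minus reference).
#' @param axis optional axis values per point (time s or frequency Hz).
#' @return a `delta_series`: list with `delta` (subjects x points),
#'   `subjects`, `axis`.
#' @export
compute_deltas <- function(values, subjects, condition,
                           active = 1, reference = 0, axis = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(subjects),
            length(condition) == length(subjects))
  subj <- unique(subjects)
  keep <- vapply(subj, function(s)
    any(subjects == s & condition == active) &&
      any(subjects == s & condition == reference), logical(1))
  if (any(!keep))
    message("compute_deltas(): dropping subjects missing a condition: ",
            paste(subj[!keep], collapse = ", "))
  subj <- subj[keep]
  delta <- t(vapply(subj, function(s) {
    a <- colMeans(values[subjects == s & condition == active, ,
                         drop = FALSE])
    r <- colMeans(values[subjects == s & condition == reference, ,
                         drop = FALSE])
    a - r
  }, numeric(ncol(values))))
  structure(list(delta = delta, subjects = subj, axis = axis),
            class = "delta_series")
}

#' Cluster-averaged delta scalar per subject
#'
#' Mean of the delta series over the points of a significant cluster,
#' yielding one scalar per subject (the cluster-indexed quantities used as
#' cross-task predictors).
#'
#' @param delta a `delta_series`.
#' @param cluster one row of a `cbpt_result` cluster table (or a list with
#'   `start` and `end` point indices).
#' @return named numeric vector, one value per subject.
#' @export
cluster_average_delta <- function(delta, cluster) {
  stopifnot(inherits(delta, "delta_series"))
  idx <- cluster$start:cluster$end
  if (!length(idx) || any(idx < 1 | idx > ncol(delta$delta)))
    stop("cluster extent outside the delta axis")
  out <- rowMeans(delta$delta[, idx, drop = FALSE])
  names(out) <- delta$subjects
  out
}

#' Predict a delta profile from cross-task cluster averages
#'
#' At each point of the outcome delta series, the outcome is regressed on
#' the per-subject predictor scalars; per-point t statistics for each
#' predictor are thresholded and clustered, and cluster masses are
#' compared against a null in which the predictor rows are jointly
#' permuted across subjects.  With one observation per subject per point a
#' subject random intercept is not identifiable, so the per-point model is
#' an ordinary linear regression (see the methods vignette).
#'
#' @param outcome a `delta_series`.
#' @param predictors data frame (or named list) of per-subject scalars;
#'   rows must align with `outcome$subjects`.
#' @param scheme a [perm_scheme()].
#' @return named list (one per predictor) of `cbpt_result` objects whose
#'   clusters carry `beta_avg`, the mean per-point slope inside the
#'   cluster.
#' @export
predict_across <- function(outcome, predictors, scheme = perm_scheme()) {
  stopifnot(inherits(outcome, "delta_series"))
  X0 <- as.data.frame(predictors)
  n <- nrow(outcome$delta)
  if (nrow(X0) != n) stop("predictors must align with the outcome subjects")
  if (n < 5) stop("predict_across() needs at least 5 subjects")
  Y <- outcome$delta
  fit_series <- function(X) {
    Xm <- cbind(1, as.matrix(X))
    qr_x <- qr(Xm)
    cf <- qr.coef(qr_x, Y)
    res <- Y - Xm %*% cf
    dfr <- n - ncol(Xm)
    sigma2 <- colSums(res^2) / dfr
    xtxi <- chol2inv(qr.R(qr_x))
    list(beta = cf[-1, , drop = FALSE],
         t = cf[-1, , drop = FALSE] /
           sqrt(outer(diag(xtxi)[-1], sigma2)),
         df = dfr)
  }
  obs <- fit_series(X0)
  threshold <- stats::qt(1 - scheme$threshold_alpha / 2, obs$df)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  perms <- replicate(scheme$n_perm, sample.int(n))
  out <- list()
  for (k in seq_len(ncol(X0))) {
    cl <- form_clusters(obs$t[k, ], threshold, signed = TRUE)
    null <- numeric(scheme$n_perm)
    for (b in seq_len(scheme$n_perm)) {
      Xp <- X0[perms[, b], , drop = FALSE]
      null[b] <- max_cluster_mass(fit_series(Xp)$t[k, ], threshold)
    }
    cl <- cluster_p(cl, null)
    cl$beta_avg <- if (nrow(cl))
      vapply(seq_len(nrow(cl)), function(i)
        mean(obs$beta[k, cl$start[i]:cl$end[i]]), numeric(1))
    else numeric(0)
    if (!is.null(outcome$axis) && nrow(cl)) {
      cl$axis_start <- outcome$axis[cl$start]
      cl$axis_end <- outcome$axis[cl$end]
    }
    out[[names(X0)[k]]] <- structure(
      list(clusters = cl, stat = obs$t[k, ], threshold = threshold,
           null = null, axis = outcome$axis, n = n,
           n_perm = scheme$n_perm, beta = obs$beta[k, ]),
      class = "cbpt_result")
  }
  out
}
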