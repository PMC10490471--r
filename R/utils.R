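# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with shrinking edge windows
#'
#' NA-aware: missing samples are ignored in each window's mean; a window with
#' no finite samples yields NA.  The window is centered, so the smoother
#' introduces no phase shift; at the series edges the window shrinks rather
#' than extrapolating.
#'
#' @param x numeric vector, possibly with NAs.
#' @param k window length in samples (coerced to an odd count >= 1).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  half <- k %/% 2L
  good <- is.finite(x)
  x0 <- ifelse(good, x, 0)
  cs <- c(0, cumsum(x0))
  cn <- c(0, cumsum(good))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Linear interpolation of interior NA runs only; leading/trailing NAs are
# preserved (no extrapolation).
interp_interior <- function(x) {
  good <- which(is.finite(x))
  if (length(good) < 2L) return(x)
  out <- x
  idx <- seq_along(x)
  filled <- stats::approx(good, x[good], xout = idx, method = "linear",
                          rule = 1)$y
  take <- !is.finite(x) & is.finite(filled)
  out[take] <- filled[take]
  out
}

# Runs of NA (or TRUE in a logical mask): returns data.frame(start, end).
na_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

# Deterministic per-stage seed derivation from a single top-level seed.
# Keeps derived seeds within 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(behavior = 101L, pupil_est = 211L, plrt = 307L, meg = 401L,
               cbpt = 503L, pipeline = 601L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}
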