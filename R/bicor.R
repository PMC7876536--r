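# Biweight midcorrelation internals.
#
# Each feature vector x is represented as a weighted, median-centered vector
#   a_i = w_i * (x_i - med(x)),  w_i = (1 - u_i^2)^2 * 1[|u_i| < 1],
#   u_i = (x_i - med(x)) / (9 * MAD(x))   (MAD unscaled, constant = 1)
# normalized to unit Euclidean norm, so that bicor(x, y) is the plain dot
# product of the two representations. The side-cap rule rescales u separately
# on each side of the median so that at most max_p_outliers of the
# observations per side get zero weight. Features with MAD = 0 fall back to a
# Pearson representation (mean-centered, unit weights) for all their pairs.

bicor_rep <- function(x, max_p_outliers = 0.05) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) {
    a <- x - mean(x)
    nrm <- sqrt(sum(a^2))
    return(list(a = if (nrm > 0) a / nrm else a, degenerate = nrm == 0,
                fallback = TRUE))
  }
  u <- (x - med) / (9 * madx)
  if (max_p_outliers < 1) {
    qs <- stats::quantile(x, probs = c(max_p_outliers, 1 - max_p_outliers),
                          names = FALSE, type = 7)
    ulo <- (qs[1] - med) / (9 * madx)
    uhi <- (qs[2] - med) / (9 * madx)
    if (ulo < -1) u[u < 0] <- u[u < 0] / abs(ulo)
    if (uhi > 1) u[u > 0] <- u[u > 0] / uhi
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- w * (x - med)
  nrm <- sqrt(sum(a^2))
  list(a = if (nrm > 0) a / nrm else a, degenerate = nrm == 0, fallback = FALSE)
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation that downweights observations far from the median; the
#' workhorse similarity of the co-abundance networks. Observations with robust
#' z-score `|u| >= 1` get zero weight, and `max_p_outliers` caps the fraction
#' of zero-weight observations on each side of the median by rescaling `u`.
#' A vector whose median absolute deviation is zero falls back to Pearson
#' (with a message); if it is constant outright the correlation is defined as
#' 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param max_p_outliers per-side cap on the zero-weight fraction
#'   (default 0.05).
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y, max_p_outliers = 0.05) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("bicor needs at least 3 observations")
  rx <- bicor_rep(x, max_p_outliers)
  ry <- bicor_rep(y, max_p_outliers)
  if (rx$degenerate || ry$degenerate) {
    warning("constant vector in bicor; correlation defined as 0")
    return(0)
  }
  min(1, max(-1, sum(rx$a * ry$a)))
}

#' All-pairs correlation matrix of an omics matrix
#'
#' Computes the biweight midcorrelation between every pair of feature rows
#' (vectorized through the per-feature representation, so it agrees with
#' looped scalar [bicor()] calls). Features with zero median absolute
#' deviation fall back to Pearson for all their pairs, with a message naming
#' how many fell back; constant features get correlation 0 to every other
#' feature.
#'
#' @param matrix an `omics_matrix` with >= 3 samples.
#' @param params a [network_params()] object (uses `max_p_outliers`).
#' @return list of class `correlation_matrix`: `values` (symmetric, unit
#'   diagonal, entries in [-1, 1]), `method = "bicor"`.
#' @export
correlation_matrix <- function(matrix, params = network_params()) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- matrix$values
  if (ncol(x) < 3L) stop("correlation needs at least 3 samples")
  reps <- apply(x, 1L, bicor_rep, max_p_outliers = params$max_p_outliers,
                simplify = FALSE)
  a <- t(vapply(reps, `[[`, numeric(ncol(x)), "a"))
  degen <- vapply(reps, `[[`, logical(1), "degenerate")
  fellback <- vapply(reps, `[[`, logical(1), "fallback")
  if (any(fellback & !degen))
    message(sum(fellback & !degen), " feature(s) with zero MAD fell back to Pearson")
  if (any(degen))
    warning(sum(degen), " constant feature(s); their correlations set to 0")
  cm <- tcrossprod(a)
  cm[cm > 1] <- 1
  cm[cm < -1] <- -1
  diag(cm) <- 1
  cm[degen, ] <- 0
  cm[, degen] <- 0
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(x), rownames(x))
  structure(list(values = cm, method = "bicor"), class = "correlation_matrix")
}
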