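#' Estimate the number of large latent effects by permutation
#'
#' Permutation test on the eigenvalue spectrum of the feature-standardized
#' data (Buja-Eyuboglu style): the observed eigenvalue fractions are compared,
#' from the top down, with the `(1 - alpha)` quantile of the fractions
#' obtained after independently permuting the values within each feature row
#' (which destroys cross-feature correlation while preserving marginals). The
#' estimate is the number of leading components that exceed their null
#' quantile before the first failure.
#'
#' @param matrix an `omics_matrix` with >= 5 samples and no constant features.
#' @param B number of permutations (default 100; below 20 a warning).
#' @param alpha per-component test level (default 0.05).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @return list of class `latent_estimate`: `n_sv`, `spectrum` (observed
#'   eigenvalue fractions), `null_quantiles`, `B`, `alpha`, `seed`.
#' @export
estimate_num_sv <- function(matrix, B = 100L, alpha = 0.05, seed) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (missing(seed)) stop("'seed' is mandatory")
  if (B < 20) warning("B < 20 permutations gives a coarse null")
  x <- matrix$values
  if (ncol(x) < 5L) stop("need at least 5 samples")
  if (any(!is.finite(x))) stop("non-finite values")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) stop("constant feature(s); filter before estimating latent effects")
  xs <- t(scale(t(x)))
  spec_frac <- function(m) {
    d2 <- svd(m, nu = 0, nv = 0)$d^2
    d2 / sum(d2)
  }
  obs <- spec_frac(xs)
  m <- length(obs)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      perm <- t(apply(xs, 1L, sample))
      spec_frac(perm)[seq_len(m)]
    }, numeric(m))
  })
  qnull <- apply(null, 1L, stats::quantile, probs = 1 - alpha, names = FALSE)
  exceeds <- obs > qnull
  n_sv <- if (!exceeds[1]) 0L else {
    firstfail <- which(!exceeds)
    if (length(firstfail)) firstfail[1] - 1L else m
  }
  max_sv <- min(nrow(x), ncol(x)) - 1L
  n_sv <- min(n_sv, max_sv)
  structure(list(n_sv = as.integer(n_sv), spectrum = obs, null_quantiles = qnull,
                 B = as.integer(B), alpha = alpha, seed = seed),
            class = "latent_estimate")
}

#' Regress leading principal components out of every feature
#'
#' Removes `n` large latent effects: features are centered, the top-`n`
#' principal-component sample scores of the row-standardized matrix are
#' computed, and each feature is replaced by its least-squares residual after
#' regression on those scores (with intercept). With `n = 0` the output is
#' simply the centered input. The residuals are exactly orthogonal to every
#' removed score vector.
#'
#' @param matrix an `omics_matrix`.
#' @param n number of components to remove, `0 <= n <= min(dim) - 1`.
#' @return an `omics_matrix` at stage `corrected`.
#' @export
remove_latent_pcs <- function(matrix, n) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- matrix$values
  maxn <- min(dim(x)) - 1L
  if (n < 0 || n > maxn) stop("'n' must be between 0 and ", maxn)
  xc <- x - rowMeans(x)
  if (n == 0) return(omics_matrix(xc, matrix$kingdom, "corrected"))
  sds <- apply(x, 1L, stats::sd)
  xs <- x
  xs[sds > 0, ] <- t(scale(t(x[sds > 0, , drop = FALSE])))
  xs[sds == 0, ] <- 0
  v <- svd(xs, nu = 0, nv = n)$v   # sample scores; centered because rows are
  res <- xc - (xc %*% v) %*% t(v)
  omics_matrix(res, matrix$kingdom, "corrected")
}
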