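# Independent straight-line reference implementations used as oracles.
# These are deliberately naive (scalar loops, direct formulas) and share no
# code with the package internals.

ref_bicor <- function(x, y, max_p_outliers = 0.05) {
  side <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) return((v - mean(v)))    # Pearson fallback representation
    u <- (v - med) / (9 * madv)
    qs <- quantile(v, c(max_p_outliers, 1 - max_p_outliers), names = FALSE)
    ulo <- (qs[1] - med) / (9 * madv)
    uhi <- (qs[2] - med) / (9 * madv)
    if (ulo < -1) u[u < 0] <- u[u < 0] / abs(ulo)
    if (uhi > 1) u[u > 0] <- u[u > 0] / uhi
    w <- (1 - u^2)^2 * (abs(u) < 1)
    w * (v - med)
  }
  ax <- side(x); ay <- side(y)
  sum(ax * ay) / sqrt(sum(ax^2) * sum(ay^2))
}

ref_signed_adjacency <- function(cm, beta) {
  n <- nrow(cm)
  a <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) a[i, j] <- ((1 + cm[i, j]) / 2)^beta
  diag(a) <- 1
  a
}

ref_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(a[i, -i])
  tom <- diag(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    s <- 0
    for (u in 1:n) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

ref_connectivity <- function(a, lab) {
  n <- nrow(a)
  out <- matrix(NA_real_, n, 4, dimnames = list(rownames(a),
                c("kTotal", "kWithin", "kOut", "kDiff")))
  for (i in 1:n) {
    kt <- sum(a[i, -i])
    kw <- 0
    if (lab[i] != 0) {
      for (j in 1:n) if (j != i && lab[j] == lab[i]) kw <- kw + a[i, j]
    }
    out[i, ] <- c(kt, kw, kt - kw, kw - (kt - kw))
  }
  out
}

# exact hypergeometric upper tail by direct mass summation
ref_hyper_p <- function(overlap, term_size, module_size, universe_size) {
  hi <- min(term_size, module_size)
  sum(vapply(overlap:hi, function(x) {
    exp(lchoose(term_size, x) + lchoose(universe_size - term_size, module_size - x) -
        lchoose(universe_size, module_size))
  }, numeric(1)))
}

# direct CSS scale factor: sum of counts <= q-th quantile of nonzero counts
ref_css_factor <- function(col, q) {
  nz <- sort(col[col > 0])
  qv <- quantile(nz, q, names = FALSE)
  sum(col[col <= qv])
}

# direct TMM factor of one sample against a reference sample
ref_tmm_pair_factor <- function(obs, ref, trim_M = 0.30, trim_A = 0.05) {
  No <- sum(obs); Nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / No) / (r / Nr))
  A <- 0.5 * log2((o / No) * (r / Nr))
  w <- 1 / ((No - o) / (No * o) + (Nr - r) / (Nr * r))
  loM <- quantile(M, trim_M, names = FALSE); hiM <- quantile(M, 1 - trim_M, names = FALSE)
  loA <- quantile(A, trim_A, names = FALSE); hiA <- quantile(A, 1 - trim_A, names = FALSE)
  keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

# two-sided p from the t transform of a correlation
ref_cor_p <- function(r, n) {
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

# random correlation-like symmetric matrix with unit diagonal
random_corr <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 2)), n)
  cm <- cor(t(x))
  dimnames(cm) <- list(paste0("f", 1:n), paste0("f", 1:n))
  cm
}

random_omics <- function(nf, ns, seed, kingdom = "host", stage = "normalized_log2") {
  set.seed(seed)
  x <- matrix(rnorm(nf * ns), nf,
              dimnames = list(paste0("f", seq_len(nf)), paste0("s", seq_len(ns))))
  omics_matrix(x, kingdom, stage)
}

# minimal valid sample table for n samples split into groups
toy_samples <- function(feeds = c("FO", "VO"), waters = c("FW", "SW"),
                        days = c(1L, 5L), reps = 2L, seed = 1) {
  set.seed(seed)
  g <- expand.grid(rep = seq_len(reps), day = days, water = waters, feed = feeds,
                   stringsAsFactors = FALSE)
  make_sample_table(data.frame(
    sample_id = sprintf("G_%s_D%d_%s_%d", g$water, g$day, g$feed, g$rep),
    day = g$day, water = g$water, feed = g$feed,
    sex = sample(c("M", "F"), nrow(g), replace = TRUE),
    weight_g = round(runif(nrow(g), 40, 60), 1),
    length_mm = round(runif(nrow(g), 140, 170), 1)))
}

# adjusted Rand index (independent of mclust, direct contingency formula)
ref_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
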