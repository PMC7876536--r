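#' TMM normalization to log2 counts-per-million
#'
#' Between-sample normalization by the trimmed mean of M-values: each sample's
#' scale factor is a precision-weighted trimmed mean of per-feature log2 ratios
#' against a reference sample (the sample whose upper-quartile/library-size
#' ratio is closest to the mean of that ratio), with features zero in either
#' sample excluded, the extreme M- and A-values trimmed, and factors rescaled
#' to geometric mean 1. Factor computation is delegated to
#' [edgeR::calcNormFactors()]; the returned matrix is
#' `log2((count + pseudocount) / (library_size * factor) * 1e6)`.
#'
#' @param counts `omics_matrix` at stage `raw_counts` with >= 2 samples.
#' @param trim_M fraction of extreme log-ratios trimmed from each tail
#'   (default 0.30, the canonical TMM trim).
#' @param trim_A fraction of extreme average-intensity values trimmed from
#'   each tail (default 0.05).
#' @param pseudocount added to counts before the log (default 0.5).
#' @return A list of class `normalization_result`: `matrix` (stage
#'   `normalized_log2`), `scale_factors`, `method = "TMM"`, `params`.
#' @export
tmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05, pseudocount = 0.5) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$stage != "raw_counts") stop("TMM expects raw counts")
  x <- counts$values
  if (ncol(x) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(x)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  names(f) <- colnames(x)
  logcpm <- log2(sweep(x + pseudocount, 2L, lib * f, "/") * 1e6)
  out <- omics_matrix(logcpm, counts$kingdom, "normalized_log2")
  structure(list(matrix = out, scale_factors = f, method = "TMM",
                 params = list(trim_M = trim_M, trim_A = trim_A,
                               pseudocount = pseudocount)),
            class = "normalization_result")
}

#' Cumulative sum scaling normalization
#'
#' Per-sample scaling designed for sparse marker-gene count tables: the scale
#' factor of a sample is the sum of its counts that are less than or equal to
#' the sample's q-th quantile of its nonzero counts, and the output is
#' `log2(count / factor * 1000 + 1)`.
#'
#' @param counts `omics_matrix` at stage `raw_counts`.
#' @param quantile_p quantile of the nonzero counts, in (0, 1]; default 0.5.
#' @return A `normalization_result` with `method = "CSS"`.
#' @export
css_normalize <- function(counts, quantile_p = 0.5) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$stage != "raw_counts") stop("CSS expects raw counts")
  if (!is.numeric(quantile_p) || quantile_p <= 0 || quantile_p > 1)
    stop("'quantile_p' must be in (0, 1]")
  x <- counts$values
  f <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    nz <- col[col > 0]
    if (length(nz) == 0L)
      stop("sample with no nonzero counts: ", colnames(x)[j])
    q <- stats::quantile(nz, probs = quantile_p, names = FALSE, type = 7)
    sum(col[col <= q])
  }, numeric(1))
  names(f) <- colnames(x)
  norm <- log2(sweep(x, 2L, f, "/") * 1000 + 1)
  out <- omics_matrix(norm, counts$kingdom, "normalized_log2")
  structure(list(matrix = out, scale_factors = f, method = "CSS",
                 params = list(quantile_p = quantile_p)),
            class = "normalization_result")
}

filter_report <- function(all_ids, kept, rule_fired) {
  removed <- setdiff(all_ids, kept)
  structure(list(kept_ids = kept, removed_ids = removed,
                 rule_fired = rule_fired[removed]),
            class = "filter_report")
}

#' Expression/variance gene filter
#'
#' Keeps a gene iff its maximum normalized expression reaches `min_expr` in at
#' least one sample AND its across-sample standard deviation (n-1 denominator)
#' is at least `min_sd`. Genes failing the first rule are reported as
#' `max_expression`, the rest of the removals as `low_sd`.
#'
#' @param matrix `omics_matrix` at stage `normalized_log2`.
#' @param min_expr minimum of the per-gene maximum expression (default 1.0).
#' @param min_sd minimum per-gene standard deviation (default 0.15).
#' @return list with elements `matrix` (filtered, original feature order) and
#'   `report` (a `filter_report`).
#' @export
filter_genes <- function(matrix, min_expr = 1.0, min_sd = 0.15) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- matrix$values
  mx <- apply(x, 1L, max)
  sds <- apply(x, 1L, stats::sd)
  low_expr <- mx < min_expr
  low_sd <- !low_expr & sds < min_sd
  keep <- !(low_expr | sds < min_sd)
  rule <- character(0)
  rule[rownames(x)[low_expr]] <- "max_expression"
  rule[rownames(x)[low_sd]] <- "low_sd"
  if (!any(keep)) warning("all genes removed by filters")
  out <- if (any(keep)) {
    omics_matrix(x[keep, , drop = FALSE], matrix$kingdom, matrix$stage)
  } else NULL
  list(matrix = out, report = filter_report(rownames(x), rownames(x)[keep], rule))
}

#' Relative-abundance OTU filter
#'
#' Keeps an OTU iff its share of the grand total count is at least
#' `min_total_fraction` (boundary retained). Applied to raw counts, before
#' normalization.
#'
#' @param counts `omics_matrix` at stage `raw_counts`.
#' @param min_total_fraction minimum fraction of total abundance
#'   (default 5e-5, i.e. 0.005%).
#' @return list with `matrix` and `report` as in [filter_genes()].
#' @export
filter_otus <- function(counts, min_total_fraction = 0.00005) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (counts$stage != "raw_counts") stop("OTU filter applies to raw counts")
  x <- counts$values
  total <- sum(x)
  if (total == 0) stop("grand total of counts is zero")
  frac <- rowSums(x) / total
  keep <- frac >= min_total_fraction
  rule <- character(0)
  rule[rownames(x)[!keep]] <- "low_total_abundance"
  if (!any(keep)) warning("all OTUs removed by abundance filter")
  out <- if (any(keep)) {
    omics_matrix(x[keep, , drop = FALSE], counts$kingdom, counts$stage)
  } else NULL
  list(matrix = out, report = filter_report(rownames(x), rownames(x)[keep], rule))
}

#' Flag outlier samples by min-max scaling and average-linkage clustering
#'
#' Each sample is min-max scaled to [0, 1], samples are clustered by
#' average-linkage on Euclidean distance, and a sample is flagged when the
#' height at which it merges into the tree exceeds
#' `median(heights) + height_mad_k * MAD(heights)`. Flagging is advisory; the
#' caller decides whether to drop flagged samples.
#'
#' @param matrix an `omics_matrix` (any stage).
#' @param height_mad_k robust z-score cut on merge heights (default 5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(matrix, height_mad_k = 5) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- matrix$values
  n <- ncol(x)
  if (n < 4L) {
    warning("fewer than 4 samples; outlier detection skipped")
    return(character(0))
  }
  scaled <- apply(x, 2L, function(col) {
    r <- range(col)
    if (r[2] == r[1]) rep(0, length(col)) else (col - r[1]) / (r[2] - r[1])
  })
  d <- stats::dist(t(scaled))
  if (all(d == 0)) return(character(0))
  hc <- stats::hclust(d, method = "average")
  h <- hc$height
  cut <- stats::median(h) + height_mad_k * stats::mad(h)
  # a leaf's merge height = height of the first merge involving that leaf
  leaf_height <- vapply(seq_len(n), function(leaf) {
    m <- which(apply(hc$merge, 1L, function(row) any(row == -leaf)))[1]
    h[m]
  }, numeric(1))
  colnames(x)[leaf_height > cut]
}
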