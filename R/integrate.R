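#' Correlate row profiles with column variables across replicate groups
#'
#' The correlation engine of the integrated heatmap. For each (row profile,
#' variable) pair it computes Pearson r (or Spearman, i.e. Pearson on average
#' ranks, for variables flagged ordinal such as Day) with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Cells where either side has zero variance get `r = NA`, `p = 1`
#' and a flag; `|r| = 1` gets the smallest positive representable p, never an
#' exact 0.
#'
#' @param x numeric matrix, profiles in rows, one column per group.
#' @param y numeric matrix, one row per group, one column per variable
#'   (e.g. a trait matrix, or transposed group-level eigennodes).
#' @param spearman_cols character vector of `y` columns to correlate by
#'   Spearman (default: `attr(y, "spearman_traits")`).
#' @return list of class `corr_result`: matrices `r` and `p`
#'   (rows x variables), `n` (groups used per cell), `method` per column,
#'   `flag` (logical matrix, TRUE where r undefined).
#' @export
correlate_groups <- function(x, y, spearman_cols = attr(y, "spearman_traits")) {
  if (is.null(colnames(x)) || is.null(rownames(y)) ||
      !identical(colnames(x), rownames(y)))
    stop("'x' columns and 'y' rows must be the same groups in the same order")
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 groups")
  if (is.null(spearman_cols)) spearman_cols <- character(0)
  r <- p <- matrix(NA_real_, nrow(x), ncol(y), dimnames = list(rownames(x), colnames(y)))
  flag <- matrix(FALSE, nrow(x), ncol(y), dimnames = dimnames(r))
  nmat <- matrix(NA_integer_, nrow(x), ncol(y), dimnames = dimnames(r))
  method <- ifelse(colnames(y) %in% spearman_cols, "spearman", "pearson")
  names(method) <- colnames(y)
  for (j in seq_len(ncol(y))) {
    yj <- y[, j]
    for (i in seq_len(nrow(x))) {
      xi <- x[i, ]
      ok <- is.finite(xi) & is.finite(yj)
      cell <- cor_cell(xi[ok], yj[ok], method[j])
      r[i, j] <- cell$r; p[i, j] <- cell$p; flag[i, j] <- cell$flag
      nmat[i, j] <- sum(ok)
    }
  }
  structure(list(r = r, p = p, n = nmat, method = method, flag = flag),
            class = "corr_result")
}

cor_cell <- function(x, y, method) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = 1, flag = TRUE))
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = 1, flag = TRUE))
  }
  r <- stats::cor(x, y)
  r <- min(1, max(-1, r))
  if (abs(r) >= 1 - 1e-15) {
    return(list(r = sign(r), p = .Machine$double.xmin, flag = TRUE))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = max(p, .Machine$double.xmin), flag = FALSE)
}

#' Significance stars for a p-value
#'
#' `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for p <= 0.05, empty
#' otherwise. Bands are exhaustive and mutually exclusive over [0, 1].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of stars.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  out <- rep("", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out
}

#' Integrated heatmap analysis of holobiont interactions (iHAHI)
#'
#' Assembles the three-panel integrated heatmap: host module eigennode
#' profiles averaged over replicate groups (center), their correlations with
#' host traits (left; Spearman for the ordinal Day, Pearson otherwise), and
#' their correlations with microbiota module eigennodes (right; Pearson).
#' With the default row rule, only host modules with at least one significant
#' trait association AND at least one significant microbiota association
#' (p <= `alpha`) are kept — the putative-interaction candidates. Group
#' columns are ordered by feed, then water, then day.
#'
#' @param hme host `eigennode_matrix` (sample-level columns).
#' @param mme microbiota `eigennode_matrix`.
#' @param traits trait matrix from [encode_traits()].
#' @param samples sample table covering the eigennode columns.
#' @param row_rule `"significant"` (default) or `"all"`.
#' @param alpha significance level for the row rule (default 0.05).
#' @return list of class `ihahi_result`: `center` (group-mean hME profiles for
#'   the selected rows), `left` and `right` (`corr_result`s over all hMEs),
#'   `left_stars`, `right_stars`, `selected` (hME names kept), `groups`.
#' @export
build_ihahi <- function(hme, mme, traits, samples,
                        row_rule = c("significant", "all"), alpha = 0.05) {
  row_rule <- match.arg(row_rule)
  hme_g <- average_replicates(hme, samples)
  mme_g <- average_replicates(mme, samples)
  groups <- intersect(colnames(hme_g), intersect(colnames(mme_g), rownames(traits)))
  if (length(groups) < 3L) stop("fewer than 3 shared replicate groups")
  hme_g <- hme_g[, groups, drop = FALSE]
  mme_g <- mme_g[, groups, drop = FALSE]
  tr <- traits[groups, , drop = FALSE]
  attr(tr, "spearman_traits") <- attr(traits, "spearman_traits")
  keep_tr <- apply(tr, 2L, function(col) stats::sd(col, na.rm = TRUE) > 0)
  if (!all(keep_tr)) {
    sp <- attr(tr, "spearman_traits")
    tr <- tr[, keep_tr, drop = FALSE]
    attr(tr, "spearman_traits") <- intersect(sp, colnames(tr))
  }
  left <- correlate_groups(hme_g, tr)
  right <- correlate_groups(hme_g, t(mme_g), spearman_cols = character(0))
  if (row_rule == "significant") {
    sel <- rownames(hme_g)[apply(left$p, 1L, min, na.rm = TRUE) <= alpha &
                           apply(right$p, 1L, min, na.rm = TRUE) <= alpha]
    if (length(sel) == 0L)
      warning("no host module passes the significance row rule; result is empty")
  } else {
    sel <- rownames(hme_g)
  }
  stars <- function(p) {
    s <- matrix(significance_stars(p), nrow(p), ncol(p), dimnames = dimnames(p))
    s
  }
  structure(list(center = hme_g[sel, , drop = FALSE],
                 left = left, right = right,
                 left_stars = stars(left$p), right_stars = stars(right$p),
                 selected = sel, groups = groups, alpha = alpha),
            class = "ihahi_result")
}

#' Single gene-OTU follow-up correlation
#'
#' Drill-down utility for a predicted module pair: Pearson correlation and
#' p-value between one host gene profile and one OTU profile after replicate
#' averaging. Exactly consistent with [correlate_groups()] on the same 1 x 1
#' input.
#'
#' @param gene_profile named numeric vector (samples) or 1-row matrix.
#' @param otu_profile named numeric vector (samples) or 1-row matrix.
#' @param samples sample table.
#' @return list: `r`, `p`, `n`.
#' @export
node_level_follow_up <- function(gene_profile, otu_profile, samples) {
  as_row <- function(v, nm) {
    if (is.matrix(v)) return(v)
    matrix(v, 1L, dimnames = list(nm, names(v)))
  }
  g <- average_replicates(as_row(gene_profile, "gene"), samples)
  o <- average_replicates(as_row(otu_profile, "otu"), samples)
  common <- intersect(colnames(g), colnames(o))
  res <- correlate_groups(g[, common, drop = FALSE],
                          t(o[, common, drop = FALSE]),
                          spearman_cols = character(0))
  list(r = res$r[1, 1], p = res$p[1, 1], n = res$n[1, 1])
}

#' Write the numeric blocks of an iHAHI result to TSV files
#'
#' Emits `<prefix>_center.tsv`, `<prefix>_left.tsv`, `<prefix>_right.tsv`
#' (correlations) and `<prefix>_stars.tsv`, so any figure is a pure view of
#' exported numbers.
#'
#' @param res an `ihahi_result`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_ihahi <- function(res, prefix) {
  wm <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(format_numeric_df(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  sel <- res$selected
  paths <- c(
    wm(res$center, paste0(prefix, "_center.tsv")),
    wm(res$left$r[sel, , drop = FALSE], paste0(prefix, "_left.tsv")),
    wm(res$right$r[sel, , drop = FALSE], paste0(prefix, "_right.tsv")),
    wm(cbind(res$left_stars, res$right_stars)[sel, , drop = FALSE],
       paste0(prefix, "_stars.tsv")),
    wm(res$left$p[sel, , drop = FALSE], paste0(prefix, "_left_p.tsv")),
    wm(res$right$p[sel, , drop = FALSE], paste0(prefix, "_right_p.tsv")))
  invisible(paths)
}

#' Plot an iHAHI result as a three-panel heatmap
#'
#' Renders the center/left/right blocks with pheatmap (if installed) into a
#' single PNG; purely a view of the numbers exported by [write_ihahi()].
#'
#' @param res an `ihahi_result`.
#' @param path output image path (PNG).
#' @export
plot_ihahi <- function(res, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    warning("pheatmap not installed; skipping figure")
    return(invisible(NULL))
  }
  sel <- res$selected
  if (length(sel) == 0L) {
    warning("empty iHAHI result; nothing to plot")
    return(invisible(NULL))
  }
  block <- cbind(res$left$r[sel, , drop = FALSE],
                 res$center,
                 res$right$r[sel, , drop = FALSE])
  grDevices::png(path, width = 200 + 24 * ncol(block), height = 120 + 16 * length(sel))
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(block, cluster_rows = length(sel) > 1, cluster_cols = FALSE,
                     main = "iHAHI: traits | hME group profiles | mME correlations")
  invisible(path)
}
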