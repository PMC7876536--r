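#' Signed adjacency from a correlation matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, so perfectly anti-correlated features get
#' adjacency 0 and the network keeps the sign information of the correlations.
#'
#' @param corr a `correlation_matrix` (or a plain symmetric matrix in
#'   [-1, 1]).
#' @param beta soft-threshold power, > 0.
#' @return list of class `adjacency_matrix`: `values` in [0, 1] with unit
#'   diagonal, and `beta`.
#' @export
signed_adjacency <- function(corr, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("'beta' must be a positive scalar")
  cm <- if (inherits(corr, "correlation_matrix")) corr$values else corr
  a <- ((1 + cm) / 2)^beta
  diag(a) <- 1
  structure(list(values = a, beta = beta), class = "adjacency_matrix")
}

#' Signed weighted topological overlap
#'
#' Pairwise similarity combining the direct edge with shared-neighbor
#' adjacency:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k_i = sum_{u != i} a_iu`; the diagonal is 1.
#' `1 - TOM` is the clustering dissimilarity used for module detection.
#'
#' @param adj an `adjacency_matrix` (or plain matrix with entries in [0, 1]).
#' @return list of class `tom_matrix` with `values` in [0, 1].
#' @export
signed_tom <- function(adj) {
  a <- if (inherits(adj, "adjacency_matrix")) adj$values else adj
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  n <- nrow(a)
  k <- rowSums(a) - 1          # unit diagonal excluded
  shared <- a %*% a            # (A^2)_ij = sum_u a_iu a_uj incl. u = i, j
  num <- shared - a            # = sum_{u != i,j} a_iu a_uj + a_ij (diag = 1)
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom[den == 0] <- 0
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(a)
  structure(list(values = tom), class = "tom_matrix")
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the signed adjacency, computes node
#' connectivities `k_i`, bins `log10(k)`, and regresses log10 bin frequency on
#' log10 mean bin connectivity; the fit index is `R^2 * sign(-slope)` so only
#' decreasing (scale-free-like) degree distributions score high. Returns the
#' smallest candidate whose fit reaches `r2_cut`, or the best-fitting
#' candidate with a `no_power_reached_cut` flag.
#'
#' @param corr a `correlation_matrix`.
#' @param candidate_powers ordered positive candidate exponents.
#' @param r2_cut minimum acceptable fit index (default 0.85).
#' @param n_bins connectivity histogram bins (default 10).
#' @return list: `power`, `fit_table` (power, fit, slope, mean_k, median_k,
#'   max_k), `flag` (`""` or `"no_power_reached_cut"`).
#' @export
pick_soft_threshold <- function(corr, candidate_powers = 1:30, r2_cut = 0.85,
                                n_bins = 10) {
  if (length(candidate_powers) == 0L) stop("empty candidate power list")
  cm <- if (inherits(corr, "correlation_matrix")) corr$values else corr
  if (nrow(cm) < 20L) warning("fewer than 20 features; scale-free fit is unreliable")
  rows <- lapply(candidate_powers, function(beta) {
    a <- signed_adjacency(cm, beta)$values
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k, n_bins)
    data.frame(power = beta, fit = unname(sf["fit"]), slope = unname(sf["slope"]),
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  fit_table <- do.call(rbind, rows)
  rownames(fit_table) <- NULL
  ok <- which(fit_table$fit >= r2_cut)
  if (length(ok)) {
    list(power = fit_table$power[ok[1]], fit_table = fit_table, flag = "")
  } else {
    list(power = fit_table$power[which.max(fit_table$fit)],
         fit_table = fit_table, flag = "no_power_reached_cut")
  }
}

# R^2 * sign(-slope) of the log-log degree-distribution regression
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2L || diff(range(k)) == 0)
    return(c(fit = 0, slope = 0))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins),
                   function(b) mean(k[as.integer(bin) == b]), numeric(1))
  keep <- freq > 0 & mean_k > 0
  if (sum(keep) < 2L) return(c(fit = 0, slope = 0))
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep])
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  c(fit = unname(r2 * sign(-slope)), slope = unname(slope))
}

#' Detect modules by tree cut of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a height
#' threshold placed within the merge-height range according to `deep_split`:
#' `h* = base + span * (0.95 - 0.05 * (4 - deep_split))` with `base`/`span`
#' the minimum and range of the merge heights (deep_split 4, the most
#' sensitive, cuts at 95% of the range; each step down moves the cut 5%
#' lower). Because branches smaller than `min_module_size` are discarded
#' rather than assigned, a higher cut retains more of the tree's fine
#' structure as countable modules, so deeper splits yield more modules on
#' structured data. Branches
#' joined below `h*` with at least `min_module_size` leaves become modules;
#' all other nodes stay unassigned (label 0). There is no post-hoc
#' reassignment of unassigned nodes (no PAM stage; reassignment threshold 0).
#' Labels are consecutive integers ordered by decreasing module size, ties
#' broken by the smallest member id.
#'
#' @param diss square symmetric dissimilarity matrix with zero diagonal
#'   (typically `1 - TOM`).
#' @param params a [network_params()] (uses `deep_split`, `min_module_size`).
#' @return named integer vector of module labels (0 = unassigned), class
#'   `module_partition`.
#' @export
detect_modules <- function(diss, params = network_params()) {
  if (inherits(diss, "tom_matrix")) diss <- 1 - diss$values
  if (!is.matrix(diss) || nrow(diss) != ncol(diss))
    stop("dissimilarity must be a square matrix")
  n <- nrow(diss)
  ids <- rownames(diss)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    lab <- stats::setNames(0L, ids)
    return(structure(lab, class = "module_partition"))
  }
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  h <- hc$height
  base <- min(h); span <- max(h) - min(h)
  hstar <- base + span * (0.95 - 0.05 * (4 - params$deep_split))
  raw <- stats::cutree(hc, h = hstar)
  sizes <- table(raw)
  raw[raw %in% as.integer(names(sizes)[sizes < params$min_module_size])] <- 0L
  lab <- stats::setNames(as.integer(raw), ids)
  structure(relabel_by_size(lab), class = "module_partition")
}

# compact labels to 1..K ordered by decreasing size, ties by smallest member id
relabel_by_size <- function(lab) {
  mods <- setdiff(unique(lab), 0L)
  if (length(mods) == 0L) return(lab)
  first_member <- vapply(mods, function(m) sort(names(lab)[lab == m])[1], character(1))
  sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
  ord <- order(-sizes, first_member)
  new <- stats::setNames(seq_along(mods), mods[ord])
  out <- lab
  out[lab != 0L] <- new[as.character(lab[lab != 0L])]
  stats::setNames(as.integer(out), names(lab))
}

#' Module eigennodes (eigengenes / eigenOTUs)
#'
#' The representative profile of each module: member feature rows are
#' standardized (zero mean, unit variance over samples), the first right
#' singular vector of the standardized member matrix is taken, re-standardized
#' and sign-oriented so that its correlation with the module's mean
#' standardized profile is non-negative. `var_explained` is the first squared
#' singular value over the total. Rows are named `hME<k>` (host) or `mME<k>`
#' (microbe). Zero-variance members are dropped from the computation with a
#' warning.
#'
#' @param matrix an `omics_matrix`.
#' @param partition a `module_partition` over the matrix features.
#' @return list of class `eigennode_matrix`: `values` (module x sample),
#'   `var_explained`, `kingdom`.
#' @export
module_eigennode <- function(matrix, partition) {
  stopifnot(inherits(matrix, "omics_matrix"))
  x <- matrix$values
  mods <- setdiff(sort(unique(as.integer(partition))), 0L)
  prefix <- if (matrix$kingdom == "host") "hME" else "mME"
  n <- ncol(x)
  vals <- matrix(NA_real_, length(mods), n,
                 dimnames = list(paste0(prefix, mods), colnames(x)))
  ve <- stats::setNames(numeric(length(mods)), paste0(prefix, mods))
  for (i in seq_along(mods)) {
    members <- names(partition)[partition == mods[i]]
    xm <- x[members, , drop = FALSE]
    sds <- apply(xm, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " zero-variance member(s) from module ",
              mods[i])
      xm <- xm[sds > 0, , drop = FALSE]
    }
    if (nrow(xm) == 0L) stop("module ", mods[i], " has no usable members")
    xs <- t(scale(t(xm)))
    sv <- svd(xs)
    e <- sv$v[, 1]
    e <- (e - mean(e)) / stats::sd(e)
    mean_profile <- colMeans(xs)
    if (stats::sd(mean_profile) > 0 && stats::cor(e, mean_profile) < 0) e <- -e
    vals[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = vals, var_explained = ve, kingdom = matrix$kingdom),
            class = "eigennode_matrix")
}

#' Module membership (KME) table
#'
#' Correlation between each feature profile and each module eigennode, using
#' the same correlation flavor as the network (biweight midcorrelation by
#' default). Column `ME<k>` corresponds to module `k`.
#'
#' @param matrix an `omics_matrix`.
#' @param eigennodes an `eigennode_matrix` sharing the matrix's sample set.
#' @param method `"bicor"` (default) or `"pearson"`.
#' @param max_p_outliers passed to [bicor()].
#' @return node x module matrix of class `kme_table`, entries in [-1, 1].
#' @export
kme <- function(matrix, eigennodes, method = c("bicor", "pearson"),
                max_p_outliers = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "omics_matrix"), inherits(eigennodes, "eigennode_matrix"))
  if (!identical(sample_ids(matrix), colnames(eigennodes$values))) {
    if (!setequal(sample_ids(matrix), colnames(eigennodes$values)))
      stop("sample sets of matrix and eigennodes differ")
    eigennodes$values <- eigennodes$values[, sample_ids(matrix), drop = FALSE]
  }
  x <- matrix$values
  en <- eigennodes$values
  modn <- sub("^[hm]ME", "ME", rownames(en))
  out <- matrix(NA_real_, nrow(x), nrow(en), dimnames = list(rownames(x), modn))
  for (j in seq_len(nrow(en))) {
    ej <- en[j, ]
    out[, j] <- apply(x, 1L, function(row) {
      if (method == "bicor") {
        suppressWarnings(suppressMessages(bicor(row, ej, max_p_outliers)))
      } else {
        if (stats::sd(row) == 0 || stats::sd(ej) == 0) 0 else stats::cor(row, ej)
      }
    })
  }
  structure(out, class = c("kme_table", "matrix", "array"))
}

#' Trim modules by membership strength
#'
#' Nodes whose KME to their own module falls below `min_kme_to_stay` are set
#' unassigned, and a module is dissolved entirely unless it keeps a core of at
#' least `min_core_kme_size` nodes with KME above `min_core_kme`. Surviving
#' labels are recompacted by size.
#'
#' @param partition a `module_partition`.
#' @param kme_table a `kme_table` computed on that partition's eigennodes.
#' @param params a [network_params()].
#' @return trimmed `module_partition`.
#' @export
trim_modules <- function(partition, kme_table, params = network_params()) {
  lab <- as.integer(partition)
  names(lab) <- names(partition)
  mods <- setdiff(unique(lab), 0L)
  for (m in mods) {
    col <- paste0("ME", m)
    members <- names(lab)[lab == m]
    km <- kme_table[members, col]
    drop <- members[km < params$min_kme_to_stay]
    lab[drop] <- 0L
    core <- sum(kme_table[members, col] > params$min_core_kme)
    if (core < params$min_core_kme_size) lab[names(lab)[lab == m]] <- 0L
  }
  structure(relabel_by_size(lab), class = "module_partition")
}

#' Merge modules with similar eigennodes
#'
#' Iteratively: compute eigennodes, cluster modules by average linkage on the
#' dissimilarity `1 - cor(eigennodes)`, merge every group of modules joined
#' below `merge_cut_height`, and recompute, until no pair of eigennodes has
#' dissimilarity below the threshold (so modules whose eigennodes correlate
#' above `1 - merge_cut_height` end up merged). Anti-correlated modules are
#' never merged: their dissimilarity approaches 2.
#'
#' @param matrix an `omics_matrix`.
#' @param partition a `module_partition`.
#' @param params a [network_params()] (uses `merge_cut_height`, `merge_cor`).
#' @param max_iter safety bound on the recompute loop.
#' @return list: `partition` (merged, relabelled) and `eigennodes` (final).
#' @export
merge_modules <- function(matrix, partition, params = network_params(),
                          max_iter = 20L) {
  lab <- structure(stats::setNames(as.integer(partition), names(partition)),
                   class = "module_partition")
  for (iter in seq_len(max_iter)) {
    en <- module_eigennode(matrix, lab)
    k <- nrow(en$values)
    if (k < 2L) return(list(partition = lab, eigennodes = en))
    d <- 1 - eigennode_cor(en, params)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- stats::cutree(hc, h = params$merge_cut_height)
    if (max(groups) == k) return(list(partition = lab, eigennodes = en))
    modnum <- as.integer(sub("^[hm]ME", "", rownames(en$values)))
    map <- stats::setNames(groups, modnum)
    newlab <- lab
    assigned <- lab != 0L
    newlab[assigned] <- as.integer(map[as.character(lab[assigned])])
    lab <- structure(relabel_by_size(stats::setNames(as.integer(newlab), names(lab))),
                     class = "module_partition")
  }
  en <- module_eigennode(matrix, lab)
  list(partition = lab, eigennodes = en)
}

eigennode_cor <- function(en, params) {
  if (params$merge_cor == "pearson") {
    stats::cor(t(en$values))
  } else {
    n <- nrow(en$values)
    out <- diag(n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <-
        suppressWarnings(bicor(en$values[i, ], en$values[j, ]))
    }
    dimnames(out) <- list(rownames(en$values), rownames(en$values))
    out
  }
}

#' Intramodular connectivity decomposition
#'
#' For every node: `kTotal` (sum of adjacencies to all other nodes),
#' `kWithin` (to same-module nodes), `kOut = kTotal - kWithin` and
#' `kDiff = kWithin - kOut`. Unassigned nodes have `kWithin = 0`.
#'
#' @param adj an `adjacency_matrix`.
#' @param partition a `module_partition` over the same nodes.
#' @return data.frame (rownames = node ids) with columns kTotal, kWithin,
#'   kOut, kDiff.
#' @export
intramodular_connectivity <- function(adj, partition) {
  a <- if (inherits(adj, "adjacency_matrix")) adj$values else adj
  nodes <- rownames(a)
  if (!setequal(nodes, names(partition))) stop("node sets differ")
  lab <- partition[nodes]
  k_total <- rowSums(a) - 1
  k_within <- vapply(seq_along(nodes), function(i) {
    if (lab[i] == 0L) return(0)
    same <- which(lab == lab[i])
    sum(a[i, same]) - 1
  }, numeric(1))
  data.frame(kTotal = k_total, kWithin = k_within, kOut = k_total - k_within,
             kDiff = 2 * k_within - k_total, row.names = nodes)
}

#' Full single-block network inference
#'
#' Composes the whole module pipeline: biweight midcorrelation, soft-threshold
#' selection by scale-free fit (unless `params$power` is set), signed
#' adjacency, signed TOM, tree-cut module detection, eigennodes, KME trimming,
#' eigennode merging, and intramodular connectivity. Deterministic given its
#' inputs.
#'
#' @param matrix a preprocessed (`normalized_log2` or `corrected`)
#'   `omics_matrix`.
#' @param params a [network_params()].
#' @return list of class `holonet_network`: `partition`, `eigennodes`, `kme`,
#'   `connectivity`, `power`, `fit_table`, `flag`, `params`.
#' @export
infer_network <- function(matrix, params = network_params()) {
  corr <- correlation_matrix(matrix, params)
  if (is.null(params$power)) {
    st <- pick_soft_threshold(corr, params$candidate_powers, params$r2_cut)
    power <- st$power; fit_table <- st$fit_table; flag <- st$flag
  } else {
    power <- params$power; fit_table <- NULL; flag <- ""
  }
  adj <- signed_adjacency(corr, power)
  tom <- signed_tom(adj)
  part <- detect_modules(1 - tom$values, params)
  if (any(part > 0)) {
    en <- module_eigennode(matrix, part)
    km <- kme(matrix, en, method = params$kme_cor,
              max_p_outliers = params$max_p_outliers)
    part <- trim_modules(part, km, params)
  }
  if (any(part > 0)) {
    merged <- merge_modules(matrix, part, params)
    part <- merged$partition
    en <- merged$eigennodes
    km <- kme(matrix, en, method = params$kme_cor,
              max_p_outliers = params$max_p_outliers)
  } else {
    en <- NULL
    km <- NULL
  }
  conn <- intramodular_connectivity(adj, part)
  structure(list(partition = part, eigennodes = en, kme = km,
                 connectivity = conn, power = power, fit_table = fit_table,
                 flag = flag, params = params),
            class = "holonet_network")
}

#' @export
print.holonet_network <- function(x, ...) {
  nmod <- length(setdiff(unique(x$partition), 0L))
  cat(sprintf("holonet_network: %d nodes, %d modules (power %s), %d unassigned\n",
              length(x$partition), nmod, format(x$power),
              sum(x$partition == 0L)))
  invisible(x)
}
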