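#' Read a count/expression table into an omics matrix
#'
#' Reads a delimited text table with one header row of ids and one id column,
#' validates it, and returns it in features x samples orientation. Orientation
#' is always explicit: the function never guesses whether rows are features.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param kingdom `"host"` or `"microbe"`.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param stage processing stage of the stored values; default `"raw_counts"`.
#' @param sep field separator, `"\t"` or `","`.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, kingdom = c("host", "microbe"),
                             orientation = c("features_in_rows", "samples_in_rows"),
                             stage = "raw_counts", sep = "\t") {
  kingdom <- match.arg(kingdom)
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(colnames(body)))
    stop("duplicate column ids in ", path)
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell in %s at row '%s', column '%s'",
                 path, ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  }
  rownames(num) <- ids
  if (orientation == "samples_in_rows") num <- t(num)
  omics_matrix(num, kingdom = kingdom, stage = stage)
}

#' Write an omics matrix to a delimited file
#'
#' Inverse of [read_omics_table()]; features in rows, full double precision.
#'
#' @param x an `omics_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @param id_header header for the id column.
#' @export
write_omics_table <- function(x, path, sep = "\t", id_header = "feature_id") {
  df <- data.frame(id = feature_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_header
  utils::write.table(format_numeric_df(df), path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# full-precision, locale-independent number formatting for all writers
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

FEED_LEVELS <- c("FO", "VO", "FOVO", "VOFO")
WATER_LEVELS <- c("FW", "SW")
SEX_LEVELS <- c("M", "F", "unknown")

#' Build a validated sample metadata table
#'
#' Validates enums, synthesizes the replicate-group key
#' `"<feed>_<water>_D<day>"`, and checks id uniqueness. The feed levels are the
#' four diets of the feeding-trial design: fish oil (FO), vegetable oil (VO)
#' and the two mid-trial switches (FOVO, VOFO); water is fresh (FW) or salt
#' (SW).
#'
#' @param df data.frame with columns `sample_id`, `day`, `water`, `feed`,
#'   `sex`, `weight_g`, `length_mm`.
#' @return The validated data.frame with an added `group_id` column, feeds and
#'   water as factors with fixed level order.
#' @export
make_sample_table <- function(df) {
  req <- c("sample_id", "day", "water", "feed", "sex", "weight_g", "length_mm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("water", "feed", "sex")) {
    lv <- switch(col, water = WATER_LEVELS, feed = FEED_LEVELS, sex = SEX_LEVELS)
    bad <- setdiff(unique(as.character(df[[col]])), lv)
    if (length(bad))
      stop(sprintf("unknown %s level(s) %s; allowed: %s", col,
                   paste(bad, collapse = ", "), paste(lv, collapse = ", ")))
  }
  df$day <- as.integer(df$day)
  if (any(is.na(df$day) | df$day < 0)) stop("'day' must be a non-negative integer")
  df$weight_g <- as.numeric(df$weight_g)
  df$length_mm <- as.numeric(df$length_mm)
  if (any(!is.na(df$weight_g) & df$weight_g <= 0)) stop("'weight_g' must be positive")
  if (any(!is.na(df$length_mm) & df$length_mm <= 0)) stop("'length_mm' must be positive")
  df$feed <- factor(as.character(df$feed), levels = FEED_LEVELS)
  df$water <- factor(as.character(df$water), levels = WATER_LEVELS)
  df$sex <- factor(as.character(df$sex), levels = SEX_LEVELS)
  df$group_id <- sprintf("%s_%s_D%d", df$feed, df$water, df$day)
  rownames(df) <- NULL
  df
}

#' Read sample metadata
#'
#' @param path TSV (or CSV via `sep`) with the columns listed in
#'   [make_sample_table()].
#' @param sep field separator.
#' @return A validated sample table with `group_id`.
#' @export
read_sample_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "")
  make_sample_table(df)
}

#' Write sample metadata
#' @param samples a validated sample table.
#' @param path output path.
#' @param sep field separator.
#' @export
write_sample_table <- function(samples, path, sep = "\t") {
  out <- samples
  for (col in c("feed", "water", "sex")) out[[col]] <- as.character(out[[col]])
  utils::write.table(format_numeric_df(out), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' Three-column TSV (`gene_id`, `term_id`, `description`); terms are assumed
#' pre-propagated to ancestors where that matters.
#'
#' @param path annotation TSV.
#' @param sep field separator.
#' @return A list with `gene2terms` (named list of character vectors) and
#'   `term_desc` (named character vector).
#' @export
read_annotation_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "")
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation must have columns gene_id, term_id (and optionally description)")
  g2t <- split(df$term_id, df$gene_id)
  g2t <- lapply(g2t, unique)
  if (any(lengths(g2t) == 0L)) stop("annotation lists a gene with no terms")
  desc <- if ("description" %in% names(df)) {
    d <- df$description[!duplicated(df$term_id)]
    names(d) <- df$term_id[!duplicated(df$term_id)]
    d
  } else {
    u <- unique(df$term_id); stats::setNames(u, u)
  }
  list(gene2terms = g2t, term_desc = desc)
}

#' Write per-node module assignments, membership and connectivity
#'
#' One row per node: id, module label (0 = unassigned "grey" nodes), kME to the
#' node's own module, and the connectivity decomposition kTotal / kWithin /
#' kOut / kDiff. Round-trips losslessly through [read_module_assignments()].
#'
#' @param partition named integer vector of module labels (0 = unassigned).
#' @param kme `kme_table` (node x module matrix) or `NULL`.
#' @param connectivity data.frame from [intramodular_connectivity()] or `NULL`.
#' @param path output path.
#' @export
write_module_assignments <- function(partition, kme = NULL, connectivity = NULL, path) {
  nodes <- names(partition)
  if (is.null(nodes)) stop("partition must be a named vector")
  own_kme <- rep(NA_real_, length(nodes))
  if (!is.null(kme)) {
    if (!setequal(rownames(kme), nodes)) stop("node sets of partition and kme differ")
    kme <- kme[nodes, , drop = FALSE]
    lab <- partition[nodes]
    has <- lab > 0 & paste0("ME", lab) %in% colnames(kme)
    own_kme[has] <- kme[cbind(which(has), match(paste0("ME", lab[has]), colnames(kme)))]
  }
  if (!is.null(connectivity)) {
    if (!setequal(rownames(connectivity), nodes))
      stop("node sets of partition and connectivity differ")
    connectivity <- connectivity[nodes, , drop = FALSE]
  } else {
    connectivity <- data.frame(kTotal = NA_real_, kWithin = NA_real_,
                               kOut = NA_real_, kDiff = NA_real_)[rep(1, length(nodes)), ]
  }
  df <- data.frame(node_id = nodes, module = unname(partition[nodes]),
                   kME_own = own_kme,
                   kTotal = connectivity$kTotal, kWithin = connectivity$kWithin,
                   kOut = connectivity$kOut, kDiff = connectivity$kDiff,
                   stringsAsFactors = FALSE)
  if (length(nodes) == 0L)
    df <- df[0, , drop = FALSE]
  utils::write.table(format_numeric_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a module-assignment file
#' @param path file written by [write_module_assignments()].
#' @return data.frame with one row per node.
#' @export
read_module_assignments <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Intersect the sample sets of paired host/microbe matrices
#'
#' Per-kingdom sample sets can legitimately differ (e.g. per-kingdom outlier
#' removal); this drops non-shared samples with a warning and returns both
#' matrices on the common, identically ordered sample set.
#'
#' @param host,microbe `omics_matrix` objects.
#' @return list with elements `host` and `microbe`.
#' @export
align_samples <- function(host, microbe) {
  common <- intersect(sample_ids(host), sample_ids(microbe))
  if (length(common) == 0L) stop("no shared samples between kingdoms")
  dropped <- c(setdiff(sample_ids(host), common), setdiff(sample_ids(microbe), common))
  if (length(dropped))
    warning("dropping samples absent from one kingdom: ", paste(dropped, collapse = ", "))
  list(host = subset_omics(host, samples = common),
       microbe = subset_omics(microbe, samples = common))
}
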