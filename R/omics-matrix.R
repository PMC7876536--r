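#' Omics matrix container
#'
#' The substrate of every normalization and network step: a features x samples
#' numeric matrix tagged with the kingdom it measures (host transcriptome or
#' gut microbiota) and the processing stage it has reached.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry row and column names (feature ids / sample ids).
#' @param kingdom `"host"` or `"microbe"`.
#' @param stage `"raw_counts"`, `"normalized_log2"` or `"corrected"`.
#'   Raw counts must be finite and non-negative; later stages merely finite.
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `kingdom` and `stage`.
#' @export
omics_matrix <- function(values, kingdom = c("host", "microbe"),
                         stage = c("raw_counts", "normalized_log2", "corrected")) {
  kingdom <- match.arg(kingdom)
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty omics matrix (", nrow(values), " x ", ncol(values), ")")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values in omics matrix")
  if (stage == "raw_counts" && any(values < 0))
    stop("raw counts must be non-negative")
  structure(list(values = values, kingdom = kingdom, stage = stage),
            class = "omics_matrix")
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an omics matrix
#' @param x an `omics_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$kingdom, x$stage))
  invisible(x)
}

#' Subset an omics matrix by feature and/or sample ids
#'
#' @param x an `omics_matrix`.
#' @param features,samples character vectors of ids to keep (default: all).
#' @return An `omics_matrix` at the same stage.
#' @export
subset_omics <- function(x, features = feature_ids(x), samples = sample_ids(x)) {
  missing_f <- setdiff(features, feature_ids(x))
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_f)) stop("unknown feature ids: ", paste(missing_f, collapse = ", "))
  if (length(missing_s)) stop("unknown sample ids: ", paste(missing_s, collapse = ", "))
  omics_matrix(x$values[features, samples, drop = FALSE], x$kingdom, x$stage)
}
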