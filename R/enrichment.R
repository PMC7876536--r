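#' Hypergeometric term over-representation for a module
#'
#' Classic one-sided hypergeometric (Fisher) test per term: for each annotated
#' term overlapping the module, `p = P(X >= overlap)` where X is
#' hypergeometric with the universe size, term size and module size as
#' margins. Terms with zero overlap are not reported. No graph-aware
#' decorrelation across terms is performed; terms are tested independently on
#' the annotation as given (assumed pre-propagated).
#'
#' @param module_genes character vector of gene ids, a subset of `universe`.
#' @param annotation annotation map from [read_annotation_map()] (or a list
#'   with `gene2terms` and `term_desc`).
#' @param universe character vector of gene ids defining the background
#'   (typically all network genes after filtering).
#' @param adjust `"none"` (default, raw p-values) or `"BH"` for an optional
#'   Benjamini-Hochberg column.
#' @return data.frame of class `enrichment_result`, sorted by ascending p:
#'   term_id, description, overlap, module_size, term_size, universe_size, p
#'   (and p_adj when requested).
#' @export
hypergeometric_enrichment <- function(module_genes, annotation, universe,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (anyDuplicated(module_genes)) module_genes <- unique(module_genes)
  outside <- setdiff(module_genes, universe)
  if (length(outside))
    stop("module genes outside the universe: ", paste(outside, collapse = ", "))
  g2t <- annotation$gene2terms[intersect(names(annotation$gene2terms), universe)]
  term_genes <- split(rep(names(g2t), lengths(g2t)), unlist(g2t, use.names = FALSE))
  N <- length(universe)
  nmod <- length(module_genes)
  rows <- lapply(names(term_genes), function(term) {
    tg <- unique(term_genes[[term]])
    ov <- length(intersect(tg, module_genes))
    if (ov == 0L) return(NULL)
    K <- length(tg)
    p <- stats::phyper(ov - 1L, K, N - K, nmod, lower.tail = FALSE)
    data.frame(term_id = term,
               description = unname(annotation$term_desc[term]),
               overlap = ov, module_size = nmod, term_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), description = character(0),
               overlap = integer(0), module_size = integer(0),
               term_size = integer(0), universe_size = integer(0),
               p = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
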