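#' Network inference parameters
#'
#' Bundles every tuning constant of the signed network pipeline. Defaults are
#' tuned to detect highly correlated, potentially very small modules first
#' (minimum module size 2, deepest split, strict membership trimming) and then
#' merge aggressively on eigennode similarity, so that small but coherent
#' abundance profiles are not lost while redundant modules collapse. The merge
#' cut height default differs by kingdom: 0.5 for host, 0.4 for microbiota.
#'
#' @param kingdom `"host"` or `"microbe"`; sets the `merge_cut_height` default.
#' @param power soft-threshold exponent; `NULL` (default) selects it by
#'   scale-free fit via [pick_soft_threshold()].
#' @param candidate_powers powers scanned when `power` is `NULL`.
#' @param r2_cut minimum scale-free fit index (default 0.85).
#' @param max_p_outliers maximum fraction of observations on each side of the
#'   median allowed zero weight in the biweight midcorrelation (default 0.05).
#' @param deep_split module-detection sensitivity, integer 0-4; 4 (default)
#'   is most sensitive (finest cut).
#' @param min_module_size minimum branch size to form a module (default 2).
#' @param min_kme_to_stay nodes with own-module KME below this are trimmed
#'   (default 0.5).
#' @param min_core_kme,min_core_kme_size a module survives only with at least
#'   `min_core_kme_size` nodes whose KME exceeds `min_core_kme`
#'   (defaults 0.5 and 2).
#' @param merge_cut_height eigennode-dissimilarity threshold below which
#'   modules merge; default 0.5 (host) / 0.4 (microbe).
#' @param merge_cor merging correlation flavor, `"pearson"` (default) or
#'   `"bicor"`.
#' @param kme_cor correlation flavor for KME, `"bicor"` (default, matching the
#'   network) or `"pearson"`.
#' @return list of class `network_params`.
#' @export
network_params <- function(kingdom = c("host", "microbe"),
                           power = NULL,
                           candidate_powers = 1:30,
                           r2_cut = 0.85,
                           max_p_outliers = 0.05,
                           deep_split = 4L,
                           min_module_size = 2L,
                           min_kme_to_stay = 0.5,
                           min_core_kme = 0.5,
                           min_core_kme_size = 2L,
                           merge_cut_height = NULL,
                           merge_cor = c("pearson", "bicor"),
                           kme_cor = c("bicor", "pearson")) {
  kingdom <- match.arg(kingdom)
  if (is.null(merge_cut_height))
    merge_cut_height <- if (kingdom == "host") 0.5 else 0.4
  stopifnot(merge_cut_height > 0, merge_cut_height < 1,
            deep_split %in% 0:4,
            max_p_outliers >= 0, max_p_outliers <= 1,
            min_module_size >= 1, min_core_kme_size >= 1)
  structure(list(kingdom = kingdom, power = power,
                 candidate_powers = candidate_powers, r2_cut = r2_cut,
                 network_type = "signed", tom_type = "signed",
                 max_p_outliers = max_p_outliers,
                 deep_split = as.integer(deep_split),
                 min_module_size = as.integer(min_module_size),
                 min_kme_to_stay = min_kme_to_stay,
                 min_core_kme = min_core_kme,
                 min_core_kme_size = as.integer(min_core_kme_size),
                 merge_cut_height = merge_cut_height,
                 reassign_threshold = 0,
                 merge_cor = match.arg(merge_cor),
                 kme_cor = match.arg(kme_cor)),
            class = "network_params")
}
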