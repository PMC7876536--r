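#' Fulton-type condition factor
#'
#' Fish fatness index `CF = 10^N * W / L^3` with weight `W` in grams and
#' length `L` in millimeters; `N = 4` brings the output range close to 1 for
#' juvenile salmon.
#'
#' @param weight_g weight in grams (> 0).
#' @param length_mm length in millimeters (> 0).
#' @param N range constant (default 4).
#' @return numeric condition factor, vectorized over `weight_g`/`length_mm`.
#' @export
condition_factor <- function(weight_g, length_mm, N = 4) {
  if (any(weight_g <= 0, na.rm = TRUE) || any(length_mm <= 0, na.rm = TRUE))
    stop("weight and length must be positive")
  10^N * weight_g / length_mm^3
}

#' Encode host variables at the replicate-group level
#'
#' One row per replicate group (feed x water x day): `Day` (native integer
#' scale, treated as ordinal downstream), `WaterSW` (1 = salt water), a
#' one-hot encoding of the four feed levels (FO, VO, FOVO, VOFO), the
#' fraction of female fish (`Female_ratio`, unknown-sex fish excluded from the
#' denominator), and the group-mean condition factor. Rows are ordered by
#' feed, then water, then day — the integrated-heatmap column order.
#'
#' @param samples a validated sample table (see [make_sample_table()]).
#' @return numeric matrix (groups x traits) with attribute `spearman_traits`
#'   naming the ordinal columns (`"Day"`).
#' @export
encode_traits <- function(samples) {
  groups <- group_order(samples)
  traits <- c("Day", "WaterSW", FEED_LEVELS, "Female_ratio", "Condition_factor")
  out <- matrix(NA_real_, length(groups), length(traits),
                dimnames = list(groups, traits))
  for (g in groups) {
    rows <- samples[samples$group_id == g, ]
    out[g, "Day"] <- rows$day[1]
    out[g, "WaterSW"] <- as.numeric(rows$water[1] == "SW")
    out[g, FEED_LEVELS] <- as.numeric(FEED_LEVELS == as.character(rows$feed[1]))
    known <- rows$sex %in% c("M", "F")
    if (!any(known)) {
      warning("group ", g, " has no samples with known sex; Female_ratio missing")
      out[g, "Female_ratio"] <- NA_real_
    } else {
      out[g, "Female_ratio"] <- mean(rows$sex[known] == "F")
    }
    cf <- condition_factor(rows$weight_g, rows$length_mm)
    if (anyNA(cf)) warning("group ", g, ": fish with missing weight/length excluded from CF")
    out[g, "Condition_factor"] <- mean(cf, na.rm = TRUE)
  }
  attr(out, "spearman_traits") <- "Day"
  out
}

# deterministic group ordering: feed, then water, then day (ties by group id)
group_order <- function(samples) {
  u <- samples[!duplicated(samples$group_id), c("group_id", "feed", "water", "day")]
  u$group_id[order(as.integer(u$feed), as.integer(u$water), u$day, u$group_id)]
}

#' Average omics or eigennode columns within replicate groups
#'
#' Arithmetic mean of the sample columns belonging to each replicate group,
#' with group columns ordered by feed, then water, then day (the heatmap
#' ordering).
#'
#' @param x an `omics_matrix`, `eigennode_matrix`, or plain matrix with sample
#'   columns.
#' @param samples sample table covering every column of `x`.
#' @return matrix with one column per replicate group.
#' @export
average_replicates <- function(x, samples) {
  vals <- if (inherits(x, "omics_matrix") || inherits(x, "eigennode_matrix"))
    x$values else x
  missing_s <- setdiff(colnames(vals), samples$sample_id)
  if (length(missing_s))
    stop("samples absent from sample table: ", paste(missing_s, collapse = ", "))
  sub <- samples[samples$sample_id %in% colnames(vals), ]
  groups <- group_order(sub)
  out <- vapply(groups, function(g) {
    ids <- sub$sample_id[sub$group_id == g]
    rowMeans(vals[, ids, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(vals), groups))
  out
}
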