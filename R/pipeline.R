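#' Default pipeline configuration
#'
#' Assembles the full-method configuration with the canonical defaults:
#' host counts are TMM-normalized and filtered (max expression >= 1.0,
#' sd >= 0.15), OTU counts abundance-filtered (>= 0.005% of total) then
#' CSS-normalized; networks are signed/signed-TOM with bicor
#' (maxPOutliers 0.05), deepSplit 4, minModuleSize 2, minKMEtoStay 0.5,
#' minCoreKME 0.5 with core size 2, no reassignment, and merge cut height
#' 0.5 (host) / 0.4 (microbe); correction of large latent effects is off by
#' default.
#'
#' @param host_counts,microbe_counts,samples input paths (TSV) or in-memory
#'   objects (`omics_matrix` / sample table).
#' @param annotation optional annotation path or map for enrichment.
#' @param out_dir output directory.
#' @param correct logical: estimate and regress out large latent effects
#'   before network inference.
#' @param correct_B,correct_alpha permutation count and level for the latent
#'   estimate.
#' @param drop_samples sample ids to drop up front (e.g. known outliers).
#' @param apply_outlier_filter logical: drop samples flagged by
#'   [detect_outlier_samples()] (flags are always logged).
#' @param host_params,microbe_params [network_params()] per kingdom.
#' @param row_rule,alpha iHAHI row-selection rule and level.
#' @param seed seed for the (only) stochastic stage, the latent-effect
#'   permutation estimate.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(host_counts, microbe_counts, samples,
                            annotation = NULL, out_dir = "holonet_run",
                            correct = FALSE, correct_B = 100L,
                            correct_alpha = 0.05,
                            drop_samples = character(0),
                            apply_outlier_filter = FALSE,
                            host_params = network_params("host"),
                            microbe_params = network_params("microbe"),
                            row_rule = "significant", alpha = 0.05,
                            seed = 1L) {
  structure(list(host_counts = host_counts, microbe_counts = microbe_counts,
                 samples = samples, annotation = annotation, out_dir = out_dir,
                 correct = correct, correct_B = as.integer(correct_B),
                 correct_alpha = correct_alpha, drop_samples = drop_samples,
                 apply_outlier_filter = apply_outlier_filter,
                 host_params = host_params, microbe_params = microbe_params,
                 row_rule = row_rule, alpha = alpha, seed = seed),
            class = "pipeline_config")
}

#' Run the full transkingdom pipeline
#'
#' Executes, in order: read/validate inputs, preprocess both kingdoms
#' (normalize, filter, flag outliers), optional large-effect correction,
#' network inference per kingdom, trait encoding, the integrated heatmap
#' analysis, and (when an annotation is supplied) per-module term enrichment.
#' Every artifact is written as TSV under `out_dir` together with a
#' `manifest.json` recording stages, parameters, seed and input hashes.
#' Reruns with an identical config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`host_net`,
#'   `microbe_net`, `traits`, `ihahi`, `enrichment`, `n_sv`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  # abort with the failing stage's name; keep partial outputs under failed/
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(config$out_dir, "failed"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  as_omics <- function(x, kingdom) {
    if (inherits(x, "omics_matrix")) x
    else read_omics_table(x, kingdom = kingdom)
  }
  host <- stage("read_inputs", as_omics(config$host_counts, "host"))
  microbe <- stage("read_inputs", as_omics(config$microbe_counts, "microbe"))
  samples <- stage("read_inputs",
                   if (is.data.frame(config$samples)) make_sample_table(config$samples)
                   else read_sample_table(config$samples))
  stages <- c(stages, "read_inputs")

  drop <- config$drop_samples
  if (config$apply_outlier_filter) {
    drop <- union(drop, c(detect_outlier_samples(host),
                          detect_outlier_samples(microbe)))
  }
  if (length(drop)) {
    message("dropping samples: ", paste(drop, collapse = ", "))
    host <- subset_omics(host, samples = setdiff(sample_ids(host), drop))
    microbe <- subset_omics(microbe, samples = setdiff(sample_ids(microbe), drop))
  }

  host_norm <- stage("preprocess", tmm_normalize(host))
  host_filt <- stage("preprocess", filter_genes(host_norm$matrix))
  otu_filt <- stage("preprocess", filter_otus(microbe))
  microbe_norm <- stage("preprocess", css_normalize(otu_filt$matrix))
  write_omics_table(host_filt$matrix, file.path(config$out_dir, "host_normalized.tsv"))
  write_omics_table(microbe_norm$matrix,
                    file.path(config$out_dir, "microbe_normalized.tsv"))
  stages <- c(stages, "preprocess")

  host_mat <- host_filt$matrix
  microbe_mat <- microbe_norm$matrix
  n_sv <- list(host = NA_integer_, microbe = NA_integer_)
  if (config$correct) {
    for (kingdom in c("host", "microbe")) {
      m <- if (kingdom == "host") host_mat else microbe_mat
      est <- stage("correct_large_effects",
                   estimate_num_sv(m, B = config$correct_B,
                                   alpha = config$correct_alpha,
                                   seed = config$seed))
      n_sv[[kingdom]] <- est$n_sv
      if (est$n_sv > 0) m <- remove_latent_pcs(m, est$n_sv)
      if (kingdom == "host") host_mat <- m else microbe_mat <- m
    }
    stages <- c(stages, "correct_large_effects")
  }

  host_net <- stage("network_host", infer_network(host_mat, config$host_params))
  microbe_net <- stage("network_microbe",
                       infer_network(microbe_mat, config$microbe_params))
  for (kingdom in c("host", "microbe")) {
    net <- if (kingdom == "host") host_net else microbe_net
    write_module_assignments(net$partition, net$kme, net$connectivity,
                             file.path(config$out_dir, paste0(kingdom, "_modules.tsv")))
    if (!is.null(net$eigennodes)) {
      em <- net$eigennodes$values
      df <- data.frame(module = rownames(em), em, check.names = FALSE)
      utils::write.table(format_numeric_df(df),
                         file.path(config$out_dir, paste0(kingdom, "_eigennodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(net$fit_table))
      utils::write.table(format_numeric_df(net$fit_table),
                         file.path(config$out_dir, paste0(kingdom, "_power_fit.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "network_host", "network_microbe")

  traits <- stage("traits", encode_traits(samples))
  tdf <- data.frame(group_id = rownames(traits), traits, check.names = FALSE)
  utils::write.table(format_numeric_df(tdf),
                     file.path(config$out_dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "traits")

  ihahi <- NULL
  if (!is.null(host_net$eigennodes) && !is.null(microbe_net$eigennodes)) {
    ihahi <- stage("ihahi",
                   build_ihahi(host_net$eigennodes, microbe_net$eigennodes, traits,
                               samples, row_rule = config$row_rule,
                               alpha = config$alpha))
    write_ihahi(ihahi, file.path(config$out_dir, "ihahi"))
  }
  stages <- c(stages, "ihahi")

  enrich <- NULL
  if (!is.null(config$annotation)) {
    ann <- if (is.character(config$annotation)) read_annotation_map(config$annotation)
           else config$annotation
    universe <- names(host_net$partition)
    mods <- setdiff(sort(unique(host_net$partition)), 0L)
    enrich <- lapply(mods, function(m) {
      genes <- names(host_net$partition)[host_net$partition == m]
      res <- hypergeometric_enrichment(genes, ann, universe)
      if (nrow(res)) cbind(module = m, res) else NULL
    })
    enrich <- do.call(rbind, enrich[!vapply(enrich, is.null, logical(1))])
    if (!is.null(enrich))
      utils::write.table(format_numeric_df(enrich),
                         file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    stages <- c(stages, "enrichment")
  }

  manifest <- list(
    package = "holonet",
    version = as.character(utils::packageVersion("holonet")),
    stages = stages,
    seed = config$seed,
    n_sv = n_sv,
    host_power = host_net$power,
    microbe_power = microbe_net$power,
    params = list(host = unclass(config$host_params),
                  microbe = unclass(config$microbe_params),
                  correct = config$correct, row_rule = config$row_rule,
                  alpha = config$alpha),
    input_hashes = input_hashes(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(list(host_net = host_net, microbe_net = microbe_net,
                 traits = traits, ihahi = ihahi, enrichment = enrich,
                 n_sv = n_sv, out_dir = config$out_dir,
                 host_filter = host_filt$report, otu_filter = otu_filt$report))
}

input_hashes <- function(config) {
  h <- list()
  for (nm in c("host_counts", "microbe_counts", "samples", "annotation")) {
    x <- config[[nm]]
    if (is.character(x) && length(x) == 1L && file.exists(x))
      h[[nm]] <- unname(tools::md5sum(x))
  }
  h
}

#' Read a pipeline configuration from YAML
#'
#' Thin front end for the command-line runner: maps a flat YAML document onto
#' [pipeline_config()] and [network_params()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  np <- function(kingdom) {
    args <- y[[paste0(kingdom, "_params")]] %||% list()
    do.call(network_params, c(list(kingdom = kingdom), args))
  }
  pipeline_config(
    host_counts = y$host_counts, microbe_counts = y$microbe_counts,
    samples = y$samples, annotation = y$annotation,
    out_dir = y$out_dir %||% "holonet_run",
    correct = isTRUE(y$correct), correct_B = y$correct_B %||% 100L,
    correct_alpha = y$correct_alpha %||% 0.05,
    drop_samples = unlist(y$drop_samples) %||% character(0),
    apply_outlier_filter = isTRUE(y$apply_outlier_filter),
    host_params = np("host"), microbe_params = np("microbe"),
    row_rule = y$row_rule %||% "significant", alpha = y$alpha %||% 0.05,
    seed = y$seed %||% 1L)
}
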