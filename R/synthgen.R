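#' Configuration for the synthetic holobiont generator
#'
#' Describes a matched host/microbe count dataset with planted co-abundance
#' modules, planted cross-kingdom couplings and trait-driven large effects.
#' The default design mirrors a diet-switch feeding trial crossing four feeds
#' with two water types over several sampling days.
#'
#' @param feeds,waters,days,replicates the sample-group design; every
#'   feed x water x day cell gets `replicates` fish.
#' @param n_genes,host_module_sizes host feature count and planted module
#'   sizes (remaining genes are unstructured noise).
#' @param n_otus,microbe_module_sizes microbiota analogues.
#' @param within_r target within-module correlation of the latent profiles
#'   (default 0.8).
#' @param lib_sdlog log-normal spread of host library-size factors
#'   (default 0.3).
#' @param host_log_mu_range range of host gene log mean counts.
#' @param otu_log_mu_range range of OTU log mean counts.
#' @param nb_dispersion negative-binomial dispersion of OTU counts
#'   (default 0.3; variance mu + dispersion * mu^2).
#' @param zero_inflation extra Bernoulli dropout rate for OTU counts
#'   (default 0.10); with the default abundance range, structural
#'   negative-binomial zeros are rare, so the marginal zero fraction tracks
#'   this rate.
#' @param bio_sd host biological log-scale effect size scaling the latent
#'   profile into log mean counts (default 0.8).
#' @param microbe_bio_sd microbiota analogue of `bio_sd` (default 1.5; taxa
#'   abundances swing over orders of magnitude).
#' @param couplings list of `list(host = i, microbe = j, r = rho)` entries:
#'   host module i and microbe module j share a latent component realizing
#'   correlation `rho` between their factors.
#' @param large_effects list of `list(trait, host_modules, microbe_modules,
#'   effect)` entries; `trait` is currently `"WaterSW"`, and `effect` shifts
#'   the affected module factors by that many latent standard deviations
#'   between the two water types.
#' @param seed mandatory RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(feeds = FEED_LEVELS,
                         waters = WATER_LEVELS,
                         days = c(1L, 2L, 5L, 9L, 13L, 16L, 20L),
                         replicates = 1L,
                         n_genes = 300L,
                         host_module_sizes = c(40L, 30L, 25L, 20L, 15L),
                         n_otus = 60L,
                         microbe_module_sizes = c(15L, 12L, 10L),
                         within_r = 0.8,
                         lib_sdlog = 0.3,
                         host_log_mu_range = c(3, 6),
                         otu_log_mu_range = c(5, 7),
                         nb_dispersion = 0.3,
                         zero_inflation = 0.10,
                         bio_sd = 0.8,
                         microbe_bio_sd = 1.5,
                         couplings = list(list(host = 1L, microbe = 1L, r = 0.8),
                                          list(host = 2L, microbe = 2L, r = 0.8)),
                         large_effects = list(),
                         seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (sum(host_module_sizes) > n_genes) stop("host module sizes exceed n_genes")
  if (sum(microbe_module_sizes) > n_otus) stop("microbe module sizes exceed n_otus")
  for (cp in couplings) {
    if (abs(cp$r) >= 1) stop("coupling |r| must be < 1")
    if (cp$host > length(host_module_sizes) || cp$microbe > length(microbe_module_sizes))
      stop("coupling references a non-existent module")
  }
  if (abs(within_r) >= 1) stop("'within_r' must be < 1 in absolute value")
  structure(list(feeds = feeds, waters = waters, days = as.integer(days),
                 replicates = as.integer(replicates),
                 n_genes = as.integer(n_genes),
                 host_module_sizes = as.integer(host_module_sizes),
                 n_otus = as.integer(n_otus),
                 microbe_module_sizes = as.integer(microbe_module_sizes),
                 within_r = within_r, lib_sdlog = lib_sdlog,
                 host_log_mu_range = host_log_mu_range,
                 otu_log_mu_range = otu_log_mu_range,
                 nb_dispersion = nb_dispersion,
                 zero_inflation = zero_inflation, bio_sd = bio_sd,
                 microbe_bio_sd = microbe_bio_sd,
                 couplings = couplings, large_effects = large_effects,
                 seed = seed),
            class = "synth_config")
}

#' Generate a matched synthetic holobiont dataset
#'
#' Draws one latent factor per planted module (standard normal over samples,
#' plus any configured trait effect), gives each member feature the profile
#' `sqrt(r) * factor + sqrt(1 - r) * noise` so member pairs correlate at the
#' configured within-module level, couples designated host/microbe module
#' pairs through a shared latent component realizing the configured
#' cross-kingdom correlation, and maps latent profiles to counts: Poisson
#' with log-normal gene means and log-normal library-size factors for the
#' host, negative binomial with configurable dispersion plus Bernoulli
#' zero-inflation for the microbiota. Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return list: `host` and `microbe` (`omics_matrix` raw counts), `samples`
#'   (sample table), `truth` (module labels per kingdom, latent factor
#'   matrices, realized coupling correlations, per-sample trait values).
#' @export
generate_holobiont <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_holobiont_impl(config))
}

generate_holobiont_impl <- function(cfg) {
  design <- expand.grid(replicate = seq_len(cfg$replicates), day = cfg$days,
                        water = cfg$waters, feed = cfg$feeds,
                        stringsAsFactors = FALSE)
  n <- nrow(design)
  sample_id <- sprintf("G_%s_D%d_%s_%d", design$water, design$day,
                       design$feed, design$replicate)
  # fish grow over the trial; weight ~ cubic in length keeps CF near 1
  length_mm <- round(stats::rnorm(n, 120 + 2.5 * design$day, 6), 1)
  weight_g <- round(1.05e-4 * length_mm^3 * exp(stats::rnorm(n, 0, 0.05)), 1)
  samples <- make_sample_table(data.frame(
    sample_id = sample_id, day = design$day, water = design$water,
    feed = design$feed, sex = sample(c("M", "F"), n, replace = TRUE),
    weight_g = weight_g, length_mm = length_mm, stringsAsFactors = FALSE))

  water_sw <- as.numeric(design$water == "SW")
  trait_vectors <- list(WaterSW = water_sw)

  factors_for <- function(sizes, kingdom) {
    k <- length(sizes)
    f <- matrix(stats::rnorm(k * n), k, n)
    rownames(f) <- paste0(if (kingdom == "host") "hM" else "mM", seq_len(k))
    f
  }
  host_f <- factors_for(cfg$host_module_sizes, "host")
  microbe_f <- factors_for(cfg$microbe_module_sizes, "microbe")

  # couple module pairs through a shared component: f = sqrt(r)*c + sqrt(1-r)*e
  for (cp in cfg$couplings) {
    shared <- stats::rnorm(n)
    r <- cp$r
    host_f[cp$host, ] <- sqrt(abs(r)) * shared +
      sqrt(1 - abs(r)) * stats::rnorm(n)
    microbe_f[cp$microbe, ] <- sign(r) * sqrt(abs(r)) * shared +
      sqrt(1 - abs(r)) * stats::rnorm(n)
  }

  # additive trait effects on latent factors (in latent sd units)
  for (ef in cfg$large_effects) {
    tv <- trait_vectors[[ef$trait]]
    if (is.null(tv)) stop("unknown large-effect trait: ", ef$trait)
    tvc <- (tv - mean(tv)) / stats::sd(tv)
    for (m in ef$host_modules %||% integer(0))
      host_f[m, ] <- host_f[m, ] + ef$effect * tvc
    for (m in ef$microbe_modules %||% integer(0))
      microbe_f[m, ] <- microbe_f[m, ] + ef$effect * tvc
  }

  latent_profiles <- function(n_feat, sizes, f, prefix) {
    labels <- integer(n_feat)
    z <- matrix(stats::rnorm(n_feat * n), n_feat, n)
    pos <- 1L
    for (m in seq_along(sizes)) {
      idx <- pos:(pos + sizes[m] - 1L)
      fm <- (f[m, ] - mean(f[m, ])) / stats::sd(f[m, ])
      z[idx, ] <- sqrt(cfg$within_r) * matrix(fm, sizes[m], n, byrow = TRUE) +
        sqrt(1 - cfg$within_r) * z[idx, , drop = FALSE]
      labels[idx] <- m
      pos <- pos + sizes[m]
    }
    rownames(z) <- paste0(prefix, seq_len(n_feat))
    names(labels) <- rownames(z)
    list(z = z, labels = labels)
  }
  host_lat <- latent_profiles(cfg$n_genes, cfg$host_module_sizes, host_f, "gene")
  microbe_lat <- latent_profiles(cfg$n_otus, cfg$microbe_module_sizes, microbe_f, "otu")

  lib <- exp(stats::rnorm(n, 0, cfg$lib_sdlog))
  host_mu0 <- exp(stats::runif(cfg$n_genes, cfg$host_log_mu_range[1],
                               cfg$host_log_mu_range[2]))
  host_mu <- host_mu0 * exp(cfg$bio_sd * host_lat$z - cfg$bio_sd^2 / 2)
  host_mu <- sweep(host_mu, 2L, lib, "*")
  host_counts <- matrix(stats::rpois(length(host_mu), host_mu),
                        nrow(host_mu), dimnames = list(rownames(host_lat$z), sample_id))

  otu_mu0 <- exp(stats::runif(cfg$n_otus, cfg$otu_log_mu_range[1],
                              cfg$otu_log_mu_range[2]))
  otu_mu <- otu_mu0 * exp(cfg$microbe_bio_sd * microbe_lat$z - cfg$microbe_bio_sd^2 / 2)
  otu_lib <- exp(stats::rnorm(n, 0, cfg$lib_sdlog))
  otu_mu <- sweep(otu_mu, 2L, otu_lib, "*")
  otu_counts <- matrix(stats::rnbinom(length(otu_mu), mu = otu_mu,
                                      size = 1 / cfg$nb_dispersion),
                       nrow(otu_mu), dimnames = list(rownames(microbe_lat$z), sample_id))
  if (cfg$zero_inflation > 0) {
    keep <- matrix(stats::rbinom(length(otu_counts), 1L, 1 - cfg$zero_inflation),
                   nrow(otu_counts))
    otu_counts <- otu_counts * keep
  }

  realized <- lapply(cfg$couplings, function(cp) {
    list(host = cp$host, microbe = cp$microbe, target_r = cp$r,
         realized_r = stats::cor(host_f[cp$host, ], microbe_f[cp$microbe, ]))
  })

  list(host = omics_matrix(host_counts, "host", "raw_counts"),
       microbe = omics_matrix(otu_counts, "microbe", "raw_counts"),
       samples = samples,
       truth = list(host_labels = host_lat$labels,
                    microbe_labels = microbe_lat$labels,
                    host_factors = host_f, microbe_factors = microbe_f,
                    couplings = realized,
                    trait_vectors = trait_vectors,
                    host_lib_factors = lib))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundled deterministic small fixture
#'
#' A fixed-seed synthetic holobiont dataset used throughout the tests and
#' documentation: 300 genes (5 planted modules of 40/30/25/20/15), 60 OTUs
#' (3 planted modules of 15/12/10), 56 samples in a 4 feeds x 2 waters x
#' 7 days design with one fish per cell, two planted cross-kingdom couplings
#' at r = 0.8, and a salt-water large effect on host module 1 and microbe
#' module 1.
#'
#' @return the [generate_holobiont()] bundle for the fixed fixture config.
#' @export
fixture_small <- function() {
  cfg <- synth_config(
    large_effects = list(list(trait = "WaterSW", host_modules = 1L,
                              microbe_modules = 1L, effect = 2)),
    seed = 20260401)
  generate_holobiont(cfg)
}
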