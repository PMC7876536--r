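test_that("signed adjacency closed forms and range contracts hold", {
  cm <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(unname(signed_adjacency(cm, 7)$values), matrix(1, 2, 2))
  cm2 <- matrix(c(1, -1, -1, 1), 2)
  expect_equal(signed_adjacency(cm2, 3)$values[1, 2], 0)
  cm3 <- matrix(c(1, 0, 0, 1), 2)
  expect_equal(signed_adjacency(cm3, 2)$values[1, 2], 0.25)
  expect_error(signed_adjacency(cm3, 0), "positive")

  for (s in 1:20) {
    cm <- random_corr(15, s)
    a <- signed_adjacency(cm, sample(1:20, 1))$values
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(a, t(a))
    expect_equal(unname(diag(a)), rep(1, 15))
  }
})

test_that("signed TOM matches the triple-loop oracle and saturates on cliques", {
  clique <- matrix(1, 3, 3)
  expect_equal(unname(signed_tom(clique)$values), matrix(1, 3, 3))

  empty <- diag(4)
  tom0 <- signed_tom(empty)$values
  expect_equal(unname(tom0), diag(4))

  set.seed(41)
  a <- matrix(runif(64), 8); a <- (a + t(a)) / 2; diag(a) <- 1
  dimnames(a) <- list(paste0("n", 1:8), paste0("n", 1:8))
  expect_equal(unname(signed_tom(a)$values), unname(ref_tom(a)), tolerance = 1e-12)

  expect_error(signed_tom(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")

  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:15, 1)
    a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 1
    tom <- signed_tom(a)$values
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
  }
})

test_that("soft threshold selection honors the cut, fallback and forced-choice contracts", {
  cm <- random_corr(40, 42)
  one <- pick_soft_threshold(cm, candidate_powers = 6)
  expect_identical(one$power, 6)
  expect_identical(nrow(one$fit_table), 1L)

  # impossible cut forces the argmax fallback with its flag
  fb <- pick_soft_threshold(cm, candidate_powers = c(2, 4, 8), r2_cut = 1.01)
  expect_identical(fb$flag, "no_power_reached_cut")
  expect_identical(fb$power, fb$fit_table$power[which.max(fb$fit_table$fit)])

  expect_error(pick_soft_threshold(cm, candidate_powers = numeric(0)), "empty")

  # procedure oracle: independent re-implementation of bin-and-regress
  ref_fit <- function(adj, n_bins = 10) {
    k <- rowSums(adj) - 1
    k <- k[k > 0]
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks, include.lowest = TRUE)
    freq <- as.vector(table(bin))
    mk <- tapply(k, bin, mean)
    keep <- freq > 0 & !is.na(mk) & mk > 0
    fit <- lm(log10(freq[keep]) ~ log10(mk[keep]))
    unname(summary(fit)$r.squared * sign(-coef(fit)[2]))
  }
  set.seed(43)
  # planted hub structure: a few dense blocks on a noise background
  z <- matrix(rnorm(300 * 30), 300)
  for (b in 0:4) {
    f <- rnorm(30)
    idx <- (b * 40 + 1):(b * 40 + 40)
    z[idx, ] <- sqrt(0.7) * matrix(f, 40, 30, byrow = TRUE) + sqrt(0.3) * z[idx, ]
  }
  cm_hub <- cor(t(z))
  dimnames(cm_hub) <- list(paste0("f", 1:300), paste0("f", 1:300))
  cand <- c(2, 4, 6, 9, 12, 16, 20)
  got <- pick_soft_threshold(cm_hub, cand, r2_cut = 0.85)
  fits <- vapply(cand, function(b) ref_fit(((1 + cm_hub) / 2)^b), numeric(1))
  ok <- which(fits >= 0.85)
  expected_power <- if (length(ok)) cand[ok[1]] else cand[which.max(fits)]
  expect_identical(got$power, expected_power)
  expect_equal(got$fit_table$fit, fits, tolerance = 1e-9)
})

test_that("module detection recovers planted blocks and respects min size", {
  set.seed(44)
  n1 <- 12; n2 <- 10
  d <- matrix(runif((n1 + n2)^2, 0.85, 0.95), n1 + n2)
  d[1:n1, 1:n1] <- runif(n1^2, 0.02, 0.08)
  d[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- runif(n2^2, 0.02, 0.08)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("n", 1:(n1 + n2)), paste0("n", 1:(n1 + n2)))
  part <- detect_modules(d, network_params("host"))
  truth <- rep(1:2, c(n1, n2))
  expect_identical(length(setdiff(unique(part), 0L)), 2L)
  expect_equal(ref_ari(truth, part), 1)
  # labels ordered by decreasing size
  expect_identical(sum(part == 1L), as.integer(n1))

  single <- matrix(0, 1, 1, dimnames = list("n1", "n1"))
  expect_identical(unname(detect_modules(single, network_params("host"))[1]), 0L)
})

test_that("deeper deep_split never yields fewer modules on co-abundance instances", {
  # instance class of interest: planted co-abundance modules over a noise
  # background, as produced by real count data after TOM transformation
  for (s in 1:20) {
    sim <- generate_holobiont(synth_config(
      n_genes = 100L, host_module_sizes = c(20L, 15L, 12L), couplings = list(),
      seed = s + 400))
    hnorm <- filter_genes(tmm_normalize(sim$host)$matrix)$matrix
    cm <- correlation_matrix(hnorm, network_params("host"))
    d <- 1 - signed_tom(signed_adjacency(cm, 12))$values
    count <- function(ds) {
      p <- detect_modules(d, network_params("host", deep_split = ds))
      length(setdiff(unique(p), 0L))
    }
    expect_gte(count(4), count(1))
  }
})

test_that("eigennodes are standardized, oriented, and match a direct eigendecomposition", {
  # rank-1 module of identical profiles
  prof <- c(2, 4, 1, 7, 3, 5)
  x <- rbind(a = prof, b = prof, c = prof)
  colnames(x) <- paste0("s", 1:6)
  m <- omics_matrix(x, "host", "normalized_log2")
  part <- structure(setNames(c(1L, 1L, 1L), rownames(x)), class = "module_partition")
  en <- module_eigennode(m, part)
  std <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(en$values["hME1", ]), unname(std), tolerance = 1e-10)
  expect_equal(unname(en$var_explained["hME1"]), 1)

  # 2-member module equals the closed-form leading principal direction
  # (positively correlated members, so the orientation rule is well defined)
  set.seed(45)
  common <- rnorm(10)
  x2 <- rbind(a = common + 0.5 * rnorm(10), b = common + 0.5 * rnorm(10))
  colnames(x2) <- paste0("s", 1:10)
  m2 <- omics_matrix(x2, "host", "normalized_log2")
  part2 <- structure(setNames(c(1L, 1L), c("a", "b")), class = "module_partition")
  en2 <- module_eigennode(m2, part2)
  xs <- t(scale(t(x2)))
  eig <- eigen(t(xs) %*% xs)
  v1 <- eig$vectors[, 1]
  v1 <- (v1 - mean(v1)) / sd(v1)
  if (cor(v1, colMeans(xs)) < 0) v1 <- -v1
  expect_equal(unname(en2$values["hME1", ]), unname(v1), tolerance = 1e-8)
  expect_equal(unname(en2$var_explained["hME1"]),
               eig$values[1] / sum(eig$values), tolerance = 1e-8)

  # flipping every member flips the mean profile, so the oriented eigennode
  # flips with it; the correlation structure is exactly preserved
  en_flip <- module_eigennode(omics_matrix(-x2, "host", "normalized_log2"), part2)
  expect_equal(en_flip$values, -en2$values, tolerance = 1e-8)

  # eigennode rows are standardized
  expect_equal(mean(en2$values[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(en2$values[1, ]), 1, tolerance = 1e-12)
})

test_that("KME equals looped correlations and hits its exact endpoints", {
  m <- random_omics(30, 15, 46)
  part <- structure(setNames(rep(c(1L, 2L, 0L), c(10, 10, 10)), feature_ids(m)),
                    class = "module_partition")
  en <- module_eigennode(m, part)
  km <- kme(m, en)
  for (i in seq_len(30)) for (j in 1:2) {
    expect_equal(km[i, j],
                 suppressWarnings(bicor(m$values[i, ], en$values[j, ])),
                 tolerance = 1e-10)
  }
  expect_true(all(km >= -1 & km <= 1))

  # a rank-1 module member has KME 1; its negation has KME -1
  prof <- c(5, 1, 4, 2, 8, 3)
  x <- rbind(a = prof, b = prof, neg = -prof)
  colnames(x) <- paste0("s", 1:6)
  mm <- omics_matrix(x, "host", "normalized_log2")
  p1 <- structure(setNames(c(1L, 1L, 0L), rownames(x)), class = "module_partition")
  km1 <- kme(mm, module_eigennode(mm, p1))
  expect_equal(km1["a", "ME1"], 1, tolerance = 1e-10)
  expect_equal(km1["neg", "ME1"], -1, tolerance = 1e-10)
})

test_that("trimming enforces membership and core rules exactly", {
  nodes <- paste0("n", 1:6)
  part <- structure(setNames(c(1L, 1L, 1L, 2L, 2L, 0L), nodes),
                    class = "module_partition")
  km <- matrix(0, 6, 2, dimnames = list(nodes, c("ME1", "ME2")))
  km[, "ME1"] <- c(0.9, 0.9, 0.3, 0, 0, 0)
  km[, "ME2"] <- c(0, 0, 0, 0.45, 0.40, 0)
  class(km) <- c("kme_table", "matrix", "array")
  p <- network_params("host")
  out <- trim_modules(part, km, p)
  # n3 trimmed but module 1 survives on its 2-node core
  expect_identical(unname(out["n3"]), 0L)
  expect_identical(unname(out["n1"]), unname(out["n2"]))
  expect_true(out["n1"] > 0L)
  # module 2 lacks a core above 0.5 and dissolves entirely
  expect_identical(unname(out["n4"]), 0L)
  expect_identical(unname(out["n5"]), 0L)

  # all-strong module is untouched
  km2 <- km; km2[, "ME1"] <- c(0.9, 0.9, 0.9, 0, 0, 0)
  class(km2) <- class(km)
  out2 <- trim_modules(part, km2, p)
  expect_identical(unname(out2[c("n1", "n2", "n3")]), c(1L, 1L, 1L))
})

test_that("module merging joins correlated eigennodes and converges", {
  set.seed(47)
  n <- 40
  driver <- rnorm(n)
  mk_mod <- function(f, size) {
    t(sapply(seq_len(size), function(i) sqrt(0.9) * f + sqrt(0.1) * rnorm(n)))
  }
  # modules 1 and 2 share a latent driver (eigennode cor ~ 0.8); 3 and 4 independent
  f1 <- sqrt(0.8) * driver + sqrt(0.2) * rnorm(n)
  f2 <- sqrt(0.8) * driver + sqrt(0.2) * rnorm(n)
  f3 <- rnorm(n); f4 <- rnorm(n)
  x <- rbind(mk_mod(f1, 6), mk_mod(f2, 6), mk_mod(f3, 6), mk_mod(f4, 6))
  dimnames(x) <- list(paste0("g", 1:24), paste0("s", 1:n))
  m <- omics_matrix(x, "host", "normalized_log2")
  part <- structure(setNames(rep(1:4, each = 6L), rownames(x)),
                    class = "module_partition")
  res <- merge_modules(m, part, network_params("host", merge_cut_height = 0.4))
  lab <- res$partition
  expect_identical(length(setdiff(unique(lab), 0L)), 3L)
  expect_identical(unname(lab["g1"]), unname(lab["g7"]))    # 1 and 2 merged
  expect_false(lab["g13"] == lab["g19"])                    # 3 and 4 distinct
  # convergence: no remaining eigennode pair within the merge radius
  d <- 1 - cor(t(res$eigennodes$values))
  expect_true(all(d[upper.tri(d)] >= 0.4))

  # identical eigennodes always merge
  x2 <- rbind(mk_mod(f3, 4), mk_mod(f3, 4))
  dimnames(x2) <- list(paste0("h", 1:8), paste0("s", 1:n))
  m2 <- omics_matrix(x2, "host", "normalized_log2")
  p2 <- structure(setNames(rep(1:2, each = 4L), rownames(x2)),
                  class = "module_partition")
  expect_identical(length(setdiff(unique(merge_modules(m2, p2)$partition), 0L)), 1L)

  # anti-correlated modules never merge in a signed analysis
  x3 <- rbind(mk_mod(f3, 4), mk_mod(-f3, 4))
  dimnames(x3) <- list(paste0("k", 1:8), paste0("s", 1:n))
  m3 <- omics_matrix(x3, "host", "normalized_log2")
  p3 <- structure(setNames(rep(1:2, each = 4L), rownames(x3)),
                  class = "module_partition")
  res3 <- merge_modules(m3, p3, network_params("host", merge_cut_height = 0.5))
  expect_identical(length(setdiff(unique(res3$partition), 0L)), 2L)
})

test_that("intramodular connectivity matches loop sums and its identities", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("n", 1:3), paste0("n", 1:3))
  part <- structure(setNames(rep(1L, 3), rownames(a)), class = "module_partition")
  ct <- intramodular_connectivity(structure(list(values = a, beta = 1),
                                            class = "adjacency_matrix"), part)
  expect_equal(ct$kTotal, rep(1, 3))
  expect_equal(ct$kWithin, rep(1, 3))
  expect_equal(ct$kOut, rep(0, 3))
  expect_equal(ct$kDiff, rep(1, 3))

  set.seed(48)
  a2 <- matrix(runif(144), 12); a2 <- (a2 + t(a2)) / 2; diag(a2) <- 1
  dimnames(a2) <- list(paste0("n", 1:12), paste0("n", 1:12))
  lab <- setNames(c(rep(1L, 5), rep(2L, 4), rep(0L, 3)), rownames(a2))
  part2 <- structure(lab, class = "module_partition")
  ct2 <- intramodular_connectivity(structure(list(values = a2, beta = 1),
                                             class = "adjacency_matrix"), part2)
  ref <- ref_connectivity(a2, lab)
  expect_equal(as.matrix(ct2), ref, tolerance = 1e-12)
  expect_equal(ct2$kWithin + ct2$kOut, ct2$kTotal)
  expect_equal(ct2$kDiff, ct2$kWithin - ct2$kOut)
  # grey nodes have zero within-module connectivity
  expect_equal(ct2["n12", "kWithin"], 0)
  expect_equal(ct2["n12", "kOut"], ct2["n12", "kTotal"])
})

test_that("full network inference is deterministic and recovers planted modules", {
  sim <- generate_holobiont(synth_config(n_genes = 150L,
                                         host_module_sizes = c(30L, 25L, 20L),
                                         couplings = list(), seed = 49))
  hnorm <- filter_genes(tmm_normalize(sim$host)$matrix)$matrix
  net1 <- infer_network(hnorm, network_params("host"))
  net2 <- infer_network(hnorm, network_params("host"))
  expect_identical(net1$partition, net2$partition)
  expect_identical(net1$eigennodes$values, net2$eigennodes$values)
  expect_identical(net1$power, net2$power)
  expect_gte(ref_ari(sim$truth$host_labels[names(net1$partition)], net1$partition),
             0.85)
  # every surviving member satisfies the membership bound (merge can relax it,
  # but on cleanly separated planted modules it should hold)
  lab <- net1$partition
  for (mname in rownames(net1$eigennodes$values)) {
    k <- as.integer(sub("hME", "", mname))
    members <- names(lab)[lab == k]
    expect_true(all(net1$kme[members, paste0("ME", k)] > 0.3))
  }
})
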