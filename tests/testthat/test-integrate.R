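grp <- function(n) paste0("g", seq_len(n))

test_that("group correlation hits exact endpoints and the t-tail oracle", {
  n <- 12
  set.seed(61)
  v <- rnorm(n)
  x <- matrix(v, 1, dimnames = list("row1", grp(n)))
  y <- cbind(same = v)
  rownames(y) <- grp(n)
  res <- correlate_groups(x, y)
  expect_equal(res$r[1, 1], 1)
  expect_lt(res$p[1, 1], 1e-100)
  expect_true(res$flag[1, 1])              # degenerate-p flag at |r| = 1
  expect_gt(res$p[1, 1], 0)                # never exactly zero

  # centered orthogonal pair: r = 0, t = 0, p = 1
  a <- c(1, -1, 1, -1, 1, -1)
  b <- c(1, 0, -1, 1, 0, -1)
  stopifnot(sum(a * b) == 0, sum(a) == 0, sum(b) == 0)
  xo <- matrix(a, 1, dimnames = list("row1", grp(6)))
  yo <- cbind(orth = b); rownames(yo) <- grp(6)
  reso <- correlate_groups(xo, yo)
  expect_equal(reso$r[1, 1], 0)
  expect_equal(reso$p[1, 1], 1)

  # random pairs match the two-sided t-tail formula and cor.test
  for (i in 1:20) {
    xr <- matrix(rnorm(n), 1, dimnames = list("row1", grp(n)))
    yr <- cbind(v = rnorm(n)); rownames(yr) <- grp(n)
    res <- correlate_groups(xr, yr)
    expect_equal(res$p[1, 1], ref_cor_p(res$r[1, 1], n), tolerance = 1e-10)
    ct <- cor.test(xr[1, ], yr[, 1])
    expect_equal(res$r[1, 1], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[1, 1], ct$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman columns rank-transform and are invariant to monotone maps", {
  n <- 10
  day <- 1:10
  resp <- day^3 + seq(0.01, 0.1, length.out = n)    # convex, strictly increasing
  x <- matrix(resp, 1, dimnames = list("row1", grp(n)))
  y <- cbind(Day = day, Lin = day)
  rownames(y) <- grp(n)
  attr(y, "spearman_traits") <- "Day"
  res <- correlate_groups(x, y)
  expect_equal(res$r[1, "Day"], 1)                   # Spearman rho = 1
  expect_lt(res$r[1, "Lin"], 1)                      # Pearson r < 1
  expect_identical(unname(res$method["Day"]), "spearman")
  expect_identical(unname(res$method["Lin"]), "pearson")

  # strictly monotone transform of either side leaves Spearman unchanged
  set.seed(62)
  xr <- rnorm(n); yr <- rnorm(n)
  r1 <- correlate_groups(matrix(xr, 1, dimnames = list("r", grp(n))),
                         structure(cbind(Day = yr), dimnames = list(grp(n), "Day"),
                                   spearman_traits = "Day"))
  r2 <- correlate_groups(matrix(exp(xr), 1, dimnames = list("r", grp(n))),
                         structure(cbind(Day = yr^3 + 2 * yr),
                                   dimnames = list(grp(n), "Day"),
                                   spearman_traits = "Day"))
  expect_equal(r1$r[1, 1], r2$r[1, 1], tolerance = 1e-12)
  expect_equal(r1$p[1, 1], r2$p[1, 1], tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are handled as specified", {
  n <- 8
  x <- matrix(rnorm(n), 1, dimnames = list("r", grp(n)))
  y <- cbind(flat = rep(2, n)); rownames(y) <- grp(n)
  res <- correlate_groups(x, y)
  expect_true(is.na(res$r[1, 1]))
  expect_equal(res$p[1, 1], 1)
  expect_true(res$flag[1, 1])

  y2 <- cbind(v = rnorm(2)); rownames(y2) <- grp(2)
  expect_error(correlate_groups(x[, 1:2, drop = FALSE], y2), "at least 3")
  expect_error(correlate_groups(x, cbind(v = rnorm(n))), "same groups")
})

test_that("significance stars use the exact published bands", {
  expect_identical(significance_stars(0.05), "*")
  expect_identical(significance_stars(0.01), "**")
  expect_identical(significance_stars(0.001), "***")
  expect_identical(significance_stars(0.0005), "***")
  expect_identical(significance_stars(0.2), "")
  expect_identical(significance_stars(0.049), "*")
  expect_identical(significance_stars(0.0101), "*")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
  expect_error(significance_stars(1.4), "\\[0, 1\\]")
  # bands are exhaustive and mutually exclusive over [0, 1]
  p <- seq(0, 1, by = 0.0001)
  s <- significance_stars(p)
  expect_true(all(s %in% c("", "*", "**", "***")))
  expect_identical(s, ifelse(p <= 0.001, "***",
                      ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
})

# small eigennode-like object for integration tests
fake_en <- function(vals, kingdom) {
  structure(list(values = vals,
                 var_explained = setNames(rep(0.5, nrow(vals)), rownames(vals)),
                 kingdom = kingdom),
            class = "eigennode_matrix")
}

test_that("iHAHI assembles its three blocks with the heatmap ordering and row rule", {
  st <- toy_samples(feeds = c("FO", "VO"), waters = c("FW", "SW"),
                    days = c(1L, 5L, 9L), reps = 2L, seed = 63)
  ns <- nrow(st)
  set.seed(64)
  water <- as.numeric(st$water == "SW")
  hvals <- rbind(hME1 = 2 * scale(water)[, 1] + rnorm(ns, sd = 0.4),
                 hME2 = rnorm(ns))
  colnames(hvals) <- st$sample_id
  mvals <- rbind(mME1 = 2 * scale(water)[, 1] + rnorm(ns, sd = 0.4),
                 mME2 = rnorm(ns))
  colnames(mvals) <- st$sample_id
  tr <- encode_traits(st)
  res <- build_ihahi(fake_en(hvals, "host"), fake_en(mvals, "microbe"), tr, st)
  # the water-driven host module is selected and starred on both sides
  expect_true("hME1" %in% res$selected)
  expect_identical(substr(res$left_stars["hME1", "WaterSW"], 1, 1), "*")
  expect_identical(substr(res$right_stars["hME1", "mME1"], 1, 1), "*")
  # center columns follow feed -> water -> day
  expect_identical(colnames(res$center),
                   c("FO_FW_D1", "FO_FW_D5", "FO_FW_D9",
                     "FO_SW_D1", "FO_SW_D5", "FO_SW_D9",
                     "VO_FW_D1", "VO_FW_D5", "VO_FW_D9",
                     "VO_SW_D1", "VO_SW_D5", "VO_SW_D9"))

  res_all <- build_ihahi(fake_en(hvals, "host"), fake_en(mvals, "microbe"), tr, st,
                         row_rule = "all")
  expect_identical(rownames(res_all$center), c("hME1", "hME2"))

  # write/read round trip of the numeric blocks
  pre <- file.path(withr::local_tempdir(), "fig")
  write_ihahi(res_all, pre)
  left <- read.table(paste0(pre, "_left.tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE)
  expect_equal(left$WaterSW, unname(res_all$left$r[, "WaterSW"]), tolerance = 1e-12)
})

test_that("an all-null dataset yields an empty selection with a warning", {
  st <- toy_samples(days = c(1L, 5L, 9L), reps = 2L, seed = 65)
  ns <- nrow(st)
  set.seed(66)
  hv <- matrix(rnorm(2 * ns), 2, dimnames = list(c("hME1", "hME2"), st$sample_id))
  mv <- matrix(rnorm(2 * ns), 2, dimnames = list(c("mME1", "mME2"), st$sample_id))
  tr <- encode_traits(st)
  # tighten alpha so a chance pass is essentially impossible
  expect_warning(res <- build_ihahi(fake_en(hv, "host"), fake_en(mv, "microbe"),
                                    tr, st, alpha = 1e-6),
                 "no host module")
  expect_identical(res$selected, character(0))
  expect_identical(nrow(res$center), 0L)
})

test_that("node-level follow-up agrees exactly with the block correlation engine", {
  st <- toy_samples(days = c(1L, 5L, 9L), reps = 2L, seed = 67)
  set.seed(68)
  gene <- setNames(rnorm(nrow(st)), st$sample_id)
  otu <- setNames(rnorm(nrow(st)), st$sample_id)
  res <- node_level_follow_up(gene, otu, st)
  g <- average_replicates(matrix(gene, 1, dimnames = list("g", names(gene))), st)
  o <- average_replicates(matrix(otu, 1, dimnames = list("o", names(otu))), st)
  block <- correlate_groups(g, t(o), spearman_cols = character(0))
  expect_identical(res$r, block$r[1, 1])
  expect_identical(res$p, block$p[1, 1])

  self <- node_level_follow_up(gene, gene, st)
  expect_equal(self$r, 1)
})

test_that("follow-up p-values are uniform under the null", {
  st <- toy_samples(feeds = "FO", waters = c("FW", "SW"),
                    days = c(1L, 2L, 5L, 9L, 13L, 16L, 20L), reps = 1L, seed = 69)
  stopifnot(length(unique(st$group_id)) == 14L)
  set.seed(70)
  ps <- vapply(1:500, function(i) {
    gene <- setNames(rnorm(nrow(st)), st$sample_id)
    otu <- setNames(rnorm(nrow(st)), st$sample_id)
    node_level_follow_up(gene, otu, st)$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
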