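test_that("count matrix rounds probability mass and clamps to coverage", {
  mk <- function(n, bsum, nmeth = 0L) {
    data.frame(chrom = "chr1", group_start = 100L, group_end = 101L,
               haplotype = "maternal", n_reads = n, beta_mean = bsum / n,
               beta_sum = bsum, n_methylated = nmeth,
               stringsAsFactors = FALSE)
  }
  cm <- build_count_matrix(list(s1 = mk(10L, 7.4), s2 = mk(5L, 5.9),
                                s3 = mk(3L, 3)))
  expect_equal(unname(cm$X[1, ]), c(7L, 5L, 3L))   # round, clamp at N, X=N
  expect_equal(unname(cm$N[1, ]), c(10L, 5L, 3L))
  # sample without coverage at a site: entry stays zero
  s4 <- mk(4L, 2)
  s4$group_start <- 500L
  s4$group_end <- 501L
  cm2 <- build_count_matrix(list(a = mk(10L, 7.4), b = s4))
  expect_equal(unname(cm2$N[, "b"]), c(0L, 4L))
  # alternative thresholded counting
  cm3 <- build_count_matrix(list(a = mk(10L, 7.4, nmeth = 9L)),
                            round_beta = FALSE)
  expect_equal(unname(cm3$X[1, 1]), 9L)
})

test_that("identical groups give zero effect and p = 1", {
  N <- matrix(10L, 1, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  X <- matrix(c(6L, 4L, 6L, 4L), 1, 4, dimnames = dimnames(N))
  r <- test_sites(make_counts(X, N), c("a1", "a2"), c("b1", "b2"))
  expect_equal(r$effect, 0)
  expect_equal(r$wald_stat, 0)
  expect_equal(r$p_value, 1)
})

test_that("extreme separation matches a brute-force formula evaluation", {
  # group1: X = N = 30 twice; group2: X = 0, N = 30 twice; dispersion -> 0
  N <- matrix(30L, 1, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  X <- matrix(c(30L, 30L, 0L, 0L), 1, 4, dimnames = dimnames(N))
  r <- test_sites(make_counts(X, N), c("a1", "a2"), c("b1", "b2"))
  # independent evaluation of the documented statistic (phi = 0 here)
  phi <- r$dispersion
  pg1 <- (60 + 0.5) / (60 + 1)
  pg2 <- 0.5 / 61
  m1 <- (60 * pg1 + 0.5) / 61
  m2 <- (60 * pg2 + 0.5) / 61
  v1 <- 60 * pg1 * (1 - pg1) * (1 + 29 * phi) / (61^2 * m1 * (1 - m1))
  v2 <- 60 * pg2 * (1 - pg2) * (1 + 29 * phi) / (61^2 * m2 * (1 - m2))
  w <- (asin(2 * pg1 - 1) - asin(2 * pg2 - 1)) / sqrt(v1 + v2)
  expect_equal(r$wald_stat, w, tolerance = 1e-12)
  expect_gt(abs(r$wald_stat), 10)
  expect_equal(r$effect, pg1 - pg2, tolerance = 1e-12)
})

test_that("swapping group labels negates effects and keeps p-values", {
  set.seed(21)
  cm <- make_null_counts(500L, 8L, 0.5, 0.08)
  cm$X[1:20, 1:2] <- cm$N[1:20, 1:2]  # some real signal
  r1 <- test_sites(cm, c("a1", "a2"), c("b1", "b2"))
  r2 <- test_sites(cm, c("b1", "b2"), c("a1", "a2"))
  expect_equal(r1$effect, -r2$effect)
  expect_equal(r1$wald_stat, -r2$wald_stat)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("sites lacking coverage in a whole group are skipped", {
  N <- matrix(c(5L, 5L, 0L, 0L,
                5L, 5L, 5L, 5L), 2, 4, byrow = TRUE,
              dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  X <- matrix(0L, 2, 4, dimnames = dimnames(N))
  r <- test_sites(make_counts(X, N), c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 500L)
  expect_error(test_sites(make_counts(X, N), c("a1", "zz"), "b1"),
               "unknown sample")
})

test_that("region calling applies the density, length and sign rules", {
  mkres <- function(start, p, eff = 0.5, w = 5) {
    data.frame(chrom = "chr1", start = start, end = start + 2L,
               effect = eff, wald_stat = w * sign(eff), p_value = p,
               dispersion = 0.05, stringsAsFactors = FALSE)
  }
  # no significant sites: empty
  expect_equal(nrow(call_dmrs(mkres(1:10 * 100L, 0.5))), 0L)
  # 5 adjacent significant sites spanning 400 bp, same sign: one DMR
  r <- mkres(seq(0L, 400L, by = 100L), 1e-8)
  d <- call_dmrs(r)
  expect_equal(nrow(d), 1L)
  expect_equal(d$n_sites, 5L)
  expect_equal(d$start, 0L)
  expect_equal(d$end, 402L)
  expect_equal(d$area_stat, sum(r$wald_stat))
  # 2 significant sites only: rejected by min_sites
  expect_equal(nrow(call_dmrs(mkres(c(0L, 100L), 1e-8))), 0L)
  # gap larger than merge_gap splits the run
  r2 <- mkres(c(0L, 50L, 100L, 400L, 450L, 500L), 1e-8)
  d2 <- call_dmrs(r2)
  expect_equal(nrow(d2), 2L)
  # opposite effect signs never merge
  r3 <- mkres(seq(0L, 500L, by = 100L), 1e-8)
  r3$effect[4:6] <- -0.5
  r3$wald_stat[4:6] <- -5
  d3 <- call_dmrs(r3)
  expect_equal(nrow(d3), 2L)
  expect_true(all(abs(d3$mean_diff) == 0.5))
  # fraction-significant filter: dense non-significant sites dilute a run
  r4 <- rbind(mkres(c(0L, 200L, 400L), 1e-8),
              mkres(c(50L, 100L, 150L, 250L, 300L, 350L), 0.5))
  expect_equal(nrow(call_dmrs(r4)), 0L)
  # ranking is by |area_stat| descending
  r5 <- rbind(mkres(c(0L, 50L, 100L), 1e-8, w = 5),
              mkres(c(5000L, 5050L, 5100L), 1e-8, eff = -0.5, w = 8))
  d5 <- call_dmrs(r5)
  expect_equal(d5$rank, 1:2)
  expect_equal(d5$start, c(5000L, 0L))
  expect_equal(d5$area_stat[1],
               sum(r5$wald_stat[r5$start >= 5000L]))
})

test_that("planted contrasts are assigned to the correct DMR list", {
  set.seed(33)
  ns <- 400L
  N <- matrix(10L, ns, 4, dimnames = list(NULL, c("m1", "p1", "m2", "p2")))
  X <- matrix(rbetabinom(ns * 4L, 10L, 0.5, 0.05), ns, 4,
              dimnames = dimnames(N))
  # sites 50..69: maternal hypermethylation in both crosses (imprinted-like)
  po_idx <- 50:69
  X[po_idx, c("m1", "m2")] <- rbetabinom(40L, 10L, 0.97, 0.01)
  X[po_idx, c("p1", "p2")] <- rbetabinom(40L, 10L, 0.03, 0.01)
  # sites 200..219: first-strain hypermethylation (strain-specific)
  st_idx <- 200:219
  X[st_idx, c("m1", "p2")] <- rbetabinom(40L, 10L, 0.97, 0.01)
  X[st_idx, c("p1", "m2")] <- rbetabinom(40L, 10L, 0.03, 0.01)
  counts <- make_counts(X, N, spacing = 60L)
  res <- run_contrasts(
    counts,
    parent = c(m1 = "maternal", p1 = "paternal", m2 = "maternal",
               p2 = "paternal"),
    strain = c(m1 = "first", p1 = "second", m2 = "second", p2 = "first")
  )
  po_d <- res$parent_of_origin$dmrs
  st_d <- res$strain$dmrs
  po_span <- c(49L * 60L, 69L * 60L + 2L)
  st_span <- c(199L * 60L, 219L * 60L + 2L)
  overlaps <- function(d, span) {
    any(d$start < span[2] & d$end > span[1])
  }
  expect_true(overlaps(po_d, po_span))
  expect_false(overlaps(po_d, st_span))
  expect_true(overlaps(st_d, st_span))
  expect_false(overlaps(st_d, po_span))
  expect_true(all(po_d$contrast == "parent_of_origin"))
  # missing design entries are fatal
  expect_error(run_contrasts(counts, parent = c(m1 = "maternal"),
                             strain = c(m1 = "first")), "design")
})

test_that("area statistic equals an independent member-site recomputation", {
  set.seed(55)
  start <- cumsum(sample(20:80, 300L, replace = TRUE))
  res <- data.frame(chrom = "chr1", start = start, end = start + 2L,
                    effect = 0.4, wald_stat = rnorm(300, 5, 0.3),
                    p_value = 10^-runif(300, 4, 9), dispersion = 0.05,
                    stringsAsFactors = FALSE)
  d <- call_dmrs(res, p_threshold = 1e-5)
  expect_gt(nrow(d), 0L)
  for (i in seq_len(nrow(d))) {
    memb <- res$start >= d$start[i] & res$end <= d$end[i]
    expect_equal(d$area_stat[i], sum(res$wald_stat[memb]))
    expect_equal(d$n_sites[i], sum(memb))
    expect_equal(d$mean_diff[i], mean(res$effect[memb]))
  }
})

test_that("the site test has power where coverage supports it", {
  # imprinted-scale effect at adequate depth: nearly every site significant
  set.seed(66)
  ns <- 200L
  N <- matrix(30L, ns, 4, dimnames = list(NULL, c("m1", "m2", "p1", "p2")))
  X <- cbind(matrix(rbetabinom(ns * 2L, 30L, 0.95, 0.02), ns, 2),
             matrix(rbetabinom(ns * 2L, 30L, 0.05, 0.02), ns, 2))
  dimnames(X) <- dimnames(N)
  r <- test_sites(make_counts(X, N), c("m1", "m2"), c("p1", "p2"))
  expect_gt(mean(r$p_value < 1e-5), 0.9)
  expect_true(all(r$effect > 0.5))
})

test_that("gene-to-DMR distances match an all-pairs brute force", {
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000L, 11500L, 50000L, 100L, 5000L),
    end = c(11000L, 12200L, 51000L, 600L, 6000L),
    gene = sprintf("g%d", 1:5),
    class = c("biased", "biased", "unbiased", "unbiased", "unbiased"),
    stringsAsFactors = FALSE
  )
  dmrs <- data.frame(
    chrom = "chr1", start = c(12000L, 40000L, 70000L),
    end = c(12500L, 41000L, 70500L), n_sites = 5L, n_significant = 5L,
    area_stat = c(50, 40, 30), mean_diff = 0.5, rank = 1:3,
    contrast = "parent_of_origin", stringsAsFactors = FALSE
  )
  expect_warning(res <- distance_to_nearest_dmr(genes, dmrs), "without DMRs")
  # brute force over all gene/DMR pairs
  brute <- vapply(seq_len(nrow(genes)), function(i) {
    same <- dmrs$chrom == genes$chrom[i]
    if (!any(same)) return(Inf)
    min(vapply(which(same), function(j) {
      if (genes$start[i] < dmrs$end[j] && genes$end[i] > dmrs$start[j]) {
        return(0)
      }
      max(dmrs$start[j] - genes$end[i], genes$start[i] - dmrs$end[j])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(res$table$distance, brute)
  # gene overlapping a DMR has distance 0 (g2 overlaps 12000-12500)
  expect_equal(res$table$distance[res$table$gene == "g2"], 0)
  # gene at 10000-11000 with DMR at 12000-12500: gap 1000
  expect_equal(res$table$distance[res$table$gene == "g1"], 1000)
  # medians per class exclude infinite distances
  fin <- res$table[is.finite(res$table$distance), ]
  expect_equal(res$medians[["biased"]],
               median(fin$distance[fin$class == "biased"]))
  # top_k restriction drops lower-ranked DMRs
  res2 <- suppressWarnings(distance_to_nearest_dmr(genes, dmrs, top_k = 1))
  expect_equal(res2$table$distance[1], 1000)
})
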