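test_that("likelihood-to-probability conversion matches closed forms", {
  expect_equal(beta_from_likelihoods(0, 0, 0.5), 0.5)
  expect_equal(beta_from_likelihoods(log(4), 0, 0.5), 0.8)
  expect_equal(beta_from_likelihoods(log(4), 0, 0.25), 4 / 7)
  # at llr = 0 the posterior equals the prior for any p0
  for (p0 in c(0.1, 0.25, 0.5, 0.9)) {
    expect_equal(beta_from_likelihoods(1.5, 1.5, p0), p0)
  }
  # infinities are exact
  expect_equal(beta_from_likelihoods(Inf, 0), 1)
  expect_equal(beta_from_likelihoods(-Inf, 0), 0)
  # extreme finite ratios do not overflow
  expect_equal(beta_from_likelihoods(800, 0), 1)
  expect_equal(beta_from_likelihoods(0, 800), 0)
  # symmetry at p0 = 0.5 and monotonicity
  llr <- seq(-30, 30, by = 0.5)
  b <- beta_from_likelihoods(llr, 0)
  expect_equal(b + rev(b), rep(1, length(b)))
  expect_true(all(diff(b) > 0))
  expect_error(beta_from_likelihoods(0, 0, 1.2), "p0")
})

test_that("CpG chaining matches the documented gap rule and closure oracle", {
  expect_equal(chain_call_groups(c(100L, 108L, 130L)), c(1L, 1L, 2L))
  expect_equal(chain_call_groups(c(100L)), 1L)
  expect_equal(chain_call_groups(integer()), integer())
  # boundary: distance exactly 11 does NOT chain (< 11 rule)
  expect_equal(chain_call_groups(c(100L, 111L)), c(1L, 2L))
  expect_equal(chain_call_groups(c(100L, 110L)), c(1L, 1L))
  expect_error(chain_call_groups(c(5L, 3L)), "sorted")

  # transitive-closure oracle on random position sets
  set.seed(9)
  for (r in 1:50) {
    pos <- sort(sample.int(2000L, 50L))
    got <- chain_call_groups(pos)
    adj <- outer(pos, pos, function(a, b) abs(a - b) < 11)
    g <- igraph_free_closure <- local({
      # union-find transitive closure
      parent <- seq_along(pos)
      find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      for (i in seq_along(pos)) {
        for (j in seq_len(i - 1L)) {
          if (adj[i, j]) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
      roots <- vapply(seq_along(pos), find, integer(1))
      match(roots, unique(roots))
    })
    expect_equal(got, g)
  }
  # chaining is idempotent: groups derived from group-start positions
  pos <- sort(sample.int(5000L, 200L))
  ids <- chain_call_groups(pos)
  spans <- call_group_spans(pos, ids)
  expect_equal(chain_call_groups(spans$start), seq_len(nrow(spans)))
})

test_that("group aggregation is the arithmetic mean over reads", {
  expect_equal(aggregate_group(c(1, 0))$beta_mean, 0.5)
  expect_equal(aggregate_group(0.8)$beta_mean, 0.8)
  expect_null(aggregate_group(numeric()))
  set.seed(3)
  b <- runif(100)
  a <- aggregate_group(b)
  expect_equal(a$beta_mean, sum(b) / 100, tolerance = 1e-12)
  expect_equal(a$n_reads, 100L)
  expect_equal(a$beta_sum, sum(b))
})

test_that("haplotype-split summaries route reads by their H label", {
  rec <- data.frame(
    chrom = "chr1", group_start = rep(c(100L, 200L), each = 3),
    group_end = rep(c(101L, 201L), each = 3),
    read_id = rep(c("m", "p", "u"), 2),
    beta = c(0.9, 0.1, 0.5, 0.8, 0.2, 0.6),
    stringsAsFactors = FALSE
  )
  hap <- data.frame(read_id = c("m", "p", "u"), H = c(1L, -1L, 0L))
  s <- summarize_call_groups(rec, hap, maternal_is_ref = TRUE)
  g1 <- s[s$group_start == 100L, ]
  expect_equal(g1$beta_mean[g1$haplotype == "maternal"], 0.9)
  expect_equal(g1$beta_mean[g1$haplotype == "paternal"], 0.1)
  # H = 0 contributes to "all" but to neither haplotype
  expect_equal(g1$n_reads[g1$haplotype == "all"], 3L)
  expect_equal(g1$beta_mean[g1$haplotype == "all"], 0.5)
  # reciprocal orientation flips the parental mapping
  s2 <- summarize_call_groups(rec, hap, maternal_is_ref = FALSE)
  g2 <- s2[s2$group_start == 100L, ]
  expect_equal(g2$beta_mean[g2$haplotype == "maternal"], 0.1)
})

test_that("group splitting emits both strand cytosines and inverts cleanly", {
  cpg <- data.frame(chrom = "chr1", pos = c(100L, 108L, 130L))
  sums <- data.frame(chrom = "chr1", group_start = c(100L, 130L),
                     group_end = c(109L, 131L), beta_mean = c(0.7, 0.2),
                     stringsAsFactors = FALSE)
  sp <- split_groups_to_sites(sums, cpg)
  expect_equal(sp$pos, c(100L, 101L, 108L, 109L, 130L, 131L))
  expect_equal(sp$beta, c(0.7, 0.7, 0.7, 0.7, 0.2, 0.2))
  # singleton group: two site rows
  expect_equal(sum(sp$pos >= 130L), 2L)
  # regrouping the forward-strand sites recovers the original groups
  fwd <- sp[sp$pos %in% cpg$pos, ]
  expect_equal(chain_call_groups(fwd$pos), c(1L, 1L, 2L))
  # total beta mass per group is preserved under split/aggregate
  expect_equal(
    tapply(fwd$beta, chain_call_groups(fwd$pos), mean),
    setNames(sums$beta_mean, c("1", "2")),
    ignore_attr = TRUE
  )
})

test_that("bisulfite concordance reports MAD, quadrants and agreement", {
  sites <- data.frame(chrom = "chr1", pos = 1:100 * 10L,
                      beta = rep(0.9, 100), stringsAsFactors = FALSE)
  c0 <- compare_with_bisulfite(sites, sites)
  expect_equal(c0$median_absolute_deviation, 0)
  expect_equal(c0$binary_agreement, 1)
  expect_equal(sum(c0$quadrant_fractions), 1)

  # values straddling the two thresholds: nanopore 0.37 is methylated at
  # its 0.36 threshold while bisulfite 0.49 is not at 0.5
  nano <- transform(sites, beta = 0.37)
  rrbs <- transform(sites, beta = 0.49)
  cx <- compare_with_bisulfite(nano, rrbs)
  expect_equal(unname(cx$quadrant_fractions["high_low"]), 1)
  expect_equal(cx$binary_agreement, 0)
  # both high under their respective thresholds
  cy <- compare_with_bisulfite(nano, transform(sites, beta = 0.51))
  expect_equal(cy$binary_agreement, 1)

  # MAD matches an independent recomputation on a noisy pair
  set.seed(12)
  nanov <- transform(sites, beta = runif(100))
  rrbsv <- transform(sites, beta = pmin(pmax(nanov$beta +
                                               rnorm(100, 0, 0.1), 0), 1))
  cz <- compare_with_bisulfite(nanov, rrbsv)
  expect_equal(cz$median_absolute_deviation,
               median(abs(nanov$beta - rrbsv$beta)))
  expect_equal(cz$n_sites, 100L)

  # only shared sites are compared; zero shared sites is fatal
  off <- transform(sites, pos = pos + 1L)
  expect_error(compare_with_bisulfite(sites, off[0, ]), "no CpG sites shared")
  part <- compare_with_bisulfite(sites, sites[1:10, ])
  expect_equal(part$n_sites, 10L)
})
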