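test_that("score_snp matches the printed empirical model", {
  # independent evaluation of S = 1 - exp(-0.6927 - 0.1203 q)
  expect_equal(score_snp(0), 1 - exp(-0.6927), tolerance = 1e-4)
  expect_equal(score_snp(0), 0.4998, tolerance = 1e-4)
  expect_equal(score_snp(10), 0.8498, tolerance = 1e-4)
  expect_equal(score_snp(30), 0.9865, tolerance = 1e-4)
  q <- seq(0, 60, by = 0.25)
  s <- score_snp(q)
  expect_true(all(diff(s) > 0))          # strictly monotonic
  expect_true(all(s > 0 & s < 1))
  expect_error(score_snp(-1), "must be >= 0")
})

test_that("basecall observations classify ref/alt/neither/deletion", {
  # read with G (q=20) over an A->G SNP: alt match scored
  seq <- strrep("A", 50)
  substr(seq, 11, 11) <- "G"
  substr(seq, 21, 21) <- "T"
  read <- make_read(seq = seq, start = 100L)
  snps <- make_snps(c(110L, 120L, 130L), ref = c("A", "A", "A"),
                    alt = c("G", "G", "G"))
  obs <- collect_basecall_observations(read, snps)
  expect_equal(obs$match, c("alt", "neither", "ref"))
  expect_equal(obs$S[1], score_snp(20))
  expect_true(is.na(obs$S[2]))           # neither carries no score
  # deletion at the SNP position is excluded
  read_del <- make_read(seq = strrep("A", 45), cigar = "10M5D35M",
                        start = 100L, qual = strrep("5", 45))
  obs_del <- collect_basecall_observations(
    read_del, make_snps(112L, "A", "G")
  )
  expect_equal(obs_del$match, "deletion")
  ev <- aggregate_evidence(obs_del)
  expect_equal(ev$n, 0L)
  expect_true(is.na(ev$h))
})

test_that("evidence aggregation is the mean per-SNP contribution", {
  obs <- data.frame(snp_pos = 1:2, match = c("ref", "alt"), q = c(1, 1),
                    S = c(0.9, 0.8))
  ev <- aggregate_evidence(obs)
  expect_equal(ev$n, 2L)
  expect_equal(ev$h, (0.9 + 0.2) / 2)
  obs5 <- data.frame(snp_pos = 1:5, match = "ref", q = 1, S = 0.9)
  expect_equal(aggregate_evidence(obs5)$h, 0.9)
  expect_equal(aggregate_evidence(obs[0, ])$n, 0L)
})

test_that("signal evidence applies the -35 offset with a floor at zero", {
  r <- data.frame(called_allele = "ref", quality = 45)
  ev <- signal_evidence(r)
  expect_equal(ev$h, score_snp(10))
  expect_equal(ev$h, 0.8498, tolerance = 1e-4)
  # quality below the offset floors to q = 0: uninformative-at-worst
  r2 <- data.frame(called_allele = "ref", quality = 30)
  expect_equal(signal_evidence(r2)$h, score_snp(0))
  ev0 <- signal_evidence(data.frame(called_allele = character(),
                                    quality = numeric()))
  expect_equal(ev0$n, 0L)
  expect_equal(ev0$source, "signal")
})

test_that("combination rules fire in order on the documented cases", {
  mk <- function(n, h, source = "basecall") list(n = n, h = h, source = source)
  cc <- combine_calls(mk(4, 0.9), mk(4, 0.9))
  expect_equal(c(cc$H, cc$rule_fired), c(0L, 1L))
  cc <- combine_calls(mk(10, 0.8), mk(10, 0.7))
  expect_equal(c(cc$H, cc$rule_fired), c(1L, 2L))
  cc <- combine_calls(mk(20, 0.3), mk(5, 0.8))    # 20 > 3*5
  expect_equal(c(cc$H, cc$rule_fired), c(-1L, 3L))
  cc <- combine_calls(mk(5, 0.8), mk(20, 0.3))
  expect_equal(c(cc$H, cc$rule_fired), c(-1L, 4L))
  cc <- combine_calls(mk(6, 0.9), mk(6, 0.45))    # 0.4 > 3*0.05
  expect_equal(c(cc$H, cc$rule_fired), c(1L, 5L))
  cc <- combine_calls(mk(6, 0.6), mk(6, 0.2))     # 0.3 > 3*0.1
  expect_equal(c(cc$H, cc$rule_fired), c(-1L, 6L))
  cc <- combine_calls(mk(6, 0.6), mk(6, 0.4))
  expect_equal(c(cc$H, cc$rule_fired), c(0L, 7L))
  # a read without signal output is assigned by basecall alone via rule 3
  cc <- combine_calls(mk(8, 0.9), mk(0, NA_real_, "signal"))
  expect_equal(c(cc$H, cc$rule_fired), c(1L, 3L))
  # h exactly 0.5 is unassigned and cannot satisfy the agreement rule
  cc <- combine_calls(mk(10, 0.5), mk(10, 0.5))
  expect_equal(cc$H, 0L)
})

test_that("combination agrees with the brute-force oracle on random tuples", {
  set.seed(101)
  n_cases <- 2000L
  n_b <- sample(0:20, n_cases, replace = TRUE)
  n_s <- sample(0:20, n_cases, replace = TRUE)
  h_b <- ifelse(n_b == 0L, NA_real_,
                sample(c(runif(n_cases), 0.5, 0.35, 0.65),
                       n_cases, replace = TRUE))
  h_s <- ifelse(n_s == 0L, NA_real_,
                sample(c(runif(n_cases), 0.5), n_cases, replace = TRUE))
  # force boundary regimes: n = 5, exact 3x ratios
  n_b[1:50] <- 5L
  n_s[51:100] <- 5L
  n_s[101:150] <- pmax(n_b[101:150] * 3L, 1L)
  for (i in seq_len(n_cases)) {
    got <- combine_calls(list(n = n_b[i], h = h_b[i], source = "basecall"),
                         list(n = n_s[i], h = h_s[i], source = "signal"))
    want <- oracle_combine(n_b[i], h_b[i], n_s[i], h_s[i])
    expect_identical(got$H, want$H)
    expect_identical(got$rule_fired, want$rule)
  }
})

test_that("swapping ref/alt labels of every SNP negates every call", {
  cfg <- small_config(seed = 11, genome_length = 2e5, coverage = 4)
  g <- simulate_genome_and_snps(cfg)
  sim <- simulate_reads(cfg, g, n_reads = 60)
  sig <- simulate_signal_scores(cfg, g, sim)
  hap <- haplotype_reads(sim$reads, g$snps_cast, signal = sig)
  snps_sw <- g$snps_cast
  names(snps_sw)[names(snps_sw) == "ref"] <- "tmp"
  names(snps_sw)[names(snps_sw) == "alt"] <- "ref"
  names(snps_sw)[names(snps_sw) == "tmp"] <- "alt"
  snps_sw <- snps_sw[names(g$snps_cast)]
  sig_sw <- sig
  sig_sw$called_allele <- ifelse(sig$called_allele == "ref", "alt", "ref")
  hap_sw <- haplotype_reads(sim$reads, snps_sw, signal = sig_sw)
  expect_equal(hap_sw$H, -hap$H)
})

test_that("assignment metrics and AUROC are computed correctly", {
  a <- data.frame(read_id = sprintf("r%d", 1:15),
                  h_base = c(rep(0.9, 8), rep(0.1, 2), rep(0.5, 5)),
                  h_signal = NA_real_,
                  H = c(rep(1L, 8), rep(-1L, 2), rep(0L, 5)))
  truth <- rep(1L, 15)
  ev <- evaluate_assignments(a, truth)
  expect_equal(ev$accuracy, 0.8)
  expect_equal(ev$fraction_called, 10 / 15)
  expect_equal(ev$misassignment, 2 / 15)
  expect_error(evaluate_assignments(a, truth[-1]), "different lengths")

  # identical scores for both classes: AUROC 0.5
  expect_equal(auroc(rep(0.7, 10), rep(c(1, -1), 5)), 0.5)
  # cross-check the rank formula against pROC on random scores
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- runif(200)
  tr <- sample(c(1, -1), 200, replace = TRUE)
  ours <- auroc(sc, tr)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(tr, levels = c(-1, 1)), predictor = sc,
    quiet = TRUE, direction = "<"
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("haplotype TSV round-trips through write and read", {
  td <- withr::local_tempdir()
  cfg <- small_config(seed = 3, genome_length = 1e5, coverage = 2)
  g <- simulate_genome_and_snps(cfg)
  sim <- simulate_reads(cfg, g, n_reads = 10)
  hap <- haplotype_reads(sim$reads, g$snps_cast)
  p <- file.path(td, "hap.tsv")
  write_haplotypes_tsv(hap, p)
  expect_equal(read_haplotypes_tsv(p), hap, ignore_attr = TRUE)
})
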