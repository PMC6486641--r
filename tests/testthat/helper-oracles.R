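# Independent oracles and small fixture builders shared across tests.

# Literal transliteration of the ordered combination rule table, written
# independently of combine_calls(). h values may be NA (no evidence).
oracle_combine <- function(n_b, h_b, n_s, h_s, min_snps = 5, ratio = 3) {
  sgn <- function(h) if (is.na(h)) 0L else as.integer(sign(h - 0.5))
  dev <- function(h) if (is.na(h)) 0 else abs(h - 0.5)
  H_b <- sgn(h_b)
  H_s <- sgn(h_s)
  if (n_b < min_snps && n_s < min_snps) return(list(H = 0L, rule = 1L))
  if (H_b != 0L && H_s != 0L && H_b == H_s) return(list(H = H_b, rule = 2L))
  if (n_b > ratio * n_s) return(list(H = H_b, rule = 3L))
  if (n_s > ratio * n_b) return(list(H = H_s, rule = 4L))
  if (dev(h_b) > ratio * dev(h_s)) return(list(H = H_b, rule = 5L))
  if (dev(h_s) > ratio * dev(h_b)) return(list(H = H_s, rule = 6L))
  list(H = 0L, rule = 7L)
}

# Beta-binomial draws (used by the DMR calibration and power simulations).
rbetabinom <- function(n, size, p, phi) {
  if (phi <= 0) return(stats::rbinom(n, size, p))
  a <- p * (1 - phi) / phi
  b <- (1 - p) * (1 - phi) / phi
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

# Null / two-group count matrix builder for test_sites(): ns sites,
# 2 vs 2 samples, constant coverage.
make_counts <- function(X, N, chrom = "chrT", spacing = 500L) {
  ns <- nrow(X)
  start <- (seq_len(ns) - 1L) * spacing
  list(sites = data.frame(chrom = chrom, start = start, end = start + 2L,
                          stringsAsFactors = FALSE),
       N = N, X = X, samples = colnames(N))
}

make_null_counts <- function(ns, N0, p, phi, spacing = 500L) {
  N <- matrix(N0, ns, 4, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  X <- matrix(rbetabinom(ns * 4L, N0, p, phi), ns, 4,
              dimnames = list(NULL, colnames(N)))
  make_counts(X, N, spacing = spacing)
}

# Exhaustive-split recursive partition oracle with the same split-acceptance
# rule as fit_partition (improvement > cp * root SS, node >= minsplit).
oracle_partition_means <- function(y, minsplit = 5, cp = 0.1) {
  ss <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  root <- ss(y)
  segs <- list()
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n >= minsplit && n >= 2L) {
      best <- -Inf
      at <- NA_integer_
      for (k in lo:(hi - 1L)) {
        imp <- ss(y[lo:hi]) - ss(y[lo:k]) - ss(y[(k + 1L):hi])
        if (imp > best) {
          best <- imp
          at <- k
        }
      }
      if (best > cp * root) {
        rec(lo, at)
        rec(at + 1L, hi)
        return(invisible())
      }
    }
    segs[[length(segs) + 1L]] <<- c(lo, hi)
    invisible()
  }
  rec(1L, length(y))
  segs <- do.call(rbind, segs)
  apply(segs, 1, function(s) mean(y[s[1]:s[2]]))
}

# One-row alignment data frame for observation-level tests.
make_read <- function(read_id = "r1", chrom = "chr1", start = 100L,
                      seq = strrep("A", 50L), qual = NULL, cigar = NULL) {
  len <- nchar(seq)
  if (is.null(qual)) qual <- strrep("5", len)  # '5' = Phred 20
  if (is.null(cigar)) cigar <- paste0(len, "M")
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  data.frame(read_id = read_id, chrom = chrom, start = start,
             end = start + width, cigar = cigar, seq = seq, qual = qual,
             mapq = 60L, stringsAsFactors = FALSE)
}

make_snps <- function(pos, ref, alt, chrom = "chr1", strain = "CAST") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             strain = strain, stringsAsFactors = FALSE)
}

# Small sim config whose planted DMRs scale with the genome length.
small_config <- function(seed = 1, genome_length = 3e5, ...) {
  s1 <- as.integer(genome_length * 0.3)
  s2 <- as.integer(genome_length * 0.7)
  sim_config(
    seed = seed, genome_length = genome_length,
    planted_dmrs = data.frame(
      start = c(s1, s2),
      end = c(s1 + 2000L, s2 + 1500L),
      contrast = c("parent_of_origin", "strain"),
      p_high = 0.95, p_low = 0.05, stringsAsFactors = FALSE
    ),
    ...
  )
}
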