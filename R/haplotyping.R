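# Per-read haplotype assignment from basecalled SNP observations and
# signal-level scores, combined by an ordered rule table.

#' Empirical SNP-observation score
#'
#' Converts a basecall quality into the probability-like score
#' `S = 1 - exp(-0.6927 - 0.1203 q)` used to weight a single SNP observation.
#' The coefficients were fitted empirically on successfully haplotyped reads;
#' the same model is applied to signal-level scores after their offset.
#'
#' @param q Numeric vector of quality scores (Phred scale), `q >= 0`.
#' @return Scores in `(0, 1)`, strictly increasing in `q`; `S(0) ~= 0.4998`.
#' @export
score_snp <- function(q) {
  if (any(q < 0, na.rm = TRUE)) {
    stop("score_snp: quality must be >= 0 (apply offset/floor first)")
  }
  1 - exp(-0.6927 - 0.1203 * q)
}

# ref-space and query-space block decomposition of one CIGAR string.
# Returns match blocks (rstart 0-based, rend half-open, qstart 1-based offset
# into seq) and deletion blocks on the reference.
.cigar_blocks <- function(cigar, start0) {
  ops_r <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, ops = c("M", "=", "X", "D", "N"), with.ops = TRUE
  )[[1]]
  ops_q <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cigar, ops = c("M", "=", "X", "D", "N"), with.ops = TRUE
  )[[1]]
  op <- names(ops_r)
  is_m <- op %in% c("M", "=", "X")
  list(
    m_rstart = start0 + IRanges::start(ops_r)[is_m] - 1L,
    m_rend = start0 + IRanges::end(ops_r)[is_m],
    m_qstart = IRanges::start(ops_q)[is_m],
    d_rstart = start0 + IRanges::start(ops_r)[!is_m] - 1L,
    d_rend = start0 + IRanges::end(ops_r)[!is_m]
  )
}

#' Collect basecall SNP observations for one aligned read
#'
#' Classifies the aligned base at every SNP overlapped by the read as matching
#' the reference allele, the alternate allele, neither, or a deletion.
#' Neither/deletion observations are excluded from scoring downstream.
#'
#' @param read A single-row data frame (one row of [read_alignments()] output).
#' @param snps SNP table from [read_snp_table()].
#' @return A `data.frame` with columns `snp_pos`, `match`
#'   (`ref`/`alt`/`neither`/`deletion`), `q` and `S` (`NA` for excluded
#'   observations).
#' @export
collect_basecall_observations <- function(read, snps) {
  idx <- which(snps$chrom == read$chrom &
                 snps$pos >= read$start & snps$pos < read$end)
  empty <- data.frame(snp_pos = integer(), match = character(), q = numeric(),
                      S = numeric(), stringsAsFactors = FALSE)
  if (length(idx) == 0L) return(empty)
  snp <- snps[idx, , drop = FALSE]
  blk <- .cigar_blocks(read$cigar, read$start)

  pos <- snp$pos
  match_type <- rep("neither", length(pos))
  q <- rep(NA_real_, length(pos))
  base <- rep(NA_character_, length(pos))

  if (length(blk$d_rstart) > 0L) {
    in_del <- vapply(pos, function(p) any(p >= blk$d_rstart & p < blk$d_rend),
                     logical(1))
    match_type[in_del] <- "deletion"
  }
  if (length(blk$m_rstart) > 0L) {
    bi <- findInterval(pos, blk$m_rstart)
    inside <- bi >= 1L & pos < blk$m_rend[pmax(bi, 1L)] &
      match_type != "deletion"
    if (any(inside)) {
      off <- blk$m_qstart[bi[inside]] + (pos[inside] - blk$m_rstart[bi[inside]])
      base[inside] <- substring(read$seq, off, off)
      q[inside] <- utf8ToInt(read$qual)[off] - 33
      is_ref <- base[inside] == snp$ref[inside]
      is_alt <- base[inside] == snp$alt[inside]
      match_type[inside] <- ifelse(is_ref, "ref",
                                   ifelse(is_alt, "alt", "neither"))
    }
  }
  S <- rep(NA_real_, length(pos))
  inf <- match_type %in% c("ref", "alt")
  S[inf] <- score_snp(q[inf])
  q[!inf] <- NA_real_
  data.frame(snp_pos = pos, match = match_type, q = q, S = S,
             stringsAsFactors = FALSE)
}

#' Aggregate SNP observations into per-read haplotype evidence
#'
#' The aggregate haplotype value is the mean per-SNP contribution: `S` for
#' observations agreeing with the reference allele and `1 - S` for those
#' agreeing with the alternate. Values near 1 support the reference (first)
#' haplotype, values near 0 the alternate.
#'
#' @param observations Data frame from [collect_basecall_observations()];
#'   only `ref`/`alt` matches are informative.
#' @param source Evidence stream label (`"basecall"` or `"signal"`).
#' @return A list with `n` (informative SNP count), `h` (aggregate value in
#'   `[0, 1]`, `NA` when `n = 0`) and `source`.
#' @export
aggregate_evidence <- function(observations, source = "basecall") {
  keep <- observations$match %in% c("ref", "alt")
  obs <- observations[keep, , drop = FALSE]
  n <- nrow(obs)
  if (n == 0L) {
    return(list(n = 0L, h = NA_real_, source = source))
  }
  contrib <- ifelse(obs$match == "ref", obs$S, 1 - obs$S)
  list(n = n, h = mean(contrib), source = source)
}

#' Haplotype evidence from signal-level scores for one read
#'
#' Signal-level qualities are offset by −35 to put them on the basecall
#' quality scale, floored at 0 (the score model is uninformative-at-worst at
#' `q = 0`), then scored and aggregated exactly as basecall observations.
#'
#' @param records Data frame of signal score records for a single read
#'   (columns `called_allele`, `quality`).
#' @param offset Quality offset subtracted before scoring (default 35).
#' @return A list with `n`, `h` and `source = "signal"` as in
#'   [aggregate_evidence()].
#' @export
signal_evidence <- function(records, offset = 35) {
  n <- nrow(records)
  if (is.null(records) || n == 0L) {
    return(list(n = 0L, h = NA_real_, source = "signal"))
  }
  q <- pmax(records$quality - offset, 0)
  S <- score_snp(q)
  contrib <- ifelse(records$called_allele == "ref", S, 1 - S)
  list(n = n, h = mean(contrib), source = "signal")
}

# sign(h - 0.5) with NA-safe handling: no evidence -> 0 (unassigned).
.hap_sign <- function(h) {
  if (is.na(h)) 0L else as.integer(sign(h - 0.5))
}

#' Combine basecall and signal haplotype evidence for one read
#'
#' Applies the ordered rule table: (1) both streams have fewer than
#' `min_snps` informative SNPs: unassigned; (2) both calls are nonzero and
#' agree: that call; (3)/(4) one stream has more than `ratio` times the SNP
#' support of the other: the better-supported call; (5)/(6) one stream's
#' deviation `|h - 0.5|` exceeds `ratio` times the other's: the stronger call;
#' (7) otherwise unassigned.
#'
#' @param base Evidence list from [aggregate_evidence()].
#' @param signal Evidence list from [signal_evidence()].
#' @param min_snps Minimum informative SNP count for a confident read
#'   (default 5).
#' @param ratio Dominance factor used by rules (3)-(6) (default 3, strict
#'   inequality).
#' @return A list with `n_base`, `h_base`, `H_base`, `n_signal`, `h_signal`,
#'   `H_signal`, `H` (−1/0/+1, +1 = reference haplotype) and `rule_fired`
#'   (1-7).
#' @export
combine_calls <- function(base, signal, min_snps = 5, ratio = 3) {
  n_b <- base$n
  n_s <- signal$n
  h_b <- base$h
  h_s <- signal$h
  H_b <- .hap_sign(h_b)
  H_s <- .hap_sign(h_s)
  d_b <- if (is.na(h_b)) 0 else abs(h_b - 0.5)
  d_s <- if (is.na(h_s)) 0 else abs(h_s - 0.5)

  if (n_b < min_snps && n_s < min_snps) {
    H <- 0L; rule <- 1L
  } else if (H_b != 0L && H_b == H_s) {
    H <- H_b; rule <- 2L
  } else if (n_b > ratio * n_s) {
    H <- H_b; rule <- 3L
  } else if (n_s > ratio * n_b) {
    H <- H_s; rule <- 4L
  } else if (d_b > ratio * d_s) {
    H <- H_b; rule <- 5L
  } else if (d_s > ratio * d_b) {
    H <- H_s; rule <- 6L
  } else {
    H <- 0L; rule <- 7L
  }
  list(n_base = n_b, h_base = h_b, H_base = H_b,
       n_signal = n_s, h_signal = h_s, H_signal = H_s,
       H = H, rule_fired = rule)
}

#' Haplotype every read in an alignment set
#'
#' Runs [collect_basecall_observations()], [signal_evidence()] and
#' [combine_calls()] over all reads.
#'
#' @param reads Data frame of alignments from [read_alignments()] (or the
#'   in-memory equivalent from the simulator).
#' @param snps SNP table from [read_snp_table()].
#' @param signal Optional data frame of signal score records from
#'   [read_signal_scores_tsv()]; reads absent from it get `n_signal = 0`.
#' @param min_snps,ratio Passed to [combine_calls()].
#' @return A `data.frame` with one row per read: `read_id`, `chrom`, `start`,
#'   `end`, `n_base`, `h_base`, `n_signal`, `h_signal`, `H`, `rule_fired`.
#' @export
haplotype_reads <- function(reads, snps, signal = NULL, min_snps = 5,
                            ratio = 3) {
  n <- nrow(reads)
  sig_split <- if (!is.null(signal) && nrow(signal) > 0L) {
    split(signal, signal$read_id)
  } else {
    list()
  }
  empty_sig <- data.frame(called_allele = character(), quality = numeric(),
                          stringsAsFactors = FALSE)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    read <- reads[i, ]
    obs <- collect_basecall_observations(read, snps)
    base_ev <- aggregate_evidence(obs)
    sig_rec <- sig_split[[read$read_id]]
    sig_ev <- signal_evidence(if (is.null(sig_rec)) empty_sig else sig_rec)
    cc <- combine_calls(base_ev, sig_ev, min_snps = min_snps, ratio = ratio)
    res[[i]] <- data.frame(
      read_id = read$read_id, chrom = read$chrom, start = read$start,
      end = read$end, n_base = cc$n_base, h_base = cc$h_base,
      n_signal = cc$n_signal, h_signal = cc$h_signal, H = cc$H,
      rule_fired = cc$rule_fired, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve for a continuous haplotype score
#'
#' Rank-based (Mann-Whitney) AUROC of `score` against binary truth; ties get
#' mid-rank credit.
#'
#' @param score Numeric score vector (higher = more reference-like).
#' @param truth Truth labels, `+1` (reference) / `-1` (alternate).
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(score, truth) {
  keep <- !is.na(score)
  score <- score[keep]
  pos <- truth[keep] > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate haplotype assignments against truth
#'
#' @param assignments Data frame from [haplotype_reads()].
#' @param truth Vector of true labels (`+1`/`-1`), one per row of
#'   `assignments`.
#' @return A list with `accuracy` (correct / called), `fraction_called`,
#'   `misassignment` (wrong / total), `n_called`, `auroc_base` and
#'   `auroc_signal` (rank AUROC of `h_base` / `h_signal` where defined).
#' @export
evaluate_assignments <- function(assignments, truth) {
  if (nrow(assignments) != length(truth)) {
    stop("assignments and truth have different lengths")
  }
  called <- assignments$H != 0L
  correct <- called & assignments$H == truth
  wrong <- called & assignments$H == -truth
  list(
    accuracy = if (any(called)) sum(correct) / sum(called) else NA_real_,
    fraction_called = mean(called),
    misassignment = sum(wrong) / length(truth),
    n_called = sum(called),
    auroc_base = auroc(assignments$h_base, truth),
    auroc_signal = auroc(assignments$h_signal, truth)
  )
}

#' Write per-read haplotype assignments as TSV
#' @param assignments Data frame from [haplotype_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes_tsv <- function(assignments, path) {
  data.table::fwrite(data.table::as.data.table(assignments), path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-read haplotype TSV written by [write_haplotypes_tsv()]
#' @param path Path to the TSV file.
#' @return A `data.frame` of assignments.
#' @export
read_haplotypes_tsv <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         showProgress = FALSE,
                                         na.strings = "NA"))
  # all-NA h columns must stay numeric
  for (col in c("h_base", "h_signal")) {
    if (col %in% names(out)) out[[col]] <- as.numeric(out[[col]])
  }
  out
}
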