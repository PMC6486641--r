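# Synthetic-data generator: every input the pipeline consumes, with known
# truth. Emulates an F1 reciprocal-cross design (B6xCast and CastxB6) on a
# single synthetic chromosome, with optional FVB ancestry segments on the
# maternal line.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: a ~10-fold
#' covered F1 placental sample with log-normal long reads, 10% basecall
#' error with Phred qualities that are exact transforms of the error rate,
#' strain SNPs at realistic densities, a mostly 50%-methylated genome, and
#' planted CpG-island-like DMRs with near-complete allelic methylation
#' differences (the imprinting-control-region regime).
#'
#' @param seed Base random seed; all derived seeds stay below 2^31.
#' @param genome_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param snp_density_cast,snp_density_fvb Strain SNP densities per bp.
#' @param cpg_density Background CpG density per bp.
#' @param dmr_cpg_spacing Mean CpG gap inside planted DMRs (CGI-like).
#' @param read_length_meanlog,read_length_sdlog Log-normal read length
#'   parameters.
#' @param per_base_error Basecall substitution error probability; qualities
#'   are `-10 log10(error)`.
#' @param deletion_event_rate Per-bp rate of small (1-3 bp) deletion events.
#' @param coverage Mean genomic coverage per cross.
#' @param background_levels Methylation probabilities of the two background
#'   domain states (hypomethylated CGI-like and methylated gene-body-like);
#'   domains alternate so the genome-wide mean is near 50%, as in placental
#'   tissue.
#' @param background_block Mean methylation-domain length in bp.
#' @param planted_dmrs Data frame (`start`, `end`, `contrast`, `p_high`,
#'   `p_low`) of planted differentially methylated regions;
#'   `contrast` is `"parent_of_origin"` (maternal high) or `"strain"`
#'   (first-strain allele high).
#' @param planted_fvb_segment Optional `c(start, end)` maternal-line FVB
#'   ancestry segment, or `NULL`.
#' @param llr_mu,llr_noise_sd Mean magnitude and noise of simulated per-group
#'   log-likelihood ratios (nats).
#' @param signal_error Signal-level miscall probability; signal qualities are
#'   `35 - 10 log10(error)`.
#' @param signal_missing_rate Fraction of reads with no signal-level output.
#' @param bisulfite_coverage Mean per-site bisulfite coverage.
#' @return A list of class `haplomet_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       genome_length = 2e6,
                       chrom = "chrS",
                       snp_density_cast = 0.002,
                       snp_density_fvb = 0.001,
                       cpg_density = 0.002,
                       dmr_cpg_spacing = 25,
                       read_length_meanlog = log(20000),
                       read_length_sdlog = 0.35,
                       per_base_error = 0.1,
                       deletion_event_rate = 2e-5,
                       coverage = 10,
                       background_levels = c(0.12, 0.85),
                       background_block = 20000,
                       planted_dmrs = NULL,
                       planted_fvb_segment = NULL,
                       llr_mu = 4,
                       llr_noise_sd = 2,
                       signal_error = 0.08,
                       signal_missing_rate = 0.15,
                       bisulfite_coverage = 30) {
  if (is.null(planted_dmrs)) {
    # anchored at fixed genome fractions so any genome length fits
    anchors <- as.integer(round(genome_length *
                                  c(0.10, 0.45, 0.75, 0.25, 0.60)))
    widths <- c(2000L, 2000L, 2000L, 1500L, 1500L)
    planted_dmrs <- data.frame(
      start = anchors,
      end = pmin(anchors + widths, as.integer(genome_length)),
      contrast = c("parent_of_origin", "parent_of_origin",
                   "parent_of_origin", "strain", "strain"),
      p_high = 0.95, p_low = 0.05,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(planted_dmrs$end <= genome_length),
            per_base_error >= 0, per_base_error < 1,
            all(background_levels >= 0), all(background_levels <= 1))
  structure(list(
    seed = seed, genome_length = as.integer(genome_length), chrom = chrom,
    snp_density_cast = snp_density_cast, snp_density_fvb = snp_density_fvb,
    cpg_density = cpg_density, dmr_cpg_spacing = dmr_cpg_spacing,
    read_length_meanlog = read_length_meanlog,
    read_length_sdlog = read_length_sdlog,
    per_base_error = per_base_error,
    deletion_event_rate = deletion_event_rate,
    coverage = coverage, background_levels = background_levels,
    background_block = background_block,
    planted_dmrs = planted_dmrs, planted_fvb_segment = planted_fvb_segment,
    llr_mu = llr_mu, llr_noise_sd = llr_noise_sd,
    signal_error = signal_error, signal_missing_rate = signal_missing_rate,
    bisulfite_coverage = bisulfite_coverage
  ), class = "haplomet_sim_config")
}

.BASES <- c("A", "C", "G", "T")

.random_alleles <- function(n) {
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Simulate the reference description: SNP tables and CpG positions
#'
#' Deterministic under `config$seed`. CAST and FVB SNP positions are disjoint;
#' CpG sites are laid down at the background density everywhere plus a dense
#' CGI-like lattice inside planted DMRs.
#'
#' @param config A [sim_config()] object.
#' @return A list with `chrom`, `length`, `snps_cast`, `snps_fvb` (SNP
#'   tables), `cpg` (data frame `chrom`, `pos`), `groups` (call-group spans
#'   with `n_sites`) and `group_of` (group id per CpG site).
#' @export
simulate_genome_and_snps <- function(config) {
  set.seed(config$seed %% 2147483040L)
  L <- config$genome_length
  n_cast <- rbinom(1, L, config$snp_density_cast)
  n_fvb <- rbinom(1, L, config$snp_density_fvb)
  if (n_cast + n_fvb > L / 2) {
    stop("SNP densities too high for genome length")
  }
  all_pos <- sample.int(L, n_cast + n_fvb) - 1L
  pos_cast <- sort(all_pos[seq_len(n_cast)])
  pos_fvb <- sort(all_pos[n_cast + seq_len(n_fvb)])

  al_c <- .random_alleles(n_cast)
  al_f <- .random_alleles(n_fvb)
  snps_cast <- data.frame(chrom = rep(config$chrom, n_cast), pos = pos_cast,
                          ref = al_c$ref, alt = al_c$alt,
                          strain = rep("CAST", n_cast),
                          stringsAsFactors = FALSE)
  snps_fvb <- data.frame(chrom = rep(config$chrom, n_fvb), pos = pos_fvb,
                         ref = al_f$ref, alt = al_f$alt,
                         strain = rep("FVB", n_fvb),
                         stringsAsFactors = FALSE)

  n_bg <- rbinom(1, L, config$cpg_density)
  cpg <- sample.int(L - 2L, n_bg) - 1L
  for (i in seq_len(nrow(config$planted_dmrs))) {
    d <- config$planted_dmrs[i, ]
    gaps <- pmax(2L, as.integer(round(
      stats::rexp(ceiling((d$end - d$start) / 2), 1 / config$dmr_cpg_spacing)
    )))
    p <- d$start + cumsum(gaps)
    cpg <- c(cpg, p[p < d$end])
  }
  cpg <- sort(unique(cpg))
  cpg <- cpg[c(TRUE, diff(cpg) >= 2L)]  # CpG cytosines cannot overlap

  group_of <- chain_call_groups(cpg)
  groups <- call_group_spans(cpg, group_of)

  # background methylation domains: alternating low/high blocks of
  # exponential length, giving a bimodal methylome with ~50% global mean
  n_blocks <- max(2L, as.integer(ceiling(L / config$background_block)) * 2L)
  block_len <- pmax(as.integer(round(
    stats::rexp(n_blocks, 1 / config$background_block))), 1000L)
  block_end <- cumsum(block_len)
  block_state <- (sample.int(2L, 1L) + seq_len(n_blocks)) %% 2L + 1L
  while (block_end[length(block_end)] < L) {
    block_len <- c(block_len, config$background_block)
    block_end <- c(block_end, block_end[length(block_end)] +
                     config$background_block)
    block_state <- c(block_state, block_state[length(block_state)] %% 2L + 1L)
  }
  base_p <- config$background_levels[
    block_state[findInterval(groups$start, c(0L, block_end),
                             left.open = TRUE)]]

  list(chrom = config$chrom, length = L,
       snps_cast = snps_cast, snps_fvb = snps_fvb,
       cpg = data.frame(chrom = config$chrom, pos = cpg,
                        stringsAsFactors = FALSE),
       groups = groups, group_of = group_of, base_p = base_p)
}

# True methylation probability per call group for an allele of a given
# parent ("maternal"/"paternal") and strain ("first"/"second"; first = the
# reference-line strain, e.g. B6).
.group_p_true <- function(config, genome, parent, strain) {
  groups <- genome$groups
  p <- genome$base_p
  pd <- config$planted_dmrs
  for (i in seq_len(nrow(pd))) {
    hit <- groups$start >= pd$start[i] & groups$start < pd$end[i]
    if (pd$contrast[i] == "parent_of_origin") {
      p[hit] <- if (parent == "maternal") pd$p_high[i] else pd$p_low[i]
    } else {
      p[hit] <- if (strain == "first") pd$p_high[i] else pd$p_low[i]
    }
  }
  p
}

#' True per-group methylation levels for every allele class
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome_and_snps()].
#' @return A `data.frame` with the group span and the true methylation
#'   probability of the maternal/paternal allele in each cross
#'   (`mat_c1` = maternal of B6xCast, etc.).
#' @export
true_methylation_table <- function(config, genome) {
  g <- genome$groups
  data.frame(
    chrom = genome$chrom, start = g$start, end = g$end,
    n_sites = g$n_sites,
    mat_c1 = .group_p_true(config, genome, "maternal", "first"),
    pat_c1 = .group_p_true(config, genome, "paternal", "second"),
    mat_c2 = .group_p_true(config, genome, "maternal", "second"),
    pat_c2 = .group_p_true(config, genome, "paternal", "first"),
    stringsAsFactors = FALSE
  )
}

# Phred quality as exact transform of an error rate, ASCII-encoded (+33).
.phred_char <- function(error) {
  q <- if (error <= 0) 60L else as.integer(round(-10 * log10(error)))
  intToUtf8(min(q, 60L) + 33L)
}

#' Simulate aligned long reads for one cross or a pure strain
#'
#' Reads carry haplotype-consistent alleles at SNP positions, confused with
#' the opposite allele with probability `per_base_error` (so an error rate
#' of 0.5 makes single-SNP evidence exactly uninformative); small deletion
#' events produce D CIGAR operations. Base qualities
#' are the exact Phred transform of the error rate, so the empirical score
#' model operates in its calibrated regime. Maternal reads inside the
#' planted FVB segment carry FVB alleles at FVB SNP positions.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome_and_snps()].
#' @param cross `"B6xCast"` (maternal = reference strain) or `"CastxB6"`.
#' @param pure_strain `NULL`, `"ref"` or `"alt"`: when set, all reads come
#'   from one parental strain (a pure-strain validation run).
#' @param n_reads Number of reads; default from coverage and mean length.
#' @param seed_offset Added to `config$seed` for this batch.
#' @return A list with `reads` (alignment data frame compatible with
#'   [read_alignments()] output) and `truth` (`read_id`, `H_true` with
#'   +1 = reference haplotype, `parent`, `strain`, `in_fvb`).
#' @export
simulate_reads <- function(config, genome, cross = "B6xCast",
                           pure_strain = NULL, n_reads = NULL,
                           seed_offset = 1L) {
  set.seed((config$seed + seed_offset) %% 2147483040L)
  L <- genome$length
  mean_len <- exp(config$read_length_meanlog +
                    config$read_length_sdlog^2 / 2)
  if (is.null(n_reads)) {
    n_reads <- as.integer(round(config$coverage * L / mean_len))
  }
  lens <- pmin(pmax(as.integer(round(rlnorm(n_reads,
                                            config$read_length_meanlog,
                                            config$read_length_sdlog))),
                    200L), L)
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                   integer(1))
  H_true <- if (is.null(pure_strain)) {
    sample(c(1L, -1L), n_reads, replace = TRUE)
  } else {
    rep(if (pure_strain == "ref") 1L else -1L, n_reads)
  }
  maternal_is_ref <- cross == "B6xCast"
  parent <- ifelse((H_true == 1L) == maternal_is_ref, "maternal", "paternal")
  strain <- ifelse(H_true == 1L, "first", "second")

  fvb <- config$planted_fvb_segment
  qc <- .phred_char(config$per_base_error)

  snps_c <- genome$snps_cast
  snps_f <- genome$snps_fvb
  reads <- vector("list", n_reads)
  in_fvb <- logical(n_reads)
  for (i in seq_len(n_reads)) {
    s <- starts[i]
    len <- lens[i]
    e <- s + len
    ch <- rep("A", len)

    idx_c <- which(snps_c$pos >= s & snps_c$pos < e)
    if (length(idx_c) > 0L) {
      if (H_true[i] == 1L) {
        allele <- snps_c$ref[idx_c]
        other <- snps_c$alt[idx_c]
      } else {
        allele <- snps_c$alt[idx_c]
        other <- snps_c$ref[idx_c]
      }
      err <- runif(length(idx_c)) < config$per_base_error
      allele[err] <- other[err]
      ch[snps_c$pos[idx_c] - s + 1L] <- allele
    }
    # FVB SNP positions: all reads carry the reference base except maternal
    # reads inside the planted FVB ancestry segment, which carry FVB alleles
    idx_f <- which(snps_f$pos >= s & snps_f$pos < e)
    if (length(idx_f) > 0L) {
      allele <- snps_f$ref[idx_f]
      other <- snps_f$alt[idx_f]
      if (!is.null(fvb) && parent[i] == "maternal") {
        swap <- snps_f$pos[idx_f] >= fvb[1] & snps_f$pos[idx_f] < fvb[2]
        tmp <- allele[swap]
        allele[swap] <- other[swap]
        other[swap] <- tmp
      }
      err <- runif(length(idx_f)) < config$per_base_error
      allele[err] <- other[err]
      ch[snps_f$pos[idx_f] - s + 1L] <- allele
    }
    if (!is.null(fvb) && parent[i] == "maternal") {
      mid <- s + len %/% 2L
      in_fvb[i] <- mid >= fvb[1] && mid < fvb[2]
    }

    # deletion events -> D ops in the CIGAR
    n_del <- rpois(1, len * config$deletion_event_rate)
    del <- integer(0)
    if (n_del > 0L) {
      for (k in seq_len(n_del)) {
        dl <- sample(1:3, 1)
        ds <- sample.int(max(len - dl - 2L, 1L), 1L) + 1L
        del <- c(del, ds:(ds + dl - 1L))
      }
      del <- sort(unique(del[del >= 2L & del <= len - 1L]))
    }
    if (length(del) > 0L) {
      keep <- setdiff(seq_len(len), del)
      r <- rle(seq_len(len) %in% del)
      cigar <- paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
      seq_str <- paste(ch[keep], collapse = "")
      qual_str <- strrep(qc, length(keep))
    } else {
      cigar <- paste0(len, "M")
      seq_str <- paste(ch, collapse = "")
      qual_str <- strrep(qc, len)
    }
    reads[[i]] <- list(start = s, end = e, cigar = cigar, seq = seq_str,
                       qual = qual_str)
  }
  ids <- sprintf("%s_read%05d", if (is.null(pure_strain)) cross else
    paste0("pure", pure_strain), seq_len(n_reads))
  rd <- data.frame(
    read_id = ids, chrom = genome$chrom, start = starts,
    end = starts + lens,
    cigar = vapply(reads, `[[`, character(1), "cigar"),
    seq = vapply(reads, `[[`, character(1), "seq"),
    qual = vapply(reads, `[[`, character(1), "qual"),
    mapq = 60L, stringsAsFactors = FALSE
  )
  o <- order(rd$start)
  rd <- rd[o, , drop = FALSE]
  rownames(rd) <- NULL
  truth <- data.frame(read_id = ids, H_true = H_true, parent = parent,
                      strain = strain, in_fvb = in_fvb,
                      stringsAsFactors = FALSE)[o, , drop = FALSE]
  rownames(truth) <- NULL
  list(reads = rd, truth = truth)
}

#' Simulate signal-level haplotype scores
#'
#' A second, independent noisy observation of the read haplotypes with its
#' own error rate and the nanopolish quality scale (+35 offset). A fraction
#' of reads produce no signal output at all.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome_and_snps()].
#' @param sim Output of [simulate_reads()].
#' @param seed_offset Added to `config$seed`.
#' @return A signal-score `data.frame` as from [read_signal_scores_tsv()].
#' @export
simulate_signal_scores <- function(config, genome, sim, seed_offset = 2L) {
  set.seed((config$seed + seed_offset) %% 2147483040L)
  reads <- sim$reads
  truth <- sim$truth
  quality <- 35 - 10 * log10(config$signal_error)
  out <- vector("list", nrow(reads))
  has_signal <- runif(nrow(reads)) >= config$signal_missing_rate
  snps <- genome$snps_cast
  for (i in seq_len(nrow(reads))) {
    if (!has_signal[i]) next
    idx <- which(snps$pos >= reads$start[i] & snps$pos < reads$end[i])
    if (length(idx) == 0L) next
    true_allele <- if (truth$H_true[i] == 1L) "ref" else "alt"
    wrong <- runif(length(idx)) < config$signal_error
    called <- ifelse(wrong, setdiff(c("ref", "alt"), true_allele), true_allele)
    out[[i]] <- data.frame(
      read_id = reads$read_id[i], chrom = reads$chrom[i],
      snp_pos = snps$pos[idx], called_allele = called, quality = quality,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(read_id = character(), chrom = character(),
                      snp_pos = integer(), called_allele = character(),
                      quality = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Simulate per-read methylation log-likelihood records
#'
#' For every read and every call group fully covered by it, the true
#' methylation state is Bernoulli with the group's allele-specific
#' probability; the emitted log-likelihood ratio is `+mu` (methylated) or
#' `-mu` plus Gaussian noise.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome_and_snps()].
#' @param sim Output of [simulate_reads()].
#' @param seed_offset Added to `config$seed`.
#' @return A methylation record `data.frame` (as from
#'   [read_methylation_tsv()]) with an additional `true_state` column.
#' @export
simulate_methylation_llrs <- function(config, genome, sim, seed_offset = 3L) {
  set.seed((config$seed + seed_offset) %% 2147483040L)
  g <- genome$groups
  reads <- sim$reads
  truth <- sim$truth
  p_by <- list(
    maternal_first = .group_p_true(config, genome, "maternal", "first"),
    maternal_second = .group_p_true(config, genome, "maternal", "second"),
    paternal_first = .group_p_true(config, genome, "paternal", "first"),
    paternal_second = .group_p_true(config, genome, "paternal", "second")
  )
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    gi <- which(g$start >= reads$start[i] & g$end <= reads$end[i])
    if (length(gi) == 0L) next
    p <- p_by[[paste(truth$parent[i], truth$strain[i], sep = "_")]][gi]
    state <- runif(length(gi)) < p
    llr <- ifelse(state, config$llr_mu, -config$llr_mu) +
      rnorm(length(gi), 0, config$llr_noise_sd)
    out[[i]] <- data.frame(
      chrom = reads$chrom[i], group_start = g$start[gi],
      group_end = g$end[gi], read_id = reads$read_id[i],
      log_lik_methylated = llr, log_lik_unmethylated = 0,
      num_cpgs = g$n_sites[gi], strand = "+", true_state = state,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$group_start, res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate per-site bisulfite methylation calls
#'
#' Unhaplotyped aggregate calls: each CpG site (both strand cytosines)
#' receives Poisson coverage and a binomial methylated count at the mean of
#' the two allelic probabilities of its call group.
#'
#' @param config A [sim_config()] object.
#' @param genome Output of [simulate_genome_and_snps()].
#' @param cross Which cross's allele probabilities to use.
#' @param seed_offset Added to `config$seed`.
#' @return A `data.frame` with `chrom`, `pos`, `beta`, `coverage`.
#' @export
simulate_bisulfite <- function(config, genome, cross = "B6xCast",
                               seed_offset = 4L) {
  set.seed((config$seed + seed_offset) %% 2147483040L)
  g <- genome$groups
  first_mat <- cross == "B6xCast"
  p_mat <- .group_p_true(config, genome, "maternal",
                         if (first_mat) "first" else "second")
  p_pat <- .group_p_true(config, genome, "paternal",
                         if (first_mat) "second" else "first")
  p_site <- ((p_mat + p_pat) / 2)[genome$group_of]
  pos <- genome$cpg$pos
  pos2 <- c(pos, pos + 1L)
  p2 <- c(p_site, p_site)
  cov <- rpois(length(pos2), config$bisulfite_coverage)
  keep <- cov > 0L
  x <- rbinom(sum(keep), cov[keep], p2[keep])
  out <- data.frame(chrom = genome$chrom, pos = pos2[keep],
                    beta = x / cov[keep], coverage = cov[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate windowed FVB fractions with one planted segment
#'
#' Lightweight generator for the recombination module: per 100 kb window,
#' `n_reads` maternal reads are drawn and the FVB count is binomial with the
#' in-segment probability inside the planted block and the background
#' probability outside.
#'
#' @param n_windows Number of windows.
#' @param block Integer window indices (1-based) of the true FVB block.
#' @param p_in,p_out FVB read probability inside/outside the block.
#' @param n_reads Maternal reads per window.
#' @param chrom Chromosome name.
#' @param window_size Window width in bp.
#' @return A list with `windows` (as from [window_fvb_fractions()]) and
#'   `truth` (`start`/`end` of the block in bp).
#' @export
simulate_fvb_windows <- function(n_windows, block, p_in = 0.9, p_out = 0.05,
                                 n_reads = 20, chrom = "chrS",
                                 window_size = 100000) {
  p <- ifelse(seq_len(n_windows) %in% block, p_in, p_out)
  n_fvb <- rbinom(n_windows, n_reads, p)
  w <- data.frame(
    chrom = chrom,
    window_start = as.integer((seq_len(n_windows) - 1L) * window_size),
    n_maternal_reads = n_reads,
    fvb_fraction = n_fvb / n_reads,
    stringsAsFactors = FALSE
  )
  list(windows = w,
       truth = c(start = (min(block) - 1L) * window_size,
                 end = max(block) * window_size))
}

#' Write a read set as a SAM file
#'
#' Minimal single-chromosome SAM with `@HD`/`@SQ` header lines; convert with
#' `Rsamtools::asBam` for BAM consumers.
#'
#' @param reads Alignment data frame from [simulate_reads()].
#' @param chrom_length Chromosome length for the `@SQ` line.
#' @param path Output path (should end in `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, chrom_length, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", reads$chrom[1],
                       as.integer(chrom_length))), con)
  writeLines(sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     reads$read_id, reads$chrom, reads$start + 1L,
                     reads$mapq, reads$cigar, reads$seq, reads$qual), con)
  invisible(path)
}

#' Write a SNP table as a minimal VCF
#' @param snps SNP table (internal 0-based positions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", snps$chrom,
                     snps$pos + 1L, snps$ref, snps$alt), con)
  invisible(path)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Emits every input dialect the pipeline reads: two strain VCFs, per-cross
#' SAM alignments, signal-score and methylation TSVs, a bisulfite table, a
#' gene BED with expression-class labels, and a truth JSON.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_set <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome_and_snps(config)
  paths <- list(
    vcf_cast = file.path(dir, "cast.vcf"),
    vcf_fvb = file.path(dir, "fvb.vcf"),
    genes = file.path(dir, "genes.bed"),
    truth = file.path(dir, "truth.json")
  )
  write_snp_vcf(genome$snps_cast, paths$vcf_cast)
  write_snp_vcf(genome$snps_fvb, paths$vcf_fvb)

  crosses <- c("B6xCast", "CastxB6")
  truth_reads <- list()
  for (k in seq_along(crosses)) {
    cr <- crosses[k]
    sim <- simulate_reads(config, genome, cross = cr,
                          seed_offset = 10L * k)
    sig <- simulate_signal_scores(config, genome, sim,
                                  seed_offset = 10L * k + 1L)
    meth <- simulate_methylation_llrs(config, genome, sim,
                                      seed_offset = 10L * k + 2L)
    tag <- tolower(cr)
    paths[[paste0("sam_", tag)]] <- file.path(dir, paste0(tag, ".sam"))
    paths[[paste0("signal_", tag)]] <- file.path(dir,
                                                 paste0(tag, "_signal.tsv"))
    paths[[paste0("meth_", tag)]] <- file.path(dir, paste0(tag, "_meth.tsv"))
    write_sam(sim$reads, genome$length, paths[[paste0("sam_", tag)]])
    write_signal_scores_tsv(sig, paths[[paste0("signal_", tag)]])
    write_methylation_tsv(meth, paths[[paste0("meth_", tag)]])
    truth_reads[[cr]] <- sim$truth
  }
  paths$cpg <- file.path(dir, "cpg_sites.tsv")
  data.table::fwrite(
    data.table::data.table(chromosome = genome$cpg$chrom,
                           position = genome$cpg$pos),
    paths$cpg, sep = "\t", quote = FALSE
  )

  bis <- simulate_bisulfite(config, genome)
  paths$bisulfite <- file.path(dir, "bisulfite.tsv")
  data.table::fwrite(
    data.table::data.table(chromosome = bis$chrom, position = bis$pos,
                           beta = bis$beta, coverage = bis$coverage),
    paths$bisulfite, sep = "\t", quote = FALSE
  )

  genes <- simulate_genes(config, seed_offset = 5L)
  con <- file(paths$genes, "w")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+\t%s", genes$chrom, genes$start,
                     genes$end, genes$gene, genes$class), con)
  close(con)

  jsonlite::write_json(
    list(config = config[setdiff(names(config), "planted_dmrs")],
         planted_dmrs = config$planted_dmrs,
         truth_methylation = true_methylation_table(config, genome),
         truth_reads = truth_reads),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Simulate gene intervals with expression-bias classes
#'
#' Parent-biased genes are placed adjacent to planted parent-of-origin DMRs
#' (imprinted expression is driven by nearby allelic methylation); unbiased
#' genes are placed uniformly at random.
#'
#' @param config A [sim_config()] object.
#' @param n_unbiased Number of unbiased genes.
#' @param seed_offset Added to `config$seed`.
#' @return A `data.frame` with `chrom`, `start`, `end`, `gene`, `class`.
#' @export
simulate_genes <- function(config, n_unbiased = 30, seed_offset = 5L) {
  set.seed((config$seed + seed_offset) %% 2147483040L)
  pd <- config$planted_dmrs
  po <- pd[pd$contrast == "parent_of_origin", , drop = FALSE]
  genes <- list()
  for (i in seq_len(nrow(po))) {
    s <- po$end[i] + sample.int(5000L, 1L)
    genes[[i]] <- data.frame(
      chrom = config$chrom, start = s, end = s + 8000L,
      gene = sprintf("imprinted_%d", i), class = "parent_biased",
      stringsAsFactors = FALSE
    )
  }
  for (j in seq_len(n_unbiased)) {
    s <- sample.int(config$genome_length - 10000L, 1L)
    genes[[length(genes) + 1L]] <- data.frame(
      chrom = config$chrom, start = s, end = s + 8000L,
      gene = sprintf("gene_%d", j), class = "unbiased",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, genes)
  out[order(out$start), , drop = FALSE]
}
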