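#' @import data.table
#' @importFrom stats median pnorm predict loess loess.control plogis qnorm
#'   rbeta rbinom rlnorm rnorm rpois runif var complete.cases setNames
#' @importFrom utils head tail
NULL

# All internal coordinates are 0-based half-open. Every reader converts at the
# boundary (VCF and SAM/BAM are 1-based; BED and bedGraph pass through).

#' Read a strain SNP table from a VCF file
#'
#' Retains biallelic single-nucleotide variants only and converts positions to
#' the internal 0-based convention. Records are sorted by (chromosome,
#' position); multi-allelic sites, indels and structural records are dropped.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzip).
#' @param strain_label Label for the strain carrying the alternate allele
#'   (e.g. `"CAST"` or `"FVB"`).
#' @return A `data.frame` with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `strain`.
#' @export
read_snp_table <- function(vcf_path, strain_label) {
  if (!file.exists(vcf_path)) {
    stop("SNP VCF not found: ", vcf_path)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  if (n_total == 0L) {
    stop("no records in VCF: ", vcf_path)
  }
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    fix$REF != fix$ALT
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) {
    stop("no usable biallelic SNVs in ", vcf_path,
         " (", n_total, " records read, 0 retained)")
  }
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    strain = strain_label,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read primary alignments from a BAM file
#'
#' Yields one row per primary alignment with the fields needed to look up the
#' aligned base and quality at any reference position (sequence, qualities and
#' CIGAR). Secondary, supplementary and unmapped records are skipped and
#' counted.
#'
#' @param bam_path Path to a coordinate-sorted BAM file. An index is built on
#'   the fly if missing.
#' @param region Optional region restriction, a list/vector
#'   `(chrom, start, end)` with 0-based half-open coordinates.
#' @return A `data.frame` with columns `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open reference span), `cigar`, `seq`, `qual` (ASCII Phred+33
#'   string) and `mapq`. The number of skipped records is in
#'   `attr(x, "n_skipped")`.
#' @export
read_alignments <- function(bam_path, region = NULL) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path)
  }
  bai <- paste0(bam_path, ".bai")
  if (!file.exists(bai)) {
    Rsamtools::indexBam(bam_path)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  what <- c("qname", "rname", "pos", "cigar", "seq", "qual", "mapq", "flag")
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    gr <- GenomicRanges::GRanges(
      as.character(region[[1]]),
      IRanges::IRanges(as.numeric(region[[2]]) + 1, as.numeric(region[[3]]))
    )
    param <- Rsamtools::ScanBamParam(flag = flag, what = what, which = gr)
  }
  res <- Rsamtools::scanBam(bam_path, param = param)
  res <- do.call(Map, c(list(c), res))  # merge ranges if region split
  n_all <- Rsamtools::countBam(bam_path)$records
  if (length(res$qname) == 0L) {
    out <- data.frame(
      read_id = character(), chrom = character(), start = integer(),
      end = integer(), cigar = character(), seq = character(),
      qual = character(), mapq = integer(), stringsAsFactors = FALSE
    )
    attr(out, "n_skipped") <- n_all
    return(out)
  }
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  out <- data.frame(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + widths,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    mapq = res$mapq,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_all - nrow(out)
  out
}

# Required columns for the methylation TSV dialect (nanopolish call-methylation
# names). Either log_lik_ratio or the two log-likelihood columns must exist.
.meth_required <- c("chromosome", "start", "end", "read_name", "num_motifs")

#' Read per-read CpG methylation records
#'
#' Accepts the nanopolish `call-methylation` column dialect. `start`/`end` give
#' the first and last CpG cytosine of the call group (both inclusive,
#' 0-based, as emitted by nanopolish); internally the group span is stored
#' half-open as `[group_start, group_end)` with `group_end = end + 1`. When
#' only `log_lik_ratio` is present it is stored as the methylated
#' log-likelihood with the unmethylated term set to 0.
#'
#' @param tsv_path Path to a tab-separated file with a header line.
#' @return A `data.frame` with columns `chrom`, `group_start`, `group_end`,
#'   `read_id`, `log_lik_methylated`, `log_lik_unmethylated`, `num_cpgs`, and
#'   `strand` (`"."` when absent from the input).
#' @export
read_methylation_tsv <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    stop("methylation TSV not found: ", tsv_path)
  }
  dt <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  miss <- setdiff(.meth_required, names(dt))
  if (length(miss) > 0L) {
    stop("methylation TSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  has_pair <- all(c("log_lik_methylated", "log_lik_unmethylated") %in% names(dt))
  if (!has_pair && !("log_lik_ratio" %in% names(dt))) {
    stop("methylation TSV must contain either log_lik_ratio or both ",
         "log_lik_methylated and log_lik_unmethylated")
  }
  n0 <- nrow(dt)
  if (n0 == 0L) {
    out <- data.frame(
      chrom = character(), group_start = integer(), group_end = integer(),
      read_id = character(), log_lik_methylated = numeric(),
      log_lik_unmethylated = numeric(), num_cpgs = integer(),
      strand = character(), stringsAsFactors = FALSE
    )
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  if (has_pair) {
    llm <- as.numeric(dt$log_lik_methylated)
    llu <- as.numeric(dt$log_lik_unmethylated)
  } else {
    llm <- as.numeric(dt$log_lik_ratio)
    llu <- rep(0, n0)
  }
  out <- data.frame(
    chrom = as.character(dt$chromosome),
    group_start = suppressWarnings(as.integer(dt$start)),
    group_end = suppressWarnings(as.integer(dt$end)) + 1L,
    read_id = as.character(dt$read_name),
    log_lik_methylated = llm,
    log_lik_unmethylated = llu,
    num_cpgs = suppressWarnings(as.integer(dt$num_motifs)),
    strand = if ("strand" %in% names(dt)) as.character(dt$strand) else ".",
    stringsAsFactors = FALSE
  )
  ok <- complete.cases(out[c("chrom", "group_start", "group_end", "read_id",
                             "log_lik_methylated", "log_lik_unmethylated",
                             "num_cpgs")]) &
    out$group_end > out$group_start & out$num_cpgs >= 1L
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning("skipped ", n_bad, " malformed methylation record(s)")
    out <- out[ok, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$group_start, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write methylation records in the nanopolish column dialect
#'
#' Inverse of [read_methylation_tsv()]: `end` is written as the inclusive
#' last-site coordinate (`group_end - 1`).
#'
#' @param records Data frame as returned by [read_methylation_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_tsv <- function(records, path) {
  dt <- data.table::data.table(
    chromosome = records$chrom,
    strand = if ("strand" %in% names(records)) records$strand else ".",
    start = records$group_start,
    end = records$group_end - 1L,
    read_name = records$read_id,
    log_lik_methylated = records$log_lik_methylated,
    log_lik_unmethylated = records$log_lik_unmethylated,
    log_lik_ratio = records$log_lik_methylated - records$log_lik_unmethylated,
    num_motifs = records$num_cpgs
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read per-read signal-level haplotype scores
#'
#' Tab-separated dialect with columns `read_name`, `chromosome`, `position`
#' (0-based SNP coordinate), `called_allele` (`ref`/`alt`) and `quality`
#' (nanopolish-scale score; the −35 offset is applied downstream by
#' [signal_evidence()]).
#'
#' @param tsv_path Path to the TSV file.
#' @return A `data.frame` with columns `read_id`, `chrom`, `snp_pos`,
#'   `called_allele`, `quality`.
#' @export
read_signal_scores_tsv <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    stop("signal score TSV not found: ", tsv_path)
  }
  dt <- data.table::fread(tsv_path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  req <- c("read_name", "chromosome", "position", "called_allele", "quality")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0L) {
    stop("signal score TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    read_id = as.character(dt$read_name),
    chrom = as.character(dt$chromosome),
    snp_pos = as.integer(dt$position),
    called_allele = as.character(dt$called_allele),
    quality = as.numeric(dt$quality),
    stringsAsFactors = FALSE
  )
  bad <- !out$called_allele %in% c("ref", "alt")
  if (any(bad)) {
    warning("dropped ", sum(bad), " signal record(s) with invalid allele")
    out <- out[!bad, , drop = FALSE]
  }
  out[order(out$chrom, out$snp_pos), , drop = FALSE]
}

#' Write signal-level haplotype scores
#' @param records Data frame as returned by [read_signal_scores_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_scores_tsv <- function(records, path) {
  dt <- data.table::data.table(
    read_name = records$read_id,
    chromosome = records$chrom,
    position = records$snp_pos,
    called_allele = records$called_allele,
    quality = records$quality
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write ranked DMRs as BED6+
#'
#' Columns: chrom, start, end, name (= rank), score (= area statistic),
#' strand (`.`), then contrast label, number of sites and mean methylation
#' difference. Coordinates are 0-based half-open (BED convention, identical to
#' the internal one).
#'
#' @param dmrs Data frame of DMRs as returned by [call_dmrs()], sorted by rank.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  if (nrow(dmrs) > 1L) {
    ov <- unlist(lapply(split(dmrs, dmrs$chrom), function(d) {
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) < 2L) return(FALSE)
      any(d$start[-1L] < d$end[-nrow(d)])
    }))
    if (any(ov)) {
      warning("overlapping DMRs within one contrast")
    }
  }
  dt <- data.table::data.table(
    chrom = dmrs$chrom,
    start = dmrs$start,
    end = dmrs$end,
    name = dmrs$rank,
    score = dmrs$area_stat,
    strand = ".",
    contrast = dmrs$contrast,
    n_sites = dmrs$n_sites,
    mean_diff = dmrs$mean_diff
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmrs_bed()]
#' @param path Path to the BED file.
#' @return A `data.frame` with the same columns as [call_dmrs()] output.
#' @export
read_dmrs_bed <- function(path) {
  cols <- c("chrom", "start", "end", "rank", "area_stat", "strand",
            "contrast", "n_sites", "mean_diff")
  if (file.size(path) == 0L) {
    out <- data.frame(
      chrom = character(), start = integer(), end = integer(),
      rank = integer(), area_stat = numeric(), strand = character(),
      contrast = character(), n_sites = integer(), mean_diff = numeric(),
      stringsAsFactors = FALSE
    )
    return(out[setdiff(cols, "strand")])
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE, col.names = cols,
                          showProgress = FALSE)
  as.data.frame(dt[, !"strand"])
}

#' Write a bedGraph track
#' @param df Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @param track_name Optional track line name; omitted when `NULL`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  }
  writeLines(sprintf("%s\t%d\t%d\t%.6g", df$chrom, as.integer(df$start),
                     as.integer(df$end), df$value), con)
  invisible(path)
}

#' Read a per-site bisulfite methylation table
#'
#' Tab-separated with header columns `chromosome`, `position` (0-based
#' cytosine coordinate), `beta` and optionally `coverage`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `chrom`, `pos`, `beta`, `coverage`.
#' @export
read_bisulfite_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  req <- c("chromosome", "position", "beta")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0L) {
    stop("bisulfite TSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  data.frame(
    chrom = as.character(dt$chromosome),
    pos = as.integer(dt$position),
    beta = as.numeric(dt$beta),
    coverage = if ("coverage" %in% names(dt)) as.integer(dt$coverage) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Read gene intervals with expression-class labels
#'
#' BED6+1: chrom, start, end, name, score, strand, class. The class column
#' carries the expression-bias label used by [distance_to_nearest_dmr()]
#' (e.g. `"biased"` / `"unbiased"`).
#'
#' @param path Path to the BED file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `gene`,
#'   `class`.
#' @export
read_genes_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, showProgress = FALSE)
  if (ncol(dt) < 7L) {
    stop("gene BED must have 7 columns (BED6 + class label)")
  }
  data.frame(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]),
    end = as.integer(dt[[3]]),
    gene = as.character(dt[[4]]),
    class = as.character(dt[[7]]),
    stringsAsFactors = FALSE
  )
}
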