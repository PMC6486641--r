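# Resolution of grand-parental recombination: which contiguous segments of the
# maternal genome derive from the FVB chromosome rather than the reference
# (B6) background.

#' Three-way haplotype call for one read
#'
#' Runs the two-way haplotyping scorer independently against the CAST and the
#' FVB SNP tables. A read whose CAST call is the alternate haplotype is
#' paternal (`CAST`); among the remaining (maternal) reads, those whose FVB
#' call is alternate are `FVB`, others with informative evidence are `mm10`,
#' and reads overlapping fewer than `min_snps` SNPs of both tables are
#' `unassigned`.
#'
#' @param read One row of [read_alignments()] output.
#' @param snps_cast,snps_fvb SNP tables on the same reference.
#' @param min_snps Minimum informative SNP count (default 5).
#' @return One of `"mm10"`, `"FVB"`, `"CAST"`, `"unassigned"`.
#' @export
three_way_haplotype <- function(read, snps_cast, snps_fvb, min_snps = 5) {
  no_sig <- list(n = 0L, h = NA_real_, source = "signal")
  ev_cast <- aggregate_evidence(collect_basecall_observations(read, snps_cast))
  cc_cast <- combine_calls(ev_cast, no_sig, min_snps = min_snps)
  if (cc_cast$H == -1L) return("CAST")
  ev_fvb <- aggregate_evidence(collect_basecall_observations(read, snps_fvb))
  cc_fvb <- combine_calls(ev_fvb, no_sig, min_snps = min_snps)
  if (cc_fvb$H == -1L) return("FVB")
  if (cc_cast$H == 0L && cc_fvb$H == 0L) return("unassigned")
  "mm10"
}

#' Three-way haplotype calls for a set of reads
#'
#' @param reads Data frame of alignments.
#' @inheritParams three_way_haplotype
#' @return A `data.frame` with columns `read_id`, `chrom`, `start`, `end`,
#'   `label`.
#' @export
three_way_haplotype_reads <- function(reads, snps_cast, snps_fvb,
                                      min_snps = 5) {
  labels <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    labels[i] <- three_way_haplotype(reads[i, ], snps_cast, snps_fvb,
                                     min_snps = min_snps)
  }
  data.frame(read_id = reads$read_id, chrom = reads$chrom,
             start = reads$start, end = reads$end, label = labels,
             stringsAsFactors = FALSE)
}

#' Windowed FVB proportions among maternal reads
#'
#' Tiles each chromosome with fixed windows from coordinate 0 and assigns
#' each read to the window containing its alignment midpoint. The FVB
#' fraction is computed among maternal (non-CAST, assigned) reads only;
#' windows without maternal reads get `NA` and are omitted from the fit.
#'
#' @param labels Data frame from [three_way_haplotype_reads()].
#' @param window_size Window width in bp (default 100000).
#' @return A `data.frame` with columns `chrom`, `window_start`,
#'   `n_maternal_reads`, `fvb_fraction`.
#' @export
window_fvb_fractions <- function(labels, window_size = 100000) {
  mat <- labels[labels$label %in% c("mm10", "FVB"), , drop = FALSE]
  if (nrow(mat) == 0L) {
    return(data.frame(chrom = character(), window_start = integer(),
                      n_maternal_reads = integer(), fvb_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  mid <- (mat$start + mat$end) %/% 2L
  win <- as.integer((mid %/% window_size) * window_size)
  key <- paste(mat$chrom, win, sep = "\r")
  n_tot <- tapply(rep(1L, nrow(mat)), key, sum)
  n_fvb <- tapply(mat$label == "FVB", key, sum)
  parts <- do.call(rbind, strsplit(names(n_tot), "\r", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1],
    window_start = as.integer(parts[, 2]),
    n_maternal_reads = as.integer(n_tot),
    fvb_fraction = as.numeric(n_fvb) / as.numeric(n_tot),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best single split of y (ordered) by between/within sum of squares.
# Returns list(improve, at) where `at` is the index of the last left-hand
# point, or NULL if no split is possible.
.best_split <- function(y) {
  n <- length(y)
  if (n < 2L) return(NULL)
  ss <- function(v) if (length(v) < 2L) 0 else sum((v - mean(v))^2)
  node_ss <- ss(y)
  best <- list(improve = -Inf, at = NA_integer_)
  for (k in seq_len(n - 1L)) {
    imp <- node_ss - ss(y[1:k]) - ss(y[(k + 1):n])
    if (imp > best$improve) best <- list(improve = imp, at = k)
  }
  best
}

#' Piecewise-constant fit of windowed FVB proportions
#'
#' CART-style greedy recursive binary splitting on genomic coordinate (the
#' anova method of recursive partition trees): at each node the split
#' minimizing the within-segment sum of squares is accepted only if the node
#' holds at least `minsplit` windows and the split reduces the total sum of
#' squares by more than `cp` times the root sum of squares. Leaves become
#' segments, labelled `FVB` when their mean fraction exceeds 0.5. Segment
#' boundaries fall midway between adjacent window starts; the first/last
#' segments extend to the chromosome ends (0 and the last window start plus
#' one window).
#'
#' @param windows Data frame from [window_fvb_fractions()]; windows with
#'   undefined fraction are ignored.
#' @param minsplit Minimum number of windows in a node to attempt a split
#'   (default 5).
#' @param cp Complexity parameter: minimum improvement as a fraction of the
#'   root sum of squares (default 0.1).
#' @param window_size Window width used to close the final segment.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `mean_fvb`,
#'   `label` (`FVB`/`B6`), tiling each chromosome without overlap.
#' @export
fit_partition <- function(windows, minsplit = 5, cp = 0.1,
                          window_size = 100000) {
  windows <- windows[!is.na(windows$fvb_fraction), , drop = FALSE]
  if (nrow(windows) == 0L) {
    stop("fit_partition: no windows with defined FVB fraction")
  }
  out <- lapply(split(windows, windows$chrom), function(w) {
    w <- w[order(w$window_start), , drop = FALSE]
    y <- w$fvb_fraction
    x <- w$window_start
    root_ss <- sum((y - mean(y))^2)
    threshold <- cp * root_ss

    # recursive splitting over index ranges [lo, hi]
    segments <- list()
    recurse <- function(lo, hi) {
      n <- hi - lo + 1L
      if (n >= minsplit) {
        bs <- .best_split(y[lo:hi])
        if (!is.null(bs) && bs$improve > threshold) {
          recurse(lo, lo + bs$at - 1L)
          recurse(lo + bs$at, hi)
          return(invisible())
        }
      }
      segments[[length(segments) + 1L]] <<- c(lo, hi)
      invisible()
    }
    recurse(1L, length(y))
    segs <- do.call(rbind, segments)
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    # boundaries: midpoints between adjacent window starts at segment joins
    starts <- c(0L, as.integer((x[segs[-1, 1]] + x[segs[-1, 1] - 1L]) %/% 2L))
    ends <- c(starts[-1], as.integer(x[length(x)] + window_size))
    mean_fvb <- apply(segs, 1, function(s) mean(y[s[1]:s[2]]))
    data.frame(chrom = w$chrom[1], start = starts, end = ends,
               mean_fvb = mean_fvb,
               label = ifelse(mean_fvb > 0.5, "FVB", "B6"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Patch the maternal SNP table inside FVB segments
#'
#' Within FVB-labelled segments the maternal haplotype derives from the FVB
#' chromosome: maternal alleles are taken from the FVB table. SNPs of the
#' main table whose position carries an FVB variant get their maternal
#' (reference-side) allele replaced by the FVB allele; records that thereby
#' lose their distinction (maternal allele equal to the paternal allele) are
#' dropped; FVB-only positions become new informative records with the FVB
#' allele on the maternal side and the reference base on the paternal side.
#'
#' @param snps_main SNP table distinguishing maternal (`ref`) from paternal
#'   (`alt`) alleles, e.g. the CAST table.
#' @param snps_fvb FVB-vs-reference SNP table (`ref` = reference base,
#'   `alt` = FVB allele).
#' @param segments Data frame from [fit_partition()].
#' @return A patched SNP table sorted by (chromosome, position).
#' @export
swap_snps <- function(snps_main, snps_fvb, segments) {
  fvb_seg <- segments[segments$label == "FVB", , drop = FALSE]
  if (nrow(fvb_seg) == 0L) return(snps_main)

  in_seg <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(fvb_seg))) {
      hit <- hit | (chrom == fvb_seg$chrom[i] &
                      pos >= fvb_seg$start[i] & pos < fvb_seg$end[i])
    }
    hit
  }

  main_in <- in_seg(snps_main$chrom, snps_main$pos)
  fvb_in <- in_seg(snps_fvb$chrom, snps_fvb$pos)
  if (!any(fvb_in)) {
    warning("FVB segment(s) contain no FVB SNP records")
  }
  fvb_sub <- snps_fvb[fvb_in, , drop = FALSE]
  fvb_key <- paste(fvb_sub$chrom, fvb_sub$pos, sep = "\r")
  main_key <- paste(snps_main$chrom, snps_main$pos, sep = "\r")

  out <- snps_main
  # maternal allele replaced by FVB allele at shared positions inside segments
  hit <- main_in & main_key %in% fvb_key
  if (any(hit)) {
    out$ref[hit] <- fvb_sub$alt[match(main_key[hit], fvb_key)]
  }
  out <- out[out$ref != out$alt, , drop = FALSE]
  # FVB-only positions inside segments become informative maternal markers:
  # maternal = FVB allele, paternal = reference base
  only <- !(fvb_key %in% main_key)
  if (any(only)) {
    add <- data.frame(
      chrom = fvb_sub$chrom[only], pos = fvb_sub$pos[only],
      ref = fvb_sub$alt[only], alt = fvb_sub$ref[only],
      strain = snps_main$strain[1], stringsAsFactors = FALSE
    )
    out <- rbind(out, add)
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write partition segments as BED
#' @param segments Data frame from [fit_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g", segments$chrom,
                     as.integer(segments$start), as.integer(segments$end),
                     segments$label, segments$mean_fvb), con)
  invisible(path)
}
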