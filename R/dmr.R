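# Differential methylation between haplotype-samples: beta-binomial Wald test
# on arcsine-transformed pooled counts, region aggregation and ranking.

#' Build a methylation count matrix across haplotype-samples
#'
#' Rows are CpG call groups, columns are haplotype-samples (e.g. the maternal
#' and paternal alleles of each reciprocal cross). Per entry, `N` is the read
#' count and `X` the rounded sum of per-read methylation probabilities,
#' clamped to `[0, N]` — the probabilistic mass of methylated reads.
#'
#' @param summaries Named list of per-haplotype summary data frames (from
#'   [summarize_call_groups()], maternal/paternal subsets); names become
#'   sample ids.
#' @param round_beta When `FALSE`, `X` counts reads with `beta > 0.5` instead
#'   of rounding the probability mass.
#' @return A list with `sites` (data frame `chrom`, `start`, `end`), matrices
#'   `N` and `X` (sites x samples; `N = 0` where a sample lacks coverage) and
#'   `samples` (column names).
#' @export
build_count_matrix <- function(summaries, round_beta = TRUE) {
  stopifnot(length(names(summaries)) == length(summaries))
  keys <- unique(do.call(rbind, lapply(summaries, function(s) {
    s[c("chrom", "group_start", "group_end")]
  })))
  keys <- keys[order(keys$chrom, keys$group_start), , drop = FALSE]
  key_str <- paste(keys$chrom, keys$group_start, keys$group_end, sep = "\r")
  n_sites <- nrow(keys)
  n_samp <- length(summaries)
  N <- matrix(0L, n_sites, n_samp, dimnames = list(NULL, names(summaries)))
  X <- N
  for (j in seq_len(n_samp)) {
    s <- summaries[[j]]
    idx <- match(paste(s$chrom, s$group_start, s$group_end, sep = "\r"),
                 key_str)
    N[idx, j] <- s$n_reads
    xj <- if (round_beta) {
      as.integer(round(s$beta_sum))
    } else {
      if (is.null(s$n_methylated)) {
        stop("round_beta = FALSE requires an n_methylated column")
      }
      as.integer(s$n_methylated)
    }
    X[idx, j] <- pmin(pmax(xj, 0L), N[idx, j])
  }
  list(
    sites = data.frame(chrom = keys$chrom, start = keys$group_start,
                       end = keys$group_end, stringsAsFactors = FALSE),
    N = N, X = X, samples = names(summaries)
  )
}

# Method-of-moments dispersion per site, shrunk toward the genome-wide mean
# with weight n/(n+4) (n = number of samples); raw estimates are clamped to
# [0, 1]. Degenerate sites inherit the genome-wide mean.
.estimate_dispersion <- function(N, X, g1, g2) {
  phat <- X / N
  wvar <- function(cols) {
    m <- phat[, cols, drop = FALSE]
    nn <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(nn - 1, 1)
    v[nn < 2] <- NA_real_
    v
  }
  s2 <- rowMeans(cbind(wvar(g1), wvar(g2)), na.rm = TRUE)
  Nh <- 1 / rowMeans(1 / pmax(N, 1), na.rm = TRUE)   # harmonic mean coverage
  pbar <- (rowSums(X) + 0.5) / (rowSums(N) + 1)
  phi_raw <- (Nh * s2 / (pbar * (1 - pbar)) - 1) / pmax(Nh - 1, 1)
  phi_raw <- pmin(pmax(phi_raw, 0), 1)
  phi_mean <- mean(phi_raw, na.rm = TRUE)
  if (!is.finite(phi_mean)) phi_mean <- 0
  n_samp <- length(g1) + length(g2)
  w <- n_samp / (n_samp + 4)
  phi <- w * phi_raw + (1 - w) * phi_mean
  phi[is.na(phi)] <- phi_mean
  phi
}

#' Beta-binomial Wald test per CpG call group
#'
#' Two-group comparison of methylation counts with an arcsine link. Counts
#' are pooled within each group (the two-group design of DSS):
#' `Y_g = arcsin(2 p_g - 1)` with `p_g = (X_g + 0.5) / (N_g + 1)`; the
#' variance of `Y_g` follows by the delta method from the beta-binomial count
#' variance `N_g p(1-p)(1 + (n̄ - 1) φ)` (with `n̄` the mean per-sample
#' coverage and `φ` the shrunk site dispersion), with the curvature factor
#' evaluated at the adjusted estimate. The Wald statistic is the difference
#' of the transformed group proportions over its standard error; p-values are
#' two-sided standard normal.
#'
#' @param counts Count matrix list from [build_count_matrix()].
#' @param group1,group2 Column names (or indices) of the two groups.
#' @return A `data.frame` with one row per site: `chrom`, `start`, `end`,
#'   `effect` (group1 − group2 on the proportion scale), `wald_stat`,
#'   `p_value`, `dispersion`. Sites with a group entirely uncovered are
#'   dropped.
#' @export
test_sites <- function(counts, group1, group2) {
  N <- counts$N
  X <- counts$X
  if (is.character(group1)) group1 <- match(group1, colnames(N))
  if (is.character(group2)) group2 <- match(group2, colnames(N))
  if (anyNA(group1) || anyNA(group2)) {
    stop("unknown sample column in contrast; available: ",
         paste(colnames(N), collapse = ", "))
  }
  keep <- rowSums(N[, group1, drop = FALSE]) > 0 &
    rowSums(N[, group2, drop = FALSE]) > 0
  N <- N[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  Nna <- N
  Nna[Nna == 0L] <- NA_integer_
  phi <- .estimate_dispersion(Nna, X, group1, group2)

  grp <- function(cols) {
    Ng <- rowSums(N[, cols, drop = FALSE])
    Xg <- rowSums(X[, cols, drop = FALSE])
    pg <- (Xg + 0.5) / (Ng + 1)
    nbar <- Ng / rowSums(N[, cols, drop = FALSE] > 0)
    m <- (Ng * pg + 0.5) / (Ng + 1)
    v <- Ng * pg * (1 - pg) * (1 + (nbar - 1) * phi) /
      ((Ng + 1)^2 * m * (1 - m))
    list(Y = asin(2 * pg - 1), v = v, p = pg)
  }
  a <- grp(group1)
  b <- grp(group2)
  wald <- (a$Y - b$Y) / sqrt(a$v + b$v)
  data.frame(
    chrom = counts$sites$chrom[keep],
    start = counts$sites$start[keep],
    end = counts$sites$end[keep],
    effect = a$p - b$p,
    wald_stat = wald,
    p_value = 2 * pnorm(-abs(wald)),
    dispersion = phi,
    stringsAsFactors = FALSE
  )
}

#' Aggregate significant sites into ranked DMRs
#'
#' Significant sites (`p < p_threshold`) are clustered: a new region starts
#' whenever the gap to the previous significant site exceeds `merge_gap` or
#' the effect changes sign. A region spans its first to last significant
#' site and is kept when it contains at least `min_sites` tested sites, is at
#' least `min_len` long, and at least `min_frac_significant` of its member
#' sites are significant. The area statistic is the sum of Wald statistics
#' over all member sites; regions are ranked by its absolute value,
#' descending.
#'
#' @param results Site test results from [test_sites()], sorted by
#'   coordinate.
#' @param p_threshold Site significance threshold (default 1e-5).
#' @param min_sites Minimum member sites per region (default 3).
#' @param min_len Minimum region length in bp (default 50).
#' @param merge_gap Maximum separation between consecutive significant sites
#'   (default 100).
#' @param min_frac_significant Minimum fraction of significant member sites
#'   (default 0.5).
#' @param contrast Label attached to the output rows.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `n_sites`,
#'   `n_significant`, `area_stat`, `mean_diff`, `rank`, `contrast`, sorted by
#'   rank.
#' @export
call_dmrs <- function(results, p_threshold = 1e-5, min_sites = 3,
                      min_len = 50, merge_gap = 100,
                      min_frac_significant = 0.5, contrast = "unspecified") {
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    n_sites = integer(), n_significant = integer(), area_stat = numeric(),
    mean_diff = numeric(), rank = integer(), contrast = character(),
    stringsAsFactors = FALSE
  )
  if (nrow(results) == 0L) return(empty)
  regions <- list()
  for (ch in unique(results$chrom)) {
    r <- results[results$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    sig <- which(r$p_value < p_threshold)
    if (length(sig) == 0L) next
    gap_break <- c(TRUE, r$start[sig[-1]] - r$end[sig[-length(sig)]] > merge_gap)
    sign_break <- c(TRUE, diff(sign(r$effect[sig])) != 0)
    cl <- cumsum(gap_break | sign_break)
    for (k in unique(cl)) {
      s <- sig[cl == k]
      span_start <- r$start[s[1]]
      span_end <- r$end[s[length(s)]]
      memb <- which(r$start >= span_start & r$end <= span_end)
      n_memb <- length(memb)
      if (n_memb < min_sites) next
      if (span_end - span_start < min_len) next
      if (length(s) / n_memb < min_frac_significant) next
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = span_start, end = span_end,
        n_sites = n_memb, n_significant = length(s),
        area_stat = sum(r$wald_stat[memb]),
        mean_diff = mean(r$effect[memb]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(regions) == 0L) return(empty)
  out <- do.call(rbind, regions)
  out <- out[order(-abs(out$area_stat)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$contrast <- contrast
  rownames(out) <- NULL
  out
}

#' Run the parent-of-origin and strain contrasts
#'
#' With the four haplotype-samples of a reciprocal cross design (maternal and
#' paternal alleles of cross 1 and cross 2), parent-of-origin DMRs come from
#' comparing the two maternal against the two paternal samples, and
#' strain DMRs from comparing the two first-strain against the two
#' second-strain samples.
#'
#' @param counts Count matrix from [build_count_matrix()].
#' @param parent Named character vector mapping each sample to
#'   `"maternal"`/`"paternal"`.
#' @param strain Named character vector mapping each sample to its strain.
#' @param ... Passed to [call_dmrs()].
#' @return A list with elements `parent_of_origin` and `strain`, each a list
#'   of `sites` (test results) and `dmrs`.
#' @export
run_contrasts <- function(counts, parent, strain, ...) {
  samp <- counts$samples
  if (!all(samp %in% names(parent)) || !all(samp %in% names(strain))) {
    stop("design incomplete: need parent and strain for samples ",
         paste(samp, collapse = ", "))
  }
  po_g1 <- samp[parent[samp] == "maternal"]
  po_g2 <- samp[parent[samp] == "paternal"]
  strains <- unique(strain[samp])
  if (length(po_g1) == 0L || length(po_g2) == 0L || length(strains) != 2L) {
    stop("design must contain maternal and paternal samples of two strains")
  }
  st_g1 <- samp[strain[samp] == strains[1]]
  st_g2 <- samp[strain[samp] == strains[2]]
  po_sites <- test_sites(counts, po_g1, po_g2)
  st_sites <- test_sites(counts, st_g1, st_g2)
  list(
    parent_of_origin = list(
      sites = po_sites,
      dmrs = call_dmrs(po_sites, contrast = "parent_of_origin", ...)
    ),
    strain = list(
      sites = st_sites,
      dmrs = call_dmrs(st_sites, contrast = "strain", ...)
    )
  )
}

#' Distance from genes to their nearest DMR
#'
#' Uses the top `top_k` DMRs by rank. Distance is 0 for overlaps, otherwise
#' the gap between closest edges. Genes on chromosomes absent from the DMR
#' list get infinite distance and are excluded from the per-class medians
#' with a warning.
#'
#' @param genes Data frame with columns `chrom`, `start`, `end`, `gene`,
#'   `class`.
#' @param dmrs Ranked DMR data frame from [call_dmrs()].
#' @param top_k Number of top-ranked DMRs to use (default 400).
#' @return A list with `table` (per-gene `distance`) and `medians` (named by
#'   gene class).
#' @export
distance_to_nearest_dmr <- function(genes, dmrs, top_k = 400) {
  d <- dmrs[dmrs$rank <= top_k, , drop = FALSE]
  if (nrow(d) == 0L) stop("no DMRs to compute distances against")
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  gr_d <- GenomicRanges::GRanges(d$chrom,
                                 IRanges::IRanges(d$start + 1, d$end))
  hits <- GenomicRanges::distanceToNearest(gr_g, gr_d)
  dist <- rep(Inf, nrow(genes))
  dist[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (any(is.infinite(dist))) {
    warning(sum(is.infinite(dist)),
            " gene(s) on chromosomes without DMRs excluded from medians")
  }
  tab <- data.frame(gene = genes$gene, class = genes$class, distance = dist,
                    stringsAsFactors = FALSE)
  fin <- tab[is.finite(tab$distance), , drop = FALSE]
  medians <- tapply(fin$distance, fin$class, median)
  list(table = tab, medians = medians)
}
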