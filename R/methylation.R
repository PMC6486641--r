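# Per-read methylation probabilities over chained CpG call groups, haplotype
# aggregation and bisulfite concordance.

#' Single-read, single-group methylation probability
#'
#' Bayes conversion of the methylated/unmethylated likelihood pair into a
#' posterior probability under a prior `p0` of methylation:
#' `beta = 1 / (1 + ((1 - p0)/p0) * L_C / L_M)`, computed in log space so that
#' arbitrarily large log-likelihood ratios are handled without overflow.
#' Infinite ratios give exactly 1 or 0.
#'
#' @param log_lik_methylated,log_lik_unmethylated Log-likelihoods (nats);
#'   vectors are recycled together.
#' @param p0 Prior probability of methylation in `(0, 1)`; default 0.5 as
#'   appropriate for placental tissue whose global methylation level is near
#'   50%.
#' @return Probabilities in `[0, 1]`.
#' @export
beta_from_likelihoods <- function(log_lik_methylated, log_lik_unmethylated,
                                  p0 = 0.5) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)")
  llr <- log_lik_methylated - log_lik_unmethylated
  z <- llr - log((1 - p0) / p0)
  # evaluate on |z| and mirror so that beta(z) + beta(-z) is exactly 1
  b <- stats::plogis(abs(z))
  ifelse(z >= 0, b, 1 - b)
}

#' Attach beta probabilities to methylation records
#' @param records Data frame from [read_methylation_tsv()].
#' @param p0 Methylation prior, see [beta_from_likelihoods()].
#' @return `records` with a `beta` column.
#' @export
add_beta <- function(records, p0 = 0.5) {
  records$beta <- beta_from_likelihoods(records$log_lik_methylated,
                                        records$log_lik_unmethylated, p0)
  records
}

#' Chain CpG sites into call groups
#'
#' Greedy left-to-right chaining: adjacent sites closer than `max_gap` bases
#' join the same group (6-mer contexts of such sites overlap, so they share
#' one methylation call). Equivalent to transitive closure of the
#' "distance < max_gap" relation on sorted positions.
#'
#' @param positions Sorted, deduplicated 0-based CpG cytosine positions.
#' @param max_gap Sites with distance strictly less than this chain together
#'   (default 11).
#' @return Integer vector of group ids (1-based, consecutive), parallel to
#'   `positions`.
#' @export
chain_call_groups <- function(positions, max_gap = 11) {
  n <- length(positions)
  if (n == 0L) return(integer())
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be sorted and deduplicated")
  }
  cumsum(c(1L, as.integer(diff(positions) >= max_gap)))
}

#' Call-group spans from positions and group ids
#'
#' @param positions Sorted CpG positions.
#' @param groups Group ids from [chain_call_groups()].
#' @return A `data.frame` with columns `group`, `start` (first site),
#'   `end` (last site + 1, half-open), `n_sites`.
#' @export
call_group_spans <- function(positions, groups) {
  first <- tapply(positions, groups, min)
  last <- tapply(positions, groups, max)
  n <- tapply(positions, groups, length)
  data.frame(group = as.integer(names(first)),
             start = as.integer(first), end = as.integer(last) + 1L,
             n_sites = as.integer(n))
}

#' Mean methylation of one call group on one haplotype
#'
#' @param betas Per-read probabilities for the records of one group and
#'   haplotype.
#' @return A list with `n_reads`, `beta_mean` and `beta_sum`, or `NULL` when
#'   there are no records.
#' @export
aggregate_group <- function(betas) {
  betas <- betas[!is.na(betas)]
  if (length(betas) == 0L) return(NULL)
  list(n_reads = length(betas), beta_mean = mean(betas), beta_sum = sum(betas))
}

#' Aggregate per-read methylation over call groups and haplotypes
#'
#' Joins methylation records with per-read haplotype assignments and computes
#' the call-group average probability per haplotype. Reads with `H = 0`
#' contribute to the `all` summary but to neither parental haplotype.
#'
#' @param records Methylation records with a `beta` column (see [add_beta()]).
#' @param assignments Per-read haplotype assignments from [haplotype_reads()],
#'   or `NULL` to aggregate all reads without haplotype splitting.
#' @param maternal_is_ref Cross orientation: `TRUE` when the reference (first)
#'   haplotype (`H = +1`) is maternal, as in a B6xCast cross on a B6-based
#'   reference.
#' @return A `data.frame` with columns `chrom`, `group_start`, `group_end`,
#'   `haplotype` (`maternal`/`paternal`/`all`), `n_reads`, `beta_mean`,
#'   `beta_sum`.
#' @export
summarize_call_groups <- function(records, assignments = NULL,
                                  maternal_is_ref = TRUE) {
  dt <- data.table::as.data.table(
    records[c("chrom", "group_start", "group_end", "read_id", "beta")]
  )
  if (is.null(assignments)) {
    dt[, H := 0L]
  } else {
    idx <- match(dt$read_id, assignments$read_id)
    dt[, H := assignments$H[idx]]
    dt <- dt[!is.na(H)]
  }
  mat_h <- if (maternal_is_ref) 1L else -1L
  agg <- function(d, label) {
    if (nrow(d) == 0L) return(NULL)
    s <- d[, .(n_reads = .N, beta_mean = mean(beta), beta_sum = sum(beta),
               n_methylated = sum(beta > 0.5)),
           by = .(chrom, group_start, group_end)]
    s[, haplotype := label]
    s
  }
  out <- data.table::rbindlist(list(
    agg(dt, "all"),
    agg(dt[H == mat_h], "maternal"),
    agg(dt[H == -mat_h], "paternal")
  ))
  data.table::setcolorder(out, c("chrom", "group_start", "group_end",
                                 "haplotype", "n_reads", "beta_mean",
                                 "beta_sum", "n_methylated"))
  data.table::setorder(out, chrom, group_start, haplotype)
  as.data.frame(out)
}

#' Split call-group summaries into per-site rows
#'
#' For comparison with bisulfite calls each CpG site of a group is emitted
#' individually — the forward-strand cytosine and its reverse-strand
#' counterpart at `position + 1` — all inheriting the group's beta value.
#'
#' @param summaries Data frame from [summarize_call_groups()] (one haplotype
#'   at a time) with `beta_mean` per group.
#' @param cpg_positions Data frame with columns `chrom`, `pos` listing all
#'   CpG cytosine positions; group membership is recomputed from the group
#'   spans.
#' @return A `data.frame` with columns `chrom`, `pos`, `beta` containing two
#'   rows per CpG site of every group.
#' @export
split_groups_to_sites <- function(summaries, cpg_positions) {
  res <- vector("list", length(unique(summaries$chrom)))
  k <- 0L
  for (ch in unique(summaries$chrom)) {
    s <- summaries[summaries$chrom == ch, , drop = FALSE]
    pos <- sort(cpg_positions$pos[cpg_positions$chrom == ch])
    # map each group span to its member sites
    lo <- findInterval(s$group_start - 1L, pos) + 1L
    hi <- findInterval(s$group_end - 1L, pos)
    n_sites <- pmax(hi - lo + 1L, 0L)
    idx <- sequence(n_sites, from = lo)
    site_pos <- pos[idx]
    beta <- rep(s$beta_mean, n_sites)
    k <- k + 1L
    res[[k]] <- data.frame(
      chrom = ch,
      pos = c(site_pos, site_pos + 1L),
      beta = c(beta, beta),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Concordance between nanopore and bisulfite per-site calls
#'
#' Restricted to sites present in both inputs. Reports the median absolute
#' deviation of the per-site difference, the four quadrant fractions under
#' the binary thresholds (nanopore default 0.36, bisulfite 0.5; a site is
#' "methylated" when its value exceeds the threshold) and the concordant
#' fraction.
#'
#' @param nanopore_sites,rrbs_sites Data frames with columns `chrom`, `pos`,
#'   `beta`.
#' @param nanopore_threshold,rrbs_threshold Binary call thresholds.
#' @return A list with `n_sites`, `median_absolute_deviation`,
#'   `quadrant_fractions` (named `low_low`, `low_high`, `high_low`,
#'   `high_high`; nanopore first) and `binary_agreement`.
#' @export
compare_with_bisulfite <- function(nanopore_sites, rrbs_sites,
                                   nanopore_threshold = 0.36,
                                   rrbs_threshold = 0.5) {
  key_n <- paste(nanopore_sites$chrom, nanopore_sites$pos, sep = "\r")
  key_r <- paste(rrbs_sites$chrom, rrbs_sites$pos, sep = "\r")
  shared <- intersect(key_n, key_r)
  if (length(shared) == 0L) {
    stop("no CpG sites shared between nanopore and bisulfite inputs")
  }
  b_n <- nanopore_sites$beta[match(shared, key_n)]
  b_r <- rrbs_sites$beta[match(shared, key_r)]
  hi_n <- b_n > nanopore_threshold
  hi_r <- b_r > rrbs_threshold
  quad <- c(
    low_low = mean(!hi_n & !hi_r),
    low_high = mean(!hi_n & hi_r),
    high_low = mean(hi_n & !hi_r),
    high_high = mean(hi_n & hi_r)
  )
  list(
    n_sites = length(shared),
    median_absolute_deviation = median(abs(b_n - b_r)),
    quadrant_fractions = quad,
    binary_agreement = unname(quad["low_low"] + quad["high_high"])
  )
}
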