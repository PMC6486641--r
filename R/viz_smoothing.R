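# Per-read loess smoothing of methylation tracks for haplotype-split
# visualization.

#' Loess span for a read of a given length
#'
#' `alpha = 0.1 + 8e-11 * (max(1e5 - L, 0))^2`: short reads get wide spans
#' (up to 0.9 at L = 0), reads of 100 kb and beyond get the floor 0.1. The
#' relationship trades smoothing quality against computation time and is
#' non-increasing in read length.
#'
#' @param L Read length(s) in bases.
#' @return Span value(s) in `(0, 1]`.
#' @export
loess_alpha <- function(L) {
  0.1 + 8e-11 * pmax(1e5 - L, 0)^2
}

#' Smooth the methylation profile of a single read
#'
#' Local linear (degree 1, tricube-weighted) loess fit of per-group beta
#' values against genomic position, evaluated at each call-group midpoint,
#' with span [loess_alpha()] of the read length clamped to
#' `[2/n_points, 1]`. Smoothed values are clipped to `[0, 1]`. Reads with
#' fewer than two call groups are returned unsmoothed.
#'
#' @param positions Call-group midpoints (0-based) of one read.
#' @param betas Per-group methylation probabilities of the read.
#' @param read_length Read length `L` in bases; when `NULL` it is taken as
#'   the span of `positions`.
#' @return A `data.frame` with columns `pos`, `beta_raw`, `beta_smooth`;
#'   the span used is in `attr(x, "alpha")`.
#' @export
smooth_read <- function(positions, betas, read_length = NULL) {
  o <- order(positions)
  positions <- positions[o]
  betas <- betas[o]
  if (is.null(read_length)) {
    read_length <- diff(range(positions)) + 1L
  }
  alpha <- loess_alpha(read_length)
  n <- length(positions)
  if (n < 2L) {
    out <- data.frame(pos = positions, beta_raw = betas, beta_smooth = betas)
    attr(out, "alpha") <- alpha
    return(out)
  }
  span <- min(max(alpha, 2 / n), 1)
  sm <- tryCatch({
    fit <- suppressWarnings(
      loess(betas ~ positions, degree = 1, span = span, family = "gaussian",
            control = loess.control(surface = "direct"))
    )
    as.numeric(predict(fit, positions))
  }, error = function(e) betas)
  out <- data.frame(pos = positions, beta_raw = betas,
                    beta_smooth = pmin(pmax(sm, 0), 1))
  attr(out, "alpha") <- alpha
  out
}

#' Smoothed tracks for all reads of a haplotype
#'
#' @param records Methylation records with `beta` (see [add_beta()]).
#' @param assignments Optional haplotype assignments; when given, a
#'   `haplotype` column (maternal/paternal/unassigned) is attached.
#' @param maternal_is_ref Cross orientation, as in
#'   [summarize_call_groups()].
#' @return A `data.frame` with columns `read_id`, `haplotype`, `pos`,
#'   `beta_raw`, `beta_smooth`.
#' @export
smooth_reads <- function(records, assignments = NULL,
                         maternal_is_ref = TRUE) {
  hap_of <- function(ids) {
    if (is.null(assignments)) return(rep("all", length(ids)))
    H <- assignments$H[match(ids, assignments$read_id)]
    mat_h <- if (maternal_is_ref) 1L else -1L
    ifelse(is.na(H) | H == 0L, "unassigned",
           ifelse(H == mat_h, "maternal", "paternal"))
  }
  parts <- lapply(split(records, records$read_id), function(r) {
    mid <- (r$group_start + r$group_end) %/% 2L
    sm <- smooth_read(mid, r$beta,
                      read_length = max(r$group_end) - min(r$group_start))
    data.frame(read_id = r$read_id[1], pos = sm$pos, beta_raw = sm$beta_raw,
               beta_smooth = sm$beta_smooth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out$haplotype <- hap_of(out$read_id)
  rownames(out) <- NULL
  out[c("read_id", "haplotype", "pos", "beta_raw", "beta_smooth")]
}
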