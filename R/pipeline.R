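# End-to-end orchestration over the in-memory simulator, and the command-line
# entry point.

#' Run the full pipeline on a simulated reciprocal-cross design
#'
#' Simulates a shared genome and two reciprocal pseudo-crosses, haplotypes
#' every read from both evidence streams, converts methylation likelihoods to
#' probabilities, aggregates call groups per haplotype, tests the
#' parent-of-origin and strain contrasts, and compares the unhaplotyped
#' nanopore calls against simulated bisulfite data. All declared outputs are
#' written under `out_dir` deterministically for a given config seed.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory, created if needed.
#' @return A list with `assignments` (per cross), `evaluation` (haplotyping
#'   metrics per cross), `contrasts` (site tests and DMRs), `concordance`,
#'   `truth` and `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome_and_snps(config)
  crosses <- c("B6xCast", "CastxB6")
  summaries <- list()
  assignments <- list()
  evaluation <- list()
  files <- list()
  all_sites_c1 <- NULL

  for (k in seq_along(crosses)) {
    cr <- crosses[k]
    tag <- tolower(cr)
    sim <- simulate_reads(config, genome, cross = cr, seed_offset = 10L * k)
    sig <- simulate_signal_scores(config, genome, sim,
                                  seed_offset = 10L * k + 1L)
    meth <- simulate_methylation_llrs(config, genome, sim,
                                      seed_offset = 10L * k + 2L)
    hap <- haplotype_reads(sim$reads, genome$snps_cast, signal = sig)
    evaluation[[cr]] <- evaluate_assignments(hap, sim$truth$H_true)
    assignments[[cr]] <- hap
    files[[paste0("haplotypes_", tag)]] <-
      write_haplotypes_tsv(hap, file.path(out_dir,
                                          paste0(tag, "_haplotypes.tsv")))
    meth <- add_beta(meth)
    maternal_is_ref <- cr == "B6xCast"
    s <- summarize_call_groups(meth, hap, maternal_is_ref = maternal_is_ref)
    summaries[[paste0("mat_c", k)]] <-
      s[s$haplotype == "maternal", , drop = FALSE]
    summaries[[paste0("pat_c", k)]] <-
      s[s$haplotype == "paternal", , drop = FALSE]
    for (hp in c("maternal", "paternal")) {
      sh <- s[s$haplotype == hp, , drop = FALSE]
      files[[paste0(tag, "_", hp)]] <- write_bedgraph(
        data.frame(chrom = sh$chrom, start = sh$group_start,
                   end = sh$group_end, value = sh$beta_mean),
        file.path(out_dir, paste0(tag, "_", hp, ".bedgraph"))
      )
    }
    if (k == 1L) {
      all_sites_c1 <- split_groups_to_sites(
        s[s$haplotype == "all", , drop = FALSE], genome$cpg
      )
    }
  }

  counts <- build_count_matrix(summaries)
  parent <- c(mat_c1 = "maternal", pat_c1 = "paternal",
              mat_c2 = "maternal", pat_c2 = "paternal")
  strain <- c(mat_c1 = "first", pat_c1 = "second",
              mat_c2 = "second", pat_c2 = "first")
  contrasts <- run_contrasts(counts, parent, strain)
  files$dmrs_parent_of_origin <- write_dmrs_bed(
    contrasts$parent_of_origin$dmrs,
    file.path(out_dir, "dmrs_parent_of_origin.bed")
  )
  files$dmrs_strain <- write_dmrs_bed(
    contrasts$strain$dmrs, file.path(out_dir, "dmrs_strain.bed")
  )

  bis <- simulate_bisulfite(config, genome)
  concordance <- compare_with_bisulfite(all_sites_c1, bis)
  files$concordance <- file.path(out_dir, "concordance.json")
  jsonlite::write_json(concordance, files$concordance, auto_unbox = TRUE,
                       digits = NA)

  list(assignments = assignments, evaluation = evaluation,
       contrasts = contrasts, concordance = concordance,
       truth = list(genome = genome,
                    methylation = true_methylation_table(config, genome)),
       files = files)
}

#' Overlap-based recovery of planted DMRs
#'
#' A planted region counts as recovered when at least one called DMR of the
#' matching contrast overlaps it by at least one base.
#'
#' @param planted Data frame of planted DMRs (`start`, `end`, `contrast`).
#' @param dmrs Called DMR data frame.
#' @param contrast Which planted contrast to evaluate.
#' @return A list with `n_planted`, `n_recovered` and `recovered` (logical
#'   per planted region).
#' @export
dmr_recovery <- function(planted, dmrs, contrast = "parent_of_origin") {
  p <- planted[planted$contrast == contrast, , drop = FALSE]
  rec <- vapply(seq_len(nrow(p)), function(i) {
    any(dmrs$start < p$end[i] & dmrs$end > p$start[i])
  }, logical(1))
  list(n_planted = nrow(p), n_recovered = sum(rec), recovered = rec)
}

# ---------------------------------------------------------------------------
# Command-line interface: thin wrappers over the exported functions.

.cli_usage <- paste(
  "usage: haplomet <subcommand> [--flag value ...]",
  "",
  "subcommands:",
  "  simulate              --out-dir D [--seed N] [--genome-length L]",
  "                        [--coverage C]",
  "  haplotype             --bam F --vcf F --out F [--signal F]",
  "                        [--min-snps 5] [--ratio 3]",
  "  resolve-recombination --bam F --vcf-cast F --vcf-fvb F",
  "                        --out-segments F [--out-snps F] [--minsplit 5]",
  "                        [--cp 0.1] [--window 100000]",
  "  call-methylation      --meth F --haplotypes F --out-prefix P [--p0 0.5]",
  "                        [--cross B6xCast]",
  "  detect-dmr            --meth1 F --hap1 F --meth2 F --hap2 F",
  "                        --out-prefix P [--p0 0.5] [--p-threshold 1e-5]",
  "  compare-rrbs          --meth F --bisulfite F --cpg F --out F [--p0 0.5]",
  "                        [--nanopore-threshold 0.36] [--rrbs-threshold 0.5]",
  "  distance              --genes F --dmrs F --out F [--top-k 400]",
  "  smooth                --meth F --out F [--haplotypes F] [--p0 0.5]",
  sep = "\n"
)

.cli_parse <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i == length(args)) stop("missing value for flag ", a)
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.cli_need <- function(flags, keys) {
  miss <- setdiff(keys, names(flags))
  if (length(miss) > 0L) {
    stop("missing required flag(s): ", paste0("--", miss, collapse = ", "))
  }
}

.cli_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

.cli_load_per_site <- function(meth_path, cpg_path, p0, hap_path = NULL,
                               haplotype = "all", cross = "B6xCast") {
  meth <- add_beta(read_methylation_tsv(meth_path), p0 = p0)
  hap <- if (is.null(hap_path)) NULL else read_haplotypes_tsv(hap_path)
  s <- summarize_call_groups(meth, hap,
                             maternal_is_ref = cross == "B6xCast")
  cpg_dt <- data.table::fread(cpg_path, sep = "\t", header = TRUE,
                              showProgress = FALSE)
  cpg <- data.frame(chrom = as.character(cpg_dt$chromosome),
                    pos = as.integer(cpg_dt$position),
                    stringsAsFactors = FALSE)
  split_groups_to_sites(s[s$haplotype == haplotype, , drop = FALSE], cpg)
}

# Per-cross maternal/paternal summaries from a methylation TSV and a
# haplotype TSV.
.cli_cross_summaries <- function(meth_path, hap_path, p0, cross) {
  meth <- add_beta(read_methylation_tsv(meth_path), p0 = p0)
  hap <- read_haplotypes_tsv(hap_path)
  s <- summarize_call_groups(meth, hap,
                             maternal_is_ref = cross == "B6xCast")
  list(maternal = s[s$haplotype == "maternal", , drop = FALSE],
       paternal = s[s$haplotype == "paternal", , drop = FALSE])
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented in the usage string. Intended to be
#' called from the installed `haplomet` script via
#' `Rscript -e 'quit(status = haplomet::cli_main())'`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success, 2 on usage errors).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    message(.cli_usage)
    return(if (length(args) == 0L) 2L else 0L)
  }
  sub <- args[1]
  res <- tryCatch({
    flags <- .cli_parse(args[-1])
    switch(
      sub,
      simulate = {
        .cli_need(flags, "out-dir")
        config <- sim_config(
          seed = as.integer(.cli_num(flags, "seed", 1)),
          genome_length = .cli_num(flags, "genome-length", 2e6),
          coverage = .cli_num(flags, "coverage", 10)
        )
        paths <- write_fixture_set(config, flags[["out-dir"]])
        message("wrote ", length(paths), " fixture files to ",
                flags[["out-dir"]])
        0L
      },
      haplotype = {
        .cli_need(flags, c("bam", "vcf", "out"))
        reads <- read_alignments(flags$bam)
        snps <- read_snp_table(flags$vcf, "ALT")
        signal <- if (is.null(flags$signal)) NULL else
          read_signal_scores_tsv(flags$signal)
        hap <- haplotype_reads(reads, snps, signal = signal,
                               min_snps = .cli_num(flags, "min-snps", 5),
                               ratio = .cli_num(flags, "ratio", 3))
        write_haplotypes_tsv(hap, flags$out)
        message(sum(hap$H != 0L), "/", nrow(hap), " reads haplotyped")
        0L
      },
      `resolve-recombination` = {
        .cli_need(flags, c("bam", "vcf-cast", "vcf-fvb", "out-segments"))
        reads <- read_alignments(flags$bam)
        snps_cast <- read_snp_table(flags[["vcf-cast"]], "CAST")
        snps_fvb <- read_snp_table(flags[["vcf-fvb"]], "FVB")
        labels <- three_way_haplotype_reads(reads, snps_cast, snps_fvb)
        w <- window_fvb_fractions(labels,
                                  window_size = .cli_num(flags, "window",
                                                         100000))
        seg <- fit_partition(w, minsplit = .cli_num(flags, "minsplit", 5),
                             cp = .cli_num(flags, "cp", 0.1),
                             window_size = .cli_num(flags, "window", 100000))
        write_segments_bed(seg, flags[["out-segments"]])
        if (!is.null(flags[["out-snps"]])) {
          patched <- swap_snps(snps_cast, snps_fvb, seg)
          write_snp_vcf(patched, flags[["out-snps"]])
        }
        message(nrow(seg), " segment(s), ",
                sum(seg$label == "FVB"), " FVB")
        0L
      },
      `call-methylation` = {
        .cli_need(flags, c("meth", "haplotypes", "out-prefix"))
        p0 <- .cli_num(flags, "p0", 0.5)
        cross <- if (is.null(flags$cross)) "B6xCast" else flags$cross
        s <- .cli_cross_summaries(flags$meth, flags$haplotypes, p0, cross)
        for (hp in names(s)) {
          write_bedgraph(
            data.frame(chrom = s[[hp]]$chrom, start = s[[hp]]$group_start,
                       end = s[[hp]]$group_end, value = s[[hp]]$beta_mean),
            paste0(flags[["out-prefix"]], "_", hp, ".bedgraph")
          )
        }
        0L
      },
      `detect-dmr` = {
        .cli_need(flags, c("meth1", "hap1", "meth2", "hap2", "out-prefix"))
        p0 <- .cli_num(flags, "p0", 0.5)
        s1 <- .cli_cross_summaries(flags$meth1, flags$hap1, p0, "B6xCast")
        s2 <- .cli_cross_summaries(flags$meth2, flags$hap2, p0, "CastxB6")
        counts <- build_count_matrix(list(
          mat_c1 = s1$maternal, pat_c1 = s1$paternal,
          mat_c2 = s2$maternal, pat_c2 = s2$paternal
        ))
        contrasts <- run_contrasts(
          counts,
          parent = c(mat_c1 = "maternal", pat_c1 = "paternal",
                     mat_c2 = "maternal", pat_c2 = "paternal"),
          strain = c(mat_c1 = "first", pat_c1 = "second",
                     mat_c2 = "second", pat_c2 = "first"),
          p_threshold = .cli_num(flags, "p-threshold", 1e-5)
        )
        write_dmrs_bed(contrasts$parent_of_origin$dmrs,
                       paste0(flags[["out-prefix"]],
                              "_parent_of_origin.bed"))
        write_dmrs_bed(contrasts$strain$dmrs,
                       paste0(flags[["out-prefix"]], "_strain.bed"))
        message(nrow(contrasts$parent_of_origin$dmrs),
                " parent-of-origin DMR(s), ",
                nrow(contrasts$strain$dmrs), " strain DMR(s)")
        0L
      },
      `compare-rrbs` = {
        .cli_need(flags, c("meth", "bisulfite", "cpg", "out"))
        p0 <- .cli_num(flags, "p0", 0.5)
        nano <- .cli_load_per_site(flags$meth, flags$cpg, p0)
        bis <- read_bisulfite_tsv(flags$bisulfite)
        conc <- compare_with_bisulfite(
          nano, bis,
          nanopore_threshold = .cli_num(flags, "nanopore-threshold", 0.36),
          rrbs_threshold = .cli_num(flags, "rrbs-threshold", 0.5)
        )
        jsonlite::write_json(conc, flags$out, auto_unbox = TRUE, digits = NA)
        message("agreement ", round(conc$binary_agreement, 3), " over ",
                conc$n_sites, " sites")
        0L
      },
      distance = {
        .cli_need(flags, c("genes", "dmrs", "out"))
        genes <- read_genes_bed(flags$genes)
        dmrs <- read_dmrs_bed(flags$dmrs)
        d <- distance_to_nearest_dmr(genes, dmrs,
                                     top_k = .cli_num(flags, "top-k", 400))
        data.table::fwrite(data.table::as.data.table(d$table), flags$out,
                           sep = "\t", quote = FALSE)
        message(paste(names(d$medians), round(d$medians), sep = "=",
                      collapse = " "))
        0L
      },
      smooth = {
        .cli_need(flags, c("meth", "out"))
        p0 <- .cli_num(flags, "p0", 0.5)
        meth <- add_beta(read_methylation_tsv(flags$meth), p0 = p0)
        hap <- if (is.null(flags$haplotypes)) NULL else
          read_haplotypes_tsv(flags$haplotypes)
        tracks <- smooth_reads(meth, hap)
        data.table::fwrite(data.table::as.data.table(tracks), flags$out,
                           sep = "\t", quote = FALSE)
        0L
      },
      {
        message("unknown subcommand: ", sub, "\n\n", .cli_usage)
        2L
      }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e), "\n\n", .cli_usage)
    2L
  })
  invisible(res)
}
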