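---
title: "Haplotype-resolved methylomes from nanopore long reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved methylomes from nanopore long reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

haplomet reconstructs haplotyped CpG methylomes of F1 hybrid mouse samples
from long-read nanopore sequencing. The motivating application is genomic
imprinting in embryonic placenta: at imprinting control regions (ICRs) the
maternal and paternal alleles differ in methylation almost completely, and in
an F1 of two divergent strains (C57BL/6 "B6" × *M. m. castaneus* "Cast",
sequenced in both cross directions) every read can in principle be traced
back to its parental chromosome through the strain SNPs it covers. This
vignette documents the statistical models, the tunable parameters, the
synthetic-data generator used for validation, and the design decisions and
limitations a user should know about.

## Per-read haplotyping

### Scoring a single SNP observation

Where a read aligns over a known strain SNP, the aligned base either matches
the reference (B6) allele, the alternate (Cast) allele, a third base, or
falls in a deletion. Third-base and deletion observations are excluded. A
matching observation with basecall quality $q$ receives the score

$$S(q) = 1 - e^{-0.6927 - 0.1203\,q},$$

an empirically calibrated probability that the basecall is correct given its
quality. $S(0) \approx 0.5$ (an uninformative base) and $S$ increases
monotonically towards 1. The two coefficients are treated as fixed constants
of the method (`score_snp()`); they were calibrated on real nanopore data
and we do not refit them.

A read with $n$ informative observations gets the aggregate haplotype value

$$h = \frac{1}{n}\sum_i \begin{cases} S_i & \text{ref-matching} \\
1 - S_i & \text{alt-matching,} \end{cases}$$

so $h > 0.5$ supports the reference haplotype. Two independent evidence
streams are scored this way: the *basecall* stream (bases and Phred
qualities from the alignment) and the *signal* stream (allele calls from a
signal-space HMM, consumed as a TSV). Signal-stream qualities live on a
different scale and are offset by −35 before scoring; we floor the offset
quality at 0 because the score model returns values below 0.5
(anti-informative) for negative arguments, which would let a poorly scored
signal observation actively vote against its own call. Flooring makes such
observations uninformative-at-worst.

### Combining the two streams

With $H_x = \operatorname{sgn}(h_x - 0.5)$ for each stream, the combined
call applies these rules in order (`combine_calls()`):

1. both streams have fewer than 5 informative SNPs → unassigned;
2. both calls are nonzero and agree → that call;
3. / 4. one stream has more than 3× the SNP support of the other → the
   better-supported call;
5. / 6. one stream's deviation $|h - 0.5|$ exceeds 3× the other's → the
   stronger call;
7. otherwise unassigned.

Design choices worth noting: $\operatorname{sgn}(0) = 0$, so a read with
$h$ exactly 0.5 is unassigned and cannot satisfy rule 2 (agreement of an
uninformative call is not evidence); a read with no signal output at all
gets $n_\text{signal} = 0$ and falls through to rule 3, which is what lets
the combined method call more reads than signal-only approaches; the 3×
comparisons are strict. The minimum SNP count (5) and the dominance factor
(3) are exposed as `min_snps` and `ratio`.

### Three-way calls and maternal recombination

The maternal B6 colony carries FVB/NJ ancestry from its grand-parental
generation, so contiguous maternal segments may derive from the FVB rather
than the B6 chromosome. `three_way_haplotype()` scores each read against
the CAST and the FVB SNP tables independently: a read whose CAST call is
alternate is paternal; among maternal reads, an alternate FVB call means
FVB ancestry. The proportion of maternal reads labelled FVB is computed in
100 kb tiling windows (reads assigned by alignment midpoint) and fitted by
greedy binary recursive splitting on genomic coordinate
(`fit_partition()`, the anova recursive-partition method): a split is
accepted only when the node holds at least `minsplit = 5` windows and
reduces the total sum of squares by more than `cp = 0.1` times the root sum
of squares. Segments with mean FVB proportion above 50% are labelled FVB
and the maternal alleles of the SNP table are patched from the FVB table
inside them (`swap_snps()`), including FVB-only positions which become new
maternal-vs-paternal markers. Windows without maternal reads are omitted
from the fit and absorbed into the surrounding segments; split coordinates
fall midway between adjacent window starts, so a recovered breakpoint is
accurate to about half a window.

## Methylation calling

Per-read methylation arrives as log-likelihoods of the methylated and
unmethylated state for *CpG call groups*: runs of CpG sites closer than 11
bp, which share overlapping 6-mer contexts and are assigned a single state.
Bayes' rule converts the pair into a posterior probability

$$\beta = \frac{1}{1 + \frac{1-p_0}{p_0}\, e^{-\mathrm{llr}}},
\qquad \mathrm{llr} = \log L_M - \log L_C,$$

with prior $p_0 = 0.5$, appropriate for placental tissue whose global
methylation is near 50%. The computation is done in log space (no overflow
for $|\mathrm{llr}| > 700$) and evaluated on $|\mathrm{llr}|$ with
mirroring, so that $\beta(\mathrm{llr}) + \beta(-\mathrm{llr}) = 1$ holds
exactly in floating point. Group averages $\beta_i$ are arithmetic means
over the reads covering the group; reads with $H = 0$ contribute to the
unsplit ("all") summary but to neither haplotype.

For comparison with bisulfite data, call groups are split back into
individual cytosines — each CpG contributes its forward-strand C and the
reverse-strand C at position +1 — all inheriting the group β. Concordance
(`compare_with_bisulfite()`) is restricted to shared sites and reported as
the median absolute deviation of the per-site difference plus binary
agreement under a nanopore threshold of 0.36 and a bisulfite threshold of
0.5. The asymmetric nanopore threshold compensates the compression of
nanopore β values toward intermediate levels; it is exposed as a parameter.

## Differential methylation

### The site test

For each call group and haplotype-sample we form $N$ (reads) and
$X = \operatorname{round}(\sum_j \beta_{ij})$ (methylation mass, clamped to
$[0, N]$; counting reads with $\beta > 0.5$ is available as a flag). The
reciprocal-cross design yields four haplotype-samples — maternal and
paternal alleles of each cross — and two contrasts: *parent-of-origin*
(maternal vs paternal samples) and *strain* (B6-allele vs Cast-allele
samples). A genuine imprint produces the same maternal–paternal difference
in both crosses and cancels in the strain contrast, and vice versa.

`test_sites()` is a two-group beta-binomial Wald test with an arcsine link,
following the two-group design of the DSS differential-methylation
framework (pooled counts per group, shrunk per-site dispersion) rather than
a per-sample regression — with 2 samples per group, per-sample variances
are not estimable. Counts are pooled within each group,

$$\tilde p_g = \frac{X_g + 1/2}{N_g + 1}, \qquad
Y_g = \arcsin(2\tilde p_g - 1),$$

and the Wald statistic is $W = (Y_1 - Y_2)/\sqrt{v_1 + v_2}$ with the
delta-method variance

$$v_g = \frac{N_g\, \tilde p_g (1-\tilde p_g)\,
\bigl(1 + (\bar n_g - 1)\hat\varphi\bigr)}
{(N_g + 1)^2\, m_g (1 - m_g)}, \qquad
m_g = \frac{N_g \tilde p_g + 1/2}{N_g + 1},$$

where $\bar n_g$ is the mean per-sample coverage and $\hat\varphi$ the
site dispersion. Evaluating the curvature at the adjusted estimate $m_g$
(rather than using the variance-stabilized constant $1/N$) is what gives
the test its power at near-saturated effects — exactly the ICR regime —
while remaining calibrated at intermediate methylation: in our null
simulations (p = 0.5, N = 10 per sample, φ = 0.1, 2 vs 2) the p < 0.05
rate is ≈ 0.06, and boundary nulls are conservative. p-values are
two-sided standard normal.

$\hat\varphi$ is a per-site method-of-moments estimate from the
within-group spread of sample proportions, clamped to $[0,1]$ and shrunk
toward the genome-wide mean with weight $w = n/(n+4)$ ($n$ = samples at
the site); with a 2 vs 2 design the raw estimate has ~2 degrees of freedom
and is unusable without shrinkage. Degenerate sites inherit the
genome-wide mean.

### Regions, ranking, and the detection limit

Sites with $p < 10^{-5}$ are clustered into candidate regions: a new
region starts when the gap to the previous significant site exceeds 100 bp
or the effect changes sign. A region is kept when it spans at least 3
tested sites and 50 bp and at least half of its member sites are
significant (all parameters exposed; the defaults mirror the established
DMR-caller defaults, and the permissive site threshold is deliberately not
corrected genome-wide). The *area statistic* — the sum of member Wald
statistics — ranks regions; `distance_to_nearest_dmr()` relates the top
400 to gene classes.

Users should understand the detection limit this implies. With 2 samples
per group at coverage $N = 10$ each and dispersion φ = 0.1, the largest
standardized per-site effect a *calibrated* test can achieve for a
methylation difference of 0.5 (say 0.75 vs 0.25) is about 2.4–2.65 —
far below the 4.42 needed for $p < 10^{-5}$. Per-site power is ~13% and
region recovery is rare (~19% in our simulations). This is not an
implementation defect but an information bound: at this depth the method
detects near-complete allelic differences (0.95 vs 0.05, as at ICRs, where
per-site power approaches 1 at modest coverage because the beta-binomial
variance collapses near the boundary), not intermediate shifts. Deeper
designs (N ≳ 30) or more replicates are needed for Δβ ≈ 0.5. The shipped
tests document both regimes.

## The synthetic-data generator

All validation runs on synthetic data with known truth (`sim_config()`,
`simulate_*()`, `write_fixture_set()`). The defaults describe the study
conditions the pipeline targets, chosen once:

* one 2 Mb chromosome, two reciprocal pseudo-crosses at 10× coverage each,
  log-normal reads (median 20 kb, σ_log = 0.35) — the coverage and
  read-length regime of a typical nanopore run of this design;
* CAST SNPs at 1/500 bp and FVB SNPs at 1/1000 bp (the FVB line is closer
  to B6), disjoint positions, random biallelic alleles;
* 10% basecall error at SNPs under an allele-confusion model (the read
  shows the opposite allele with probability *e*), with Phred qualities
  that are the exact transform $q = -10\log_{10} e$ — so the score model
  operates in its calibrated regime and a 50% error rate makes single-SNP
  evidence exactly uninformative; small 1–3 bp deletion events produce D
  CIGAR operations;
* an independent signal-score stream with its own error rate (8%), the
  +35 quality scale, and 15% of reads missing entirely (exercising every
  combination-rule path);
* a bimodal background methylome: alternating low (0.12) and high (0.85)
  domains of mean length 20 kb, averaging ~50% genome-wide as in placenta;
  background CpGs at 1/500 bp;
* planted DMRs as CGI-like dense CpG lattices (mean spacing 25 bp) with
  near-complete differences (0.95 vs 0.05) — three parent-of-origin and
  two strain regions anchored at fixed genome fractions — the ICR regime
  the method is designed to detect;
* per-read, per-group log-likelihood ratios at ±4 nats with Gaussian noise
  (σ = 2), giving realistic β noise with ~2% sign errors;
* bisulfite truth at ~30× Poisson coverage of the allele-averaged
  methylation.

What the generator does *not* emulate: sequence-context-dependent error,
basecaller miscalibration, alignment artifacts at structural variants,
repeat-driven mismapping, CpG-density-dependent likelihood quality, or
biological replicate variation beyond binomial sampling (the two
pseudo-crosses share the same truth). Passing tests therefore demonstrate
the correctness and calibration of the algorithms under the stated noise
model, not performance on real flowcells; the empirical score coefficients
and the 0.36 concordance threshold in particular are taken from real-data
calibration, not rederived here.

Problem sizes in the shipped tests were chosen to exercise the full
pipeline at the default study conditions (2 Mb, 10×, reciprocal crosses;
2,000 pure-strain reads; 100-replicate calibration and recovery loops) —
large enough that every rate is measured with useful precision.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; VCF and SAM convert at
  the boundary, BED/bedGraph pass through.
* `fit_partition()` with a zero root sum of squares never splits (the
  improvement must strictly exceed cp × root SS); leaves of a single
  window are allowed (no minimum-bucket constraint beyond `minsplit`).
* Loess smoothing of per-read tracks (`smooth_read()`) uses degree-1
  local regression with span $\alpha(L) = 0.1 + 8\times10^{-11}
  (\max\{10^5 - L, 0\})^2$ of the read length, clamped to
  $[2/n_\text{points}, 1]$; fits are evaluated at call-group midpoints
  and clipped to $[0,1]$; reads with fewer than two groups pass through
  unsmoothed.
* Methylation records are attached to a read only when the read's span
  covers the whole call group (group-level records make partial overlap
  moot for real input).
* Sites where one contrast group has no coverage are skipped by the site
  test; samples with zero coverage at a site are excluded from that
  site's group means.
* Ties: `sgn(0) = 0` throughout; the FVB label requires mean proportion
  strictly above 0.5.

## Known limitations

* The DMR test assumes the four haplotype-samples are independent given
  the site dispersion; reads misassigned between haplotypes (~1–2% at
  realistic error rates) slightly dilute true differences.
* The site test is mildly anticonservative at intermediate methylation
  with very small designs (null p < 0.05 rate ≈ 0.06–0.07 at 2 vs 2,
  N = 10) — a known property of plug-in Wald tests with shrunk
  dispersions; the permissive 1e-5 region threshold is unaffected
  (zero null DMRs in 100/100 simulated replicates).
* Recombination breakpoints are resolved to ~half a 100 kb window;
  sub-window recombination events are invisible.
* Only 5mC in CpG context is modelled; call groups assume a shared state
  across their sites by construction, so true mixed-state groups are
  averaged.
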