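## Per-gene population-genetic summaries: folded SFS, divergence with
## multiple-hit corrections, codon usage bias and genomic covariates.

#' Fold allele counts into a minor-allele site frequency spectrum
#'
#' @param minor_counts Integer vector of minor-allele counts, one per
#'   biallelic segregating column (values in `1..floor(n/2)`); monomorphic
#'   columns contribute nothing and should not be included.
#' @param n_chromosomes Number of chromosomes every column was sampled at.
#' @return Integer vector of length `floor(n/2)`; entry `i` is the number of
#'   sites with minor-allele count `i`.
#' @export
build_folded_sfs <- function(minor_counts, n_chromosomes) {
  half <- n_chromosomes %/% 2L
  if (length(minor_counts) == 0L) return(integer(half))
  stopifnot(all(minor_counts >= 1), all(minor_counts <= half))
  tabulate(minor_counts, nbins = half)
}

#' Fold per-column allele count vectors
#'
#' Takes raw base counts per column (a 4 x ncol matrix over A,C,G,T after
#' downsampling) and returns the folded SFS plus tallies of monomorphic and
#' excluded (>2 alleles) columns.
#'
#' @param base_counts Matrix with 4 rows (A, C, G, T) and one column per
#'   alignment column; every column must sum to `n_chromosomes`.
#' @param n_chromosomes Sample size.
#' @param strict If `TRUE`, a column with more than two alleles is an error;
#'   otherwise it is excluded and tallied.
#' @return A list with `sfs` (folded counts), `n_monomorphic` and
#'   `n_excluded`.
#' @export
fold_columns <- function(base_counts, n_chromosomes, strict = FALSE) {
  stopifnot(nrow(base_counts) == 4L)
  if (ncol(base_counts) == 0L)
    return(list(sfs = integer(n_chromosomes %/% 2L),
                n_monomorphic = 0L, n_excluded = 0L))
  if (!all(colSums(base_counts) == n_chromosomes))
    stop("every column must carry exactly n_chromosomes alleles")
  n_alleles <- colSums(base_counts > 0)
  if (any(n_alleles > 2)) {
    if (strict) stop("column with more than two alleles in strict mode")
  }
  biallelic <- n_alleles == 2
  minor <- if (any(biallelic))
    apply(base_counts[, biallelic, drop = FALSE], 2,
          function(cc) min(cc[cc > 0]))
  else integer(0)
  minor <- pmin(minor, n_chromosomes - minor)
  list(sfs = build_folded_sfs(as.integer(minor), n_chromosomes),
       n_monomorphic = sum(n_alleles == 1),
       n_excluded = sum(n_alleles > 2))
}

#' Count substitutions between one ingroup haplotype and the outgroup
#'
#' @param ingroup Character vector of bases of the sampled divergence
#'   haplotype at the columns of one site class.
#' @param outgroup Character vector of outgroup bases at the same columns.
#' @return A list with `D` (differing comparable columns), `L` (comparable
#'   columns: both bases in A/C/G/T), and `D_ts`/`D_tv` transition and
#'   transversion counts among the differences.
#' @export
count_substitutions <- function(ingroup, outgroup) {
  stopifnot(length(ingroup) == length(outgroup))
  bases <- c("A", "C", "G", "T")
  ok <- ingroup %in% bases & outgroup %in% bases
  a <- ingroup[ok]; b <- outgroup[ok]
  diffs <- a != b
  purine <- c("A", "G")
  is_ts <- diffs & ((a %in% purine) == (b %in% purine))
  list(D = sum(diffs), L = sum(ok), D_ts = sum(is_ts),
       D_tv = sum(diffs) - sum(is_ts))
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of differing sites (`0 <= p < 0.75`).
#' @return Corrected substitutions per site
#'   \eqn{K = -\frac{3}{4}\ln(1 - \frac{4p}{3})}.
#' @export
jc_correct <- function(p) {
  stopifnot(all(p >= 0))
  if (any(p >= 0.75))
    stop("Jukes-Cantor correction saturated: p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' Fast plug-in f_HRi statistic for resampling loops
#'
#' Vectorised recombination-bin pipeline for bootstrap and permutation
#' replicates: ranks genes into bins, pools divergence counts with column
#' sums, applies the plug-in adaptation estimate with a fixed DFE
#' correction factor, then the LOESS/asymptote loss accounting. Produces
#' the same quantity as the full [hri_analysis()] chain with
#' `fixation_factor` supplied, at a fraction of the cost.
#'
#' @param gs Gene set.
#' @param n_bins Number of recombination bins.
#' @param fixation_factor Fixed DFE correction \eqn{E_f[r(S)]} (see
#'   [pooled_fixation_factor()]).
#' @param rr_threshold Asymptote/loss threshold (cM/Mb).
#' @param clamp Clamp negative LOESS predictions to 0.
#' @param span LOESS span.
#' @param estimate_part,n_parts Optional hypergeometric split part for the
#'   divergence estimate (columns `d4_<part>` must exist in `gs$tab`).
#' @return The f_HRi estimate (scalar).
#' @export
fhri_plugin_stat <- function(gs, n_bins, fixation_factor, rr_threshold = 2,
                             clamp = TRUE, span = 1.0,
                             estimate_part = NULL, n_parts = 3L) {
  tab <- gs$tab
  rb <- rank_bin(tab$rr, tab$gene_id, n_bins)
  binof <- integer(nrow(tab))
  for (i in seq_along(rb$bins)) binof[rb$bins[[i]]] <- i
  keep <- binof > 0
  b <- binof[keep]
  L0 <- rowsum(tab$L0[keep], b)[, 1]
  D0 <- rowsum(tab$D0[keep], b)[, 1]
  if (is.null(estimate_part)) {
    L4 <- rowsum(tab$L4[keep], b)[, 1]
    D4 <- rowsum(tab$D4[keep], b)[, 1]
  } else {
    L4 <- rowsum(tab$L4[keep], b)[, 1] / n_parts
    D4 <- rowsum(tab[[paste0("d4_", estimate_part)]][keep], b)[, 1]
  }
  rr <- rowsum(tab$rr[keep], b)[, 1] / tabulate(b, n_bins)
  ka <- jc_correct(D0 / L0)
  k4 <- tamura_correct((D4 / L4) / 3, 2 * (D4 / L4) / 3, 0.5)
  ka_plus <- ka - k4 * fixation_factor
  pred <- loess_predict(rr, ka_plus, span = span)
  ka0 <- asymptotic_ka(rr, ka_plus, rr_threshold)
  estimate_fhri(L0, rr, pred, ka0, rr_threshold, clamp = clamp)$f_hri
}

#' Tamura (1992) multiple-hit correction
#'
#' Corrects divergence allowing for unequal GC content and a
#' transition/transversion bias; reduces to Kimura's two-parameter
#' correction at `theta_gc = 0.5`.
#'
#' @param P Transition difference proportion.
#' @param Q Transversion difference proportion.
#' @param theta_gc GC content at the sites being corrected.
#' @return Corrected substitutions per site
#'   \eqn{K = -h \ln(1 - P/h - Q) - \frac{1}{2}(1 - h)\ln(1 - 2Q)} with
#'   \eqn{h = 2\theta(1-\theta)}.
#' @export
tamura_correct <- function(P, Q, theta_gc) {
  stopifnot(all(P >= 0), all(Q >= 0), all(theta_gc >= 0), all(theta_gc <= 1))
  h <- 2 * theta_gc * (1 - theta_gc)
  arg1 <- 1 - P / h - Q
  arg2 <- 1 - 2 * Q
  if (any(arg1 <= 0))
    stop("Tamura correction saturated: 1 - P/h - Q = ", format(min(arg1)))
  if (any(arg2 <= 0))
    stop("Tamura correction saturated: 1 - 2Q = ", format(min(arg2)))
  -h * log(arg1) - 0.5 * (1 - h) * log(arg2)
}

#' Frequency of optimal codons
#'
#' @param coding_seq Coding nucleotide sequence (character scalar or vector
#'   of codons), length divisible by 3, read in frame.
#' @param optimal_codons Character vector of codons considered optimal (see
#'   [dmel_optimal_codons()] for the shipped default).
#' @return Fraction of codons that are optimal among codons with synonymous
#'   alternatives (Met, Trp and stop codons excluded from the denominator);
#'   `NA` with a warning if the denominator is empty.
#' @export
compute_fop <- function(coding_seq, optimal_codons = dmel_optimal_codons()) {
  codons <- if (length(coding_seq) == 1L && nchar(coding_seq[1]) > 3L) {
    s <- toupper(coding_seq)
    stopifnot(nchar(s) %% 3 == 0)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  } else toupper(coding_seq)
  aa <- GENCODE[codons]
  degenerate <- !is.na(aa) & !(aa %in% c("M", "W", "*"))
  if (!any(degenerate)) {
    warning("no codons with synonymous alternatives; Fop undefined")
    return(NA_real_)
  }
  sum(codons[degenerate] %in% optimal_codons) / sum(degenerate)
}

#' Default optimal codon set for Drosophila melanogaster
#'
#' The C/G-ending major codons classically reported as translationally
#' optimal in D. melanogaster. The set is a configurable input to
#' [compute_fop()]; analyses of other organisms should supply their own.
#'
#' @return Character vector of codons.
#' @export
dmel_optimal_codons <- function() {
  c("TTC", "CTG", "ATC", "GTC", "GTG", "TCC", "AGC", "CCC", "ACC", "GCC",
    "TAC", "CAC", "CAG", "AAC", "AAG", "GAC", "GAG", "TGC", "CGC", "CGT",
    "GGC")
}

#' Gene density around a gene midpoint
#'
#' Number of positions covered by at least one coding exon within 50 kb
#' either side of the gene midpoint, per 100,000 sites. The full annotation
#' (all coding genes, not only analysis genes) should be supplied. At
#' chromosome ends the window is truncated and the count rescaled to the
#' surveyed length.
#'
#' @param cds_ranges [IRanges::IRanges] (or start/end data.frame) of coding
#'   exons on the gene's chromosome arm, in 0-based half-open coordinates.
#' @param midpoint Gene midpoint coordinate (0-based).
#' @param arm_length Length of the chromosome arm (for truncation); `Inf`
#'   disables truncation.
#' @param half_window Half window size in bp (default 50000).
#' @return Coding sites per 100,000 sites.
#' @export
gene_density <- function(cds_ranges, midpoint, arm_length = Inf,
                         half_window = 50000) {
  if (midpoint < 0 || midpoint > arm_length)
    stop("gene midpoint lies outside the chromosome arm")
  if (is.data.frame(cds_ranges))
    cds_ranges <- IRanges::IRanges(start = cds_ranges$start + 1L,
                                   end = cds_ranges$end)
  win_lo <- max(0, midpoint - half_window)
  win_hi <- min(arm_length, midpoint + half_window)
  window <- IRanges::IRanges(start = win_lo + 1L, end = win_hi)
  covered <- sum(IRanges::width(
    IRanges::intersect(IRanges::reduce(cds_ranges), window)))
  covered / (win_hi - win_lo) * 1e5
}

#' Recombination rate at a gene midpoint
#'
#' Looks up the cM/Mb of the unique non-overlapping window of a
#' recombination map that contains the gene midpoint; no smoothing is
#' applied.
#'
#' @param recmap Data frame with columns `arm`, `start`, `end`, `cM_per_Mb`
#'   (0-based half-open windows, typically 100-kb tiles).
#' @param arm Chromosome arm of the gene.
#' @param midpoint Gene midpoint (0-based).
#' @return The window's cM/Mb, or `NA` (with a warning) if the midpoint is
#'   not covered by the map.
#' @export
assign_rr <- function(recmap, arm, midpoint) {
  m <- recmap[recmap$arm == arm, , drop = FALSE]
  hit <- m$start <= midpoint & midpoint < m$end
  if (sum(hit) > 1) stop("recombination map windows overlap at ", midpoint)
  if (!any(hit)) {
    warning("gene midpoint ", midpoint, " not covered by recombination map")
    return(NA_real_)
  }
  m$cM_per_Mb[hit]
}

#' Read a recombination map TSV
#'
#' @param path TSV with columns `arm`, `start`, `end`, `cM_per_Mb`
#'   (0-based half-open windows).
#' @return Data frame.
#' @export
read_recmap <- function(path) {
  m <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("arm", "start", "end", "cM_per_Mb") %in% names(m)))
  m
}
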