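## Per-gene alignment handling: exon filtering, site classification into
## 0-fold / 4-fold / short-intron classes, allele downsampling.

# Evaluate fn under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Construct a per-gene alignment record
#'
#' @param gene_id Gene identifier.
#' @param ingroup_seqs Character vector of aligned ingroup haplotype
#'   sequences (equal length, alphabet ACGTN-), at least 2.
#' @param outgroup_seq Aligned outgroup sequence of the same length.
#' @param exons,introns Lists (or 2-column matrices) of `[start, end)`
#'   intervals in 0-based alignment coordinates.
#' @param arm Chromosome arm label.
#' @param strand `"+"` or `"-"`; minus-strand genes are reverse-complemented
#'   once at load so that all downstream work is on the coding strand.
#' @return An object of class `gene_alignment` holding the ingroup as a
#'   haplotype-by-column character matrix.
#' @export
gene_alignment <- function(gene_id, ingroup_seqs, outgroup_seq,
                           exons = list(), introns = list(),
                           arm = "2L", strand = "+") {
  stopifnot(length(ingroup_seqs) >= 2,
            all(nchar(ingroup_seqs) == nchar(outgroup_seq)))
  L <- nchar(outgroup_seq)
  if (strand == "-") {
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ingroup_seqs <- vapply(ingroup_seqs, rc, character(1), USE.NAMES = FALSE)
    outgroup_seq <- rc(outgroup_seq)
    flip <- function(iv) c(L - iv[2], L - iv[1])
    exons <- lapply(exons, flip)
    introns <- lapply(introns, flip)
    strand <- "+"
  }
  mat <- do.call(rbind, strsplit(toupper(ingroup_seqs), ""))
  out <- strsplit(toupper(outgroup_seq), "")[[1]]
  as_iv <- function(v) lapply(v, function(iv) {
    stopifnot(length(iv) == 2, iv[1] >= 0, iv[2] <= L, iv[1] < iv[2])
    as.integer(iv)
  })
  structure(list(gene_id = gene_id, arm = arm, strand = strand,
                 ingroup = mat, outgroup = out,
                 exons = as_iv(exons), introns = as_iv(introns)),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment %s: %d haplotypes x %d columns, %d exons, %d introns\n",
              x$gene_id, nrow(x$ingroup), ncol(x$ingroup),
              length(x$exons), length(x$introns)))
  invisible(x)
}

#' Filter and codon-trim exon intervals
#'
#' Applies the exon quality cascade: among overlapping exons only the largest
#' is kept; each survivor is trimmed at its 3' end to contain only full
#' codons; exons containing an alignment gap in any sequence, or an internal
#' stop codon in any haplotype or in the outgroup (per-exon reading frame),
#' are removed.
#'
#' @param aln A [gene_alignment()].
#' @param log_fn Optional callback `function(exon, reason)` invoked for every
#'   dropped exon.
#' @return List of retained `[start, end)` intervals (possibly empty; an
#'   empty result means the gene is dropped from the coding analysis).
#' @export
filter_and_trim_exons <- function(aln, log_fn = NULL) {
  note <- function(iv, why) if (!is.null(log_fn)) log_fn(iv, why)
  exons <- aln$exons
  if (length(exons) == 0L) return(list())
  # resolve overlaps: consider exons largest-first, drop any that overlaps an
  # already retained one
  ord <- order(-vapply(exons, function(iv) iv[2] - iv[1], numeric(1)),
               vapply(exons, `[`, numeric(1), 1))
  kept <- list()
  for (iv in exons[ord]) {
    clash <- any(vapply(kept, function(k) iv[1] < k[2] && k[1] < iv[2],
                        logical(1)))
    if (clash) note(iv, "overlap") else kept <- c(kept, list(iv))
  }
  out <- list()
  for (iv in kept) {
    len <- (iv[2] - iv[1]) %/% 3L * 3L
    if (len < 3L) { note(iv, "too_short"); next }
    iv <- c(iv[1], iv[1] + len)
    cols <- (iv[1] + 1L):iv[2]
    block <- rbind(aln$ingroup[, cols, drop = FALSE], aln$outgroup[cols])
    if (any(block == "-")) { note(iv, "gap"); next }
    starts <- seq(1L, len, 3L)
    has_stop <- FALSE
    for (r in seq_len(nrow(block))) {
      codons <- paste0(block[r, starts], block[r, starts + 1L],
                       block[r, starts + 2L])
      aa <- GENCODE[codons]
      if (any(aa == "*", na.rm = TRUE)) { has_stop <- TRUE; break }
    }
    if (has_stop) { note(iv, "internal_stop"); next }
    out <- c(out, list(as.integer(iv)))
  }
  out[order(vapply(out, `[`, integer(1), 1))]
}

#' Downsample alleles at alignment columns
#'
#' At every requested column, draws exactly `n_target` called alleles
#' uniformly without replacement from the ingroup; columns with fewer than
#' `n_target` called (A/C/G/T) alleles are flagged unusable.
#'
#' @param aln A [gene_alignment()].
#' @param columns 1-based alignment column indices.
#' @param n_target Number of chromosomes to downsample to (>= 2).
#' @param seed RNG seed.
#' @return A list with `counts` (4 x length(columns) matrix of A/C/G/T
#'   counts after downsampling; NA columns are unusable) and `usable`
#'   (logical vector).
#' @export
downsample_alleles <- function(aln, columns, n_target, seed = 1L) {
  stopifnot(n_target >= 2)
  if (n_target > nrow(aln$ingroup))
    stop("n_target exceeds the number of ingroup sequences")
  bases <- c("A", "C", "G", "T")
  counts <- matrix(NA_integer_, 4, length(columns),
                   dimnames = list(bases, NULL))
  usable <- logical(length(columns))
  with_seed(seed, function() {
    for (i in seq_along(columns)) {
      col <- aln$ingroup[, columns[i]]
      called <- col[col %in% bases]
      if (length(called) < n_target) next
      drawn <- if (length(called) == n_target) called
               else sample(called, n_target)
      counts[, i] <<- tabulate(match(drawn, bases), 4L)
      usable[i] <<- TRUE
    }
  })
  list(counts = counts, usable = usable)
}

#' Sample the haplotype used for divergence
#'
#' Divergence out to the outgroup is computed against a single randomly
#' chosen ingroup chromosome.
#'
#' @param aln A [gene_alignment()].
#' @param seed RNG seed.
#' @return Haplotype row index (1-based), uniform over haplotypes across
#'   seeds and deterministic under a fixed seed.
#' @export
pick_divergence_haplotype <- function(aln, seed = 1L) {
  n <- nrow(aln$ingroup)
  if (n == 1L) return(1L)
  with_seed(seed, function() sample.int(n, 1L))
}

#' Classify coding columns into 0-fold and 4-fold sites
#'
#' Works on codon-trimmed retained exons. Codon degeneracy is assessed on the
#' ingroup majority codon; a column is 0-fold if every base change at it is
#' nonsynonymous, 4-fold if all four bases are synonymous. 4-fold columns are
#' retained only when the codon encodes the same amino acid in every ingroup
#' haplotype and in the outgroup (codons segregating for amino-acid changes
#' keep their 0-fold sites). Codons containing N in any sequence, codons
#' whose outgroup copy is not fully called, and codons within
#' `core_margin_codons` of either exon boundary are skipped.
#'
#' @param aln A [gene_alignment()].
#' @param exons Retained exon intervals from [filter_and_trim_exons()].
#' @param core_margin_codons Codons excluded at each exon boundary
#'   (exon "core" definition; default 8).
#' @return A list with integer column vectors `sites_0fold` and
#'   `sites_4fold` (1-based alignment columns).
#' @export
classify_coding_sites <- function(aln, exons, core_margin_codons = 8L) {
  s0 <- integer(0); s4 <- integer(0)
  for (iv in exons) {
    ncod <- (iv[2] - iv[1]) %/% 3L
    codon_idx <- seq_len(ncod)
    if (core_margin_codons > 0L)
      codon_idx <- codon_idx[codon_idx > core_margin_codons &
                             codon_idx <= ncod - core_margin_codons]
    for (k in codon_idx) {
      cols <- iv[1] + 3L * (k - 1L) + 1:3
      ing <- aln$ingroup[, cols, drop = FALSE]
      outg <- aln$outgroup[cols]
      if (any(ing == "N") || !all(outg %in% c("A", "C", "G", "T"))) next
      cod_strings <- paste0(ing[, 1], ing[, 2], ing[, 3])
      tab <- sort(table(cod_strings), decreasing = TRUE)
      majority <- names(tab)[1]
      deg <- codon_degeneracy(majority)
      if (all(is.na(deg))) next
      s0 <- c(s0, cols[deg == "0fold"])
      if (any(deg == "4fold")) {
        aas <- GENCODE[cod_strings]
        out_aa <- GENCODE[paste0(outg, collapse = "")]
        same_aa <- !any(is.na(aas)) && length(unique(aas)) == 1L &&
          !is.na(out_aa) && out_aa == aas[1]
        if (same_aa) s4 <- c(s4, cols[deg == "4fold"])
      }
    }
  }
  list(sites_0fold = s0, sites_4fold = s4)
}

#' Extract short-intron neutral reference columns
#'
#' Positions 8-30 (1-based from the 5' end on the coding strand) of introns
#' at most `max_len` bp long serve as an alternative near-neutral reference.
#' The invariant GT/AG splice dinucleotides never contribute. The gene yields
#' an empty set unless at least `min_introns` qualifying introns exist and
#' the gap fraction across their aligned sequences is below `max_gap_frac`.
#' Columns containing a gap or N in any sequence are excluded.
#'
#' @param aln A [gene_alignment()].
#' @param max_len Maximum intron length (default 65).
#' @param pos_range Contributing positions within the intron (default 8-30).
#' @param min_introns Minimum number of qualifying introns (default 2).
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.10).
#' @return Integer vector of 1-based alignment columns (possibly empty).
#' @export
extract_short_intron_sites <- function(aln, max_len = 65L,
                                       pos_range = c(8L, 30L),
                                       min_introns = 2L,
                                       max_gap_frac = 0.10) {
  qual <- Filter(function(iv) (iv[2] - iv[1]) <= max_len, aln$introns)
  if (length(qual) < min_introns) return(integer(0))
  all_cols <- unlist(lapply(qual, function(iv) (iv[1] + 1L):iv[2]))
  block <- rbind(aln$ingroup[, all_cols, drop = FALSE], aln$outgroup[all_cols])
  if (mean(block == "-") >= max_gap_frac) return(integer(0))
  cols <- integer(0)
  for (iv in qual) {
    len <- iv[2] - iv[1]
    pos <- seq(pos_range[1], min(pos_range[2], len))
    pos <- pos[pos > 2L & pos <= len - 2L]  # keep clear of GT..AG junctions
    cols <- c(cols, iv[1] + pos)
  }
  keep <- vapply(cols, function(cc) {
    v <- c(aln$ingroup[, cc], aln$outgroup[cc])
    all(v %in% c("A", "C", "G", "T", "N")) && !any(v == "-")
  }, logical(1))
  cols[keep]
}

#' Classify all site classes of a gene
#'
#' Runs the exon filter, coding-site classification and short-intron
#' extraction, and asserts site-class disjointness.
#'
#' @param aln A [gene_alignment()].
#' @param core_margin_codons Exon-core margin (see [classify_coding_sites()]).
#' @param log_fn Optional drop logger passed to [filter_and_trim_exons()].
#' @return A list with `sites_0fold`, `sites_4fold`, `sites_intron` and
#'   `retained_exons`.
#' @export
classify_gene_sites <- function(aln, core_margin_codons = 8L, log_fn = NULL) {
  exons <- filter_and_trim_exons(aln, log_fn)
  coding <- classify_coding_sites(aln, exons, core_margin_codons)
  intr <- extract_short_intron_sites(aln)
  classes <- list(coding$sites_0fold, coding$sites_4fold, intr)
  all_sites <- unlist(classes)
  if (anyDuplicated(all_sites))
    stop("site classes are not disjoint for gene ", aln$gene_id)
  list(sites_0fold = coding$sites_0fold, sites_4fold = coding$sites_4fold,
       sites_intron = intr, retained_exons = exons)
}

#' Per-gene site counts, folded SFS and divergence
#'
#' Assembles the full per-gene record: downsamples each site class to
#' `n_chromosomes`, builds the folded SFS per class, samples one divergence
#' haplotype and counts substitutions out to the outgroup, recording the
#' transition/transversion split and GC content at 4-fold sites for the
#' Tamura correction.
#'
#' @param aln A [gene_alignment()].
#' @param sites Output of [classify_gene_sites()].
#' @param n_chromosomes Downsampling target.
#' @param seed RNG seed (downsampling and haplotype choice are derived from
#'   it deterministically).
#' @return A list of class `gene_counts` with `L0`, `L4`, `Li`, `D0`, `D4`,
#'   `Di`, `sfs0`, `sfs4`, `sfsi`, `gc4`, `P4_ts`, `P4_tv`, `div_haplotype`
#'   and QC tallies.
#' @export
gene_counts <- function(aln, sites, n_chromosomes, seed = 1L) {
  hap <- pick_divergence_haplotype(aln, seed = seed + 1L)
  class_block <- function(cols, cls_seed) {
    if (length(cols) == 0L)
      return(list(L = 0L, D = 0L, D_ts = 0L, D_tv = 0L,
                  sfs = integer(n_chromosomes %/% 2L),
                  n_monomorphic = 0L, n_excluded = 0L, cols_usable = integer(0)))
    ds <- downsample_alleles(aln, cols, n_chromosomes, seed = cls_seed)
    ok <- ds$usable
    fc <- fold_columns(ds$counts[, ok, drop = FALSE], n_chromosomes)
    dv <- count_substitutions(aln$ingroup[hap, cols[ok]], aln$outgroup[cols[ok]])
    list(L = dv$L, D = dv$D, D_ts = dv$D_ts, D_tv = dv$D_tv, sfs = fc$sfs,
         n_monomorphic = fc$n_monomorphic, n_excluded = fc$n_excluded,
         cols_usable = cols[ok])
  }
  b0 <- class_block(sites$sites_0fold, seed + 2L)
  b4 <- class_block(sites$sites_4fold, seed + 3L)
  bi <- class_block(sites$sites_intron, seed + 4L)
  gc4 <- if (length(b4$cols_usable)) {
    v <- c(aln$ingroup[hap, b4$cols_usable], aln$outgroup[b4$cols_usable])
    mean(v %in% c("G", "C"))
  } else NA_real_
  structure(list(gene_id = aln$gene_id,
                 L0 = b0$L, L4 = b4$L, Li = bi$L,
                 D0 = b0$D, D4 = b4$D, Di = bi$D,
                 sfs0 = b0$sfs, sfs4 = b4$sfs, sfsi = bi$sfs,
                 gc4 = gc4,
                 P4_ts = if (b4$L > 0) b4$D_ts / b4$L else NA_real_,
                 P4_tv = if (b4$L > 0) b4$D_tv / b4$L else NA_real_,
                 div_haplotype = hap,
                 qc = list(mono0 = b0$n_monomorphic, mono4 = b4$n_monomorphic,
                           excl0 = b0$n_excluded, excl4 = b4$n_excluded)),
            class = "gene_counts")
}

#' Read per-gene alignments from FASTA and GFF3
#'
#' FASTA records named by line id form the ingroup; the record whose id
#' starts with `outgroup|` is the outgroup. Exon (`CDS`) and `intron`
#' features are taken from the GFF3, matched by the `gene_id` attribute and
#' converted from 1-based inclusive to 0-based half-open coordinates.
#'
#' @param fasta_files Named character vector of per-gene FASTA paths (names
#'   are gene ids).
#' @param gff_file GFF3 annotation path.
#' @return A list of [gene_alignment()] objects.
#' @export
read_gene_alignments <- function(fasta_files, gff_file) {
  ann <- rtracklayer::import(gff_file)
  lapply(names(fasta_files), function(gid) {
    seqs <- Biostrings::readDNAStringSet(fasta_files[[gid]])
    ids <- names(seqs)
    is_out <- startsWith(ids, "outgroup|")
    if (sum(is_out) != 1L)
      stop("expected exactly one outgroup record in ", fasta_files[[gid]])
    feats <- ann[!is.na(ann$gene_id) & ann$gene_id == gid]
    to_iv <- function(gr) lapply(seq_along(gr), function(i)
      c(GenomicRanges::start(gr)[i] - 1L, GenomicRanges::end(gr)[i]))
    exons <- to_iv(feats[feats$type == "CDS"])
    introns <- to_iv(feats[feats$type == "intron"])
    strand <- as.character(GenomicRanges::strand(feats))[1]
    if (is.na(strand) || strand == "*") strand <- "+"
    arm <- as.character(GenomicRanges::seqnames(feats))[1]
    gene_alignment(gid,
                   ingroup_seqs = as.character(seqs[!is_out]),
                   outgroup_seq = as.character(seqs[is_out]),
                   exons = exons, introns = introns,
                   arm = if (is.na(arm)) "2L" else arm, strand = strand)
  })
}
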