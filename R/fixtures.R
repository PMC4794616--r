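## Sequence-level fixtures: write small FASTA/GFF3/recombination-map data
## sets realizing simulated counts, and read them back through the
## alignment pipeline.

# Expand a folded SFS vector into a list of minor-allele counts, capping at
# floor((n-1)/2) so the ingroup majority codon is never ambiguous.
expand_sfs_events <- function(sfs, n_chromosomes) {
  cap <- (n_chromosomes - 1L) %/% 2L
  counts <- integer(0)
  for (m in seq_along(sfs)) if (sfs[m] > 0)
    counts <- c(counts, rep(min(m, cap), sfs[m]))
  counts
}

#' Write sequence fixtures realizing a simulated gene set
#'
#' Generates a small synthetic gene set with [simulate_genes()] and writes
#' per-gene FASTA alignments, a GFF3 annotation, a recombination map and a
#' covariate table that, read back through the alignment and counting
#' stages with the same seed, reproduce the recorded counts. Each gene is a
#' single exon of glycine codons (margins included so the exon-core filter
#' leaves the intended codons) plus two 60-bp introns; polymorphic and
#' divergent columns are placed on dedicated codons. Counts exceeding the
#' sequence capacity are thinned; the returned `expected` table records
#' what the files actually realize (including the divergence haplotype the
#' reader will sample under `seed`).
#'
#' @param params A [sim_params()] at fixture scale (small `n_genes`,
#'   small `n_chromosomes`).
#' @param seed RNG seed; must be the seed later passed to
#'   [read_fixture_counts()].
#' @param out_dir Output directory (created if needed).
#' @param core_margin_codons Exon-core margin the reader will use.
#' @param inject_bad_exon Add an extra gap-containing exon to the first
#'   gene (it must be dropped and logged by the reader).
#' @return Invisibly, a list with `files` (paths) and `expected` (data.frame
#'   of realized per-gene `L0`, `L4`, `Li`, `D0`, `D4`, `Di`, plus realized
#'   folded SFS totals `S0`, `S4`, `Si`).
#' @export
emit_fixtures <- function(params, seed = 1L, out_dir,
                          core_margin_codons = 8L,
                          inject_bad_exon = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- simulate_genes(params, seed)
  n <- params$n_chromosomes
  M <- core_margin_codons
  gff_rows <- list()
  expected <- list()
  fasta_files <- character(0)
  for (g in seq_len(nrow(gs$tab))) {
    gid <- gs$tab$gene_id[g]
    seed_g <- seed + g
    hap <- with_seed(seed_g + 1L, function() sample.int(n, 1L))
    ncore <- gs$tab$L4[g]
    seg4 <- expand_sfs_events(gs$sfs4[g, ], n)
    seg0 <- expand_sfs_events(gs$sfs0[g, ], n)
    d4 <- gs$tab$D4[g]; d0 <- gs$tab$D0[g]
    # one event per codon; thin if over capacity
    budget <- ncore
    take <- function(k) { k <- min(k, budget); budget <<- budget - k; k }
    n_d4 <- take(d4); n_d0 <- take(d0)
    seg4 <- seg4[seq_len(take(length(seg4)))]
    seg0 <- seg0[seq_len(take(length(seg0)))]
    # codon layout: margins | events | plain core
    codons <- rep("GGG", ncore + 2L * M)
    ing <- matrix(rep(unlist(strsplit(paste(codons, collapse = ""), "")),
                      each = 1), nrow = n, ncol = 3L * (ncore + 2L * M),
                  byrow = TRUE)
    outg <- unlist(strsplit(paste(codons, collapse = ""), ""))
    core_start <- function(k) 3L * (M + k - 1L)  # 0-based codon offset
    k <- 0L
    # 4-fold divergent codons: outgroup GGA (same amino acid)
    for (i in seq_len(n_d4)) { k <- k + 1L; outg[core_start(k) + 3L] <- "A" }
    # 0-fold divergent codons: outgroup AGG (these codons lose their 4-fold
    # site to the same-amino-acid filter)
    for (i in seq_len(n_d0)) { k <- k + 1L; outg[core_start(k) + 1L] <- "A" }
    # 4-fold polymorphic codons: minor GGA on haplotypes 2..m+1
    carriers4 <- list()
    for (m in seg4) {
      k <- k + 1L
      ing[1L + seq_len(m), core_start(k) + 3L] <- "A"
      carriers4[[length(carriers4) + 1L]] <- 1L + seq_len(m)
    }
    # 0-fold polymorphic codons: minor AGG (lose the 4-fold site)
    carriers0 <- list()
    for (m in seg0) {
      k <- k + 1L
      ing[1L + seq_len(m), core_start(k) + 1L] <- "A"
      carriers0[[length(carriers0) + 1L]] <- 1L + seq_len(m)
    }
    exon_len <- 3L * (ncore + 2L * M)
    # introns: GT + T-body + AG, with intron events on positions 8..30
    ilen <- 60L
    intron <- c("G", "T", rep("T", ilen - 4L), "A", "G")
    int1 <- intron; int2 <- intron
    segi <- expand_sfs_events(gs$sfsi[g, ], n)
    di <- gs$tab$Di[g]
    ipos <- 8:30
    cap_i <- 2L * length(ipos)
    n_di <- min(di, cap_i)
    segi <- segi[seq_len(min(length(segi), cap_i - n_di))]
    islots <- c(lapply(ipos, function(p) c(1L, p)),
                lapply(ipos, function(p) c(2L, p)))
    imat <- matrix("T", n, 2L * ilen)
    iout <- c(int1, int2)
    slot <- 0L
    for (i in seq_len(n_di)) {
      slot <- slot + 1L
      off <- (islots[[slot]][1] - 1L) * ilen + islots[[slot]][2]
      iout[off] <- "G"
    }
    carriersi <- list()
    for (m in segi) {
      slot <- slot + 1L
      off <- (islots[[slot]][1] - 1L) * ilen + islots[[slot]][2]
      imat[1L + seq_len(m), off] <- "C"
      carriersi[[length(carriersi) + 1L]] <- 1L + seq_len(m)
    }
    full_ing <- cbind(ing, imat)
    full_out <- c(outg, iout)
    seqs <- apply(full_ing, 1, paste, collapse = "")
    names(seqs) <- sprintf("line%03d", seq_len(n))
    fa <- file.path(out_dir, paste0(gid, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(seqs,
                                 setNames(paste(full_out, collapse = ""),
                                          "outgroup|yak"))), fa)
    fasta_files[gid] <- fa
    gff_rows[[length(gff_rows) + 1L]] <- data.frame(
      seqid = gid, type = c("CDS", "intron", "intron"),
      start = c(1L, exon_len + 1L, exon_len + ilen + 1L),
      end = c(exon_len, exon_len + ilen, exon_len + 2L * ilen),
      gene_id = gid)
    if (inject_bad_exon && g == 1L) {
      # an extra CDS over the first intron carrying an alignment gap in one
      # haplotype: the exon filter must drop it (reason "gap"); the gap sits
      # at intron position 4, outside the 8-30 neutral window, so the
      # short-intron counts are unaffected
      gff_rows[[length(gff_rows) + 1L]] <- data.frame(
        seqid = gid, type = "CDS", start = exon_len + 4L,
        end = exon_len + 33L, gene_id = gid)
      full_ing[1L, exon_len + 4L] <- "-"
      seqs <- apply(full_ing, 1, paste, collapse = "")
      names(seqs) <- sprintf("line%03d", seq_len(n))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(c(seqs,
                                   setNames(paste(full_out, collapse = ""),
                                            "outgroup|yak"))), fa)
    }
    # realized expectations, accounting for minor alleles carried by the
    # divergence haplotype the reader will draw
    spurious4 <- sum(vapply(carriers4, function(cc) hap %in% cc, logical(1)))
    spurious0 <- sum(vapply(carriers0, function(cc) hap %in% cc, logical(1)))
    spuriousi <- sum(vapply(carriersi, function(cc) hap %in% cc, logical(1)))
    expected[[g]] <- data.frame(
      gene_id = gid,
      L0 = 2L * ncore, L4 = ncore - n_d0 - length(seg0),
      Li = cap_i,
      D0 = n_d0 + spurious0, D4 = n_d4 + spurious4, Di = n_di + spuriousi,
      S0 = length(seg0), S4 = length(seg4), Si = length(segi),
      div_haplotype = hap)
  }
  gff <- if (length(gff_rows)) do.call(rbind, gff_rows) else
    data.frame(seqid = character(0), type = character(0),
               start = integer(0), end = integer(0), gene_id = character(0))
  gr <- GenomicRanges::GRanges(
    seqnames = gff$seqid,
    ranges = IRanges::IRanges(start = gff$start, end = gff$end),
    strand = rep("+", nrow(gff)), type = gff$type, gene_id = gff$gene_id,
    phase = ifelse(gff$type == "CDS", 0L, NA_integer_))
  gff_file <- file.path(out_dir, "genes.gff3")
  if (length(gr) == 0L)
    writeLines("##gff-version 3", gff_file)
  else
    rtracklayer::export(gr, gff_file, format = "gff3")
  recmap <- data.frame(arm = rep("2L", nrow(gs$tab)),
                       start = (seq_len(nrow(gs$tab)) - 1L) * 100000L,
                       end = seq_len(nrow(gs$tab)) * 100000L,
                       cM_per_Mb = gs$tab$rr)
  recmap_file <- file.path(out_dir, "recmap.tsv")
  write.table(recmap, recmap_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cov_file <- file.path(out_dir, "covariates.tsv")
  write.table(gs$tab[, c("gene_id", "rr", "density", "fop", "immune_testes")],
              cov_file, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_file <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(f_hri = gs$truth$f_hri,
                            adaptive_curve = as.list(gs$truth$params$adaptive_curve)),
                       truth_file, auto_unbox = TRUE, digits = NA)
  invisible(list(files = list(fasta = fasta_files, gff = gff_file,
                              recmap = recmap_file, covariates = cov_file,
                              truth = truth_file),
                 expected = do.call(rbind, expected)))
}

#' Read fixture alignments back into per-gene counts
#'
#' Runs the full alignment path (exon filtering, site classification,
#' downsampling, folded SFS, divergence) on a fixture directory written by
#' [emit_fixtures()], using the same per-gene seed derivation.
#'
#' @param dir Fixture directory.
#' @param n_chromosomes Downsampling target (the fixture sample size).
#' @param seed The seed [emit_fixtures()] was called with.
#' @param core_margin_codons Exon-core margin.
#' @param log_fn Optional drop logger forwarded to the exon filter.
#' @return A gene set (`tab` + SFS matrices) with covariates joined from
#'   the fixture covariate table.
#' @export
read_fixture_counts <- function(dir, n_chromosomes, seed = 1L,
                                core_margin_codons = 8L, log_fn = NULL) {
  fa <- list.files(dir, pattern = "\\.fa$", full.names = TRUE)
  ids <- sub("\\.fa$", "", basename(fa))
  ord <- order(ids)
  fasta_files <- setNames(fa[ord], ids[ord])
  alns <- read_gene_alignments(fasta_files, file.path(dir, "genes.gff3"))
  covs <- read.table(file.path(dir, "covariates.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  genes_from_alignments(alns, n_chromosomes, seed = seed,
                        core_margin_codons = core_margin_codons,
                        covariates = covs, log_fn = log_fn)
}

#' Assemble a gene set from alignments
#'
#' @param alns List of [gene_alignment()] objects.
#' @param n_chromosomes Downsampling target.
#' @param seed Master seed; gene `i` uses `seed + i`.
#' @param core_margin_codons Exon-core margin.
#' @param covariates Optional data.frame keyed by `gene_id` with `rr`,
#'   `density`, `fop`, `immune_testes` columns to join.
#' @param log_fn Optional drop logger.
#' @return A gene set: `tab`, `sfs0`, `sfs4`, `sfsi`.
#' @export
genes_from_alignments <- function(alns, n_chromosomes, seed = 1L,
                                  core_margin_codons = 8L,
                                  covariates = NULL, log_fn = NULL) {
  half <- n_chromosomes %/% 2L
  rows <- list(); s0 <- list(); s4 <- list(); si <- list()
  for (i in seq_along(alns)) {
    aln <- alns[[i]]
    sites <- classify_gene_sites(aln, core_margin_codons, log_fn)
    gc <- gene_counts(aln, sites, n_chromosomes, seed = seed + i)
    rows[[i]] <- data.frame(
      gene_id = gc$gene_id, arm = aln$arm,
      L0 = gc$L0, L4 = gc$L4, Li = gc$Li,
      D0 = gc$D0, D4 = gc$D4,
      D4_ts = round(if (is.na(gc$P4_ts)) gc$D4 / 3 else gc$P4_ts * gc$L4),
      Di = gc$Di, gc4 = gc$gc4, div_haplotype = gc$div_haplotype,
      stringsAsFactors = FALSE)
    s0[[i]] <- gc$sfs0; s4[[i]] <- gc$sfs4; si[[i]] <- gc$sfsi
  }
  tab <- do.call(rbind, rows)
  if (!is.null(covariates))
    tab <- merge(tab, covariates, by = "gene_id", sort = FALSE)
  list(tab = tab, sfs0 = do.call(rbind, s0), sfs4 = do.call(rbind, s4),
       sfsi = do.call(rbind, si))
}
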