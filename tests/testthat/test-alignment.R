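test_that("exon filter keeps the largest of two overlapping exons and trims to full codons", {
  L <- 600
  seqstr <- paste(rep("GGG", L / 3), collapse = "")
  aln <- gene_alignment("g1", rep(seqstr, 3), seqstr,
                        exons = list(c(0, 300), c(200, 350)))
  kept <- filter_and_trim_exons(aln)
  expect_equal(kept, list(c(0L, 300L)))

  # a 301-bp exon is trimmed to 300
  aln2 <- gene_alignment("g2", rep(seqstr, 3), seqstr,
                         exons = list(c(0, 301)))
  expect_equal(filter_and_trim_exons(aln2), list(c(0L, 300L)))
})

test_that("exons with gaps or internal stops are dropped and logged", {
  seqstr <- paste(rep("GGG", 40), collapse = "")
  gapped <- seqstr
  substr(gapped, 10, 10) <- "-"
  aln <- gene_alignment("g1", c(gapped, seqstr, seqstr), seqstr,
                        exons = list(c(0, 120)))
  drops <- list()
  kept <- filter_and_trim_exons(aln, function(iv, why)
    drops[[length(drops) + 1]] <<- why)
  expect_length(kept, 0)
  expect_equal(drops[[1]], "gap")

  stopped <- seqstr
  substr(stopped, 13, 15) <- "TAA"
  aln2 <- gene_alignment("g2", c(stopped, seqstr, seqstr), seqstr,
                         exons = list(c(0, 120)))
  expect_length(filter_and_trim_exons(aln2), 0)
})

test_that("downsampling draws exactly n_target called alleles and flags shallow columns", {
  # column 1: A x130 monomorphic; column 2: 120 called + 10 N
  col1 <- rep("A", 130)
  col2 <- c(rep("A", 120), rep("N", 10))
  seqs <- vapply(seq_len(130), function(i) paste0(col1[i], col2[i]),
                 character(1))
  aln <- gene_alignment("g1", seqs, "AA", exons = list(c(0, 2)))
  ds <- downsample_alleles(aln, c(1L, 2L), 128L, seed = 3)
  expect_equal(unname(ds$counts["A", 1]), 128L)
  expect_true(ds$usable[1])
  expect_false(ds$usable[2])
  expect_error(downsample_alleles(aln, 1L, 131L), "exceeds")
})

test_that("downsampling is hypergeometric in expectation", {
  # A x100 + T x30, n_target 128: E[T] = 128 * 30 / 130
  seqs <- c(rep("T", 30), rep("A", 100))
  aln <- gene_alignment("g1", seqs, "A", exons = list(c(0, 1)))
  tcounts <- vapply(1:10000, function(s)
    downsample_alleles(aln, 1L, 128L, seed = s)$counts["T", 1], integer(1))
  expect_true(all(tcounts >= 2 & tcounts <= 30))
  m <- 128 * 30 / 130
  v <- 128 * (30 / 130) * (100 / 130) * (130 - 128) / (130 - 1)
  expect_lt(abs(mean(tcounts) - m), 3 * sqrt(v / 10000))
})

test_that("divergence haplotype choice is seed-deterministic and uniform", {
  seqs <- rep("GGG", 8)
  aln <- gene_alignment("g1", seqs, "GGG", exons = list(c(0, 3)))
  expect_identical(pick_divergence_haplotype(aln, seed = 11),
                   pick_divergence_haplotype(aln, seed = 11))
  draws <- vapply(1:10000, function(s) pick_divergence_haplotype(aln, s),
                  integer(1))
  f1 <- mean(draws == 1)
  expect_lt(abs(f1 - 1 / 8), 3 * sqrt((1 / 8) * (7 / 8) / 10000))
})

test_that("coding-site classification follows codon degeneracy and the same-amino-acid filter", {
  # 20 codons, no margin: GGG -> positions 1,2 are 0-fold, 3 is 4-fold
  aln <- make_aln(rep("GGG", 20))
  cs <- classify_coding_sites(aln, aln$exons, core_margin_codons = 0L)
  expect_length(cs$sites_0fold, 40)
  expect_length(cs$sites_4fold, 20)
  expect_true(all(cs$sites_4fold %% 3 == 0))

  # outgroup codon GAA (Glu) vs ingroup GGA (Gly): third position dropped
  # from the 4-fold class, first two positions keep their 0-fold status
  aln2 <- make_aln(rep("GGA", 10), outgroup_patches = list(list(2, "A")))
  cs2 <- classify_coding_sites(aln2, aln2$exons, core_margin_codons = 0L)
  expect_length(cs2$sites_4fold, 9)
  expect_length(cs2$sites_0fold, 20)

  # ATG (Met): all three positions 0-fold
  aln3 <- make_aln(rep("ATG", 5))
  cs3 <- classify_coding_sites(aln3, aln3$exons, core_margin_codons = 0L)
  expect_length(cs3$sites_0fold, 15)
  expect_length(cs3$sites_4fold, 0)

  # exon-core margin removes boundary codons
  cs4 <- classify_coding_sites(aln, aln$exons, core_margin_codons = 8L)
  expect_length(cs4$sites_4fold, 20 - 16)
})

test_that("codons containing N in any sequence are skipped", {
  aln <- make_aln(rep("GGG", 10), ingroup_patches = list(list(2, 5, "N")))
  cs <- classify_coding_sites(aln, aln$exons, core_margin_codons = 0L)
  expect_length(cs$sites_4fold, 9)
  expect_length(cs$sites_0fold, 18)
})

test_that("short-intron extraction applies length, position, junction and quality rules", {
  body <- function(len) paste0("GT", strrep("T", len - 4), "AG")
  mk <- function(ilens, n_hap = 3) {
    exon <- strrep("GGG", 10)
    seqstr <- paste0(exon, paste(vapply(ilens, body, character(1)),
                                 collapse = ""))
    ivs <- list(); pos <- 30L
    for (l in ilens) { ivs <- c(ivs, list(c(pos, pos + l))); pos <- pos + l }
    gene_alignment("g1", rep(seqstr, n_hap), seqstr,
                   exons = list(c(0, 30)), introns = ivs)
  }
  expect_length(extract_short_intron_sites(mk(c(66, 66))), 0)   # too long
  expect_length(extract_short_intron_sites(mk(c(65, 60))), 46)  # 23 each
  expect_length(extract_short_intron_sites(mk(c(60))), 0)       # one intron
  # position range: a 30-bp intron contributes 8..28 only (AG kept clear)
  expect_length(extract_short_intron_sites(mk(c(30, 60))), 21 + 23)
})

test_that("site classes are disjoint and frames are stop-free on a mixed gene", {
  intron <- paste0("GT", strrep("T", 56), "AG")
  exon <- strrep("GGATTCGCC", 8)  # GGA TTC GCC x8 = 24 codons
  seqstr <- paste0(exon, intron, intron)
  aln <- gene_alignment("g1", rep(seqstr, 4), seqstr,
                        exons = list(c(0, nchar(exon))),
                        introns = list(c(nchar(exon), nchar(exon) + 60),
                                       c(nchar(exon) + 60, nchar(exon) + 120)))
  sites <- classify_gene_sites(aln, core_margin_codons = 2L)
  all_cols <- c(sites$sites_0fold, sites$sites_4fold, sites$sites_intron)
  expect_equal(anyDuplicated(all_cols), 0L)
  expect_gt(length(sites$sites_intron), 0)
  for (iv in sites$retained_exons) {
    s <- paste(aln$ingroup[1, (iv[1] + 1):iv[2]], collapse = "")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1]]
    expect_false(any(aa == "*"))
  }
})

test_that("minus-strand genes are reverse-complemented to the coding strand at load", {
  # coding-strand GGG codons, stored flipped
  fwd <- strrep("GGG", 10)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  aln <- gene_alignment("g1", rep(rc, 3), rc, exons = list(c(0, 30)),
                        strand = "-")
  expect_equal(paste(aln$ingroup[1, 1:3], collapse = ""), "GGG")
  cs <- classify_coding_sites(aln, filter_and_trim_exons(aln),
                              core_margin_codons = 0L)
  expect_length(cs$sites_4fold, 10)
})
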