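## Standard genetic code and codon degeneracy.

GENCODE <- Biostrings::GENETIC_CODE

#' Degeneracy class of each position of a codon
#'
#' A position is 0-fold degenerate if every possible base change there is
#' nonsynonymous, and 4-fold degenerate if all four bases encode the same
#' amino acid. Positions that are neither (2- or 3-fold) are reported as
#' `"other"`.
#'
#' @param codon A 3-letter DNA codon (A/C/G/T).
#' @return Character vector of length 3 with values `"0fold"`, `"4fold"` or
#'   `"other"`; all `NA` for codons containing non-ACGT characters or stops.
#' @export
codon_degeneracy <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) return(rep(NA_character_, 3))
  aa <- GENCODE[[codon]]
  if (aa == "*") return(rep(NA_character_, 3))
  bases <- c("A", "C", "G", "T")
  vapply(1:3, function(pos) {
    alt <- setdiff(bases, substr(codon, pos, pos))
    aas <- vapply(alt, function(b) {
      mut <- codon
      substr(mut, pos, pos) <- b
      GENCODE[[mut]]
    }, character(1))
    if (all(aas != aa)) "0fold" else if (all(aas == aa)) "4fold" else "other"
  }, character(1))
}

# Precomputed degeneracy lookup for all sense codons: 3 x 61 matrix.
degeneracy_table <- function() {
  cache_get("degtab", function() {
    codons <- names(GENCODE)[GENCODE != "*"]
    vapply(codons, codon_degeneracy, character(3))
  })
}

translate_codons <- function(codons) {
  out <- GENCODE[toupper(codons)]
  unname(out)
}
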