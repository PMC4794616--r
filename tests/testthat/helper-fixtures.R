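# Shared fixture builders and independent oracles.

# A minimal gene alignment: `codons` gives the shared codon sequence; per-
# haplotype or outgroup overrides patch single columns (1-based).
make_aln <- function(codons = rep("GGG", 20), n_hap = 4,
                     ingroup_patches = list(), outgroup_patches = list(),
                     introns = list(), gene_id = "gX") {
  seqstr <- paste(codons, collapse = "")
  L <- nchar(seqstr)
  ing <- rep(seqstr, n_hap)
  for (p in ingroup_patches) {  # list(hap, col, base)
    s <- ing[p[[1]]]
    substr(s, p[[2]], p[[2]]) <- p[[3]]
    ing[p[[1]]] <- s
  }
  outg <- seqstr
  for (p in outgroup_patches) substr(outg, p[[1]], p[[1]]) <- p[[2]]
  gene_alignment(gene_id, ing, outg, exons = list(c(0, L)),
                 introns = introns)
}

# Brute-force degeneracy oracle: mutate each position to all 3 alternatives
# and translate with Biostrings.
oracle_degeneracy <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  if (is.na(aa) || aa == "*") return(rep(NA_character_, 3))
  sapply(1:3, function(pos) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
    aas <- sapply(alts, function(b) {
      m <- codon; substr(m, pos, pos) <- b; code[[m]]
    })
    if (all(aas != aa)) "0fold" else if (all(aas == aa)) "4fold" else "other"
  })
}

# Independently coded tricube weighted local-quadratic fit at one query
# point, mimicking span-1 LOESS (all points in the window, distances scaled
# by the farthest).
oracle_loess_at <- function(x, y, x0) {
  d <- abs(x - x0)
  w <- (1 - (d / max(d))^3)^3
  X <- cbind(1, x - x0, (x - x0)^2)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  beta[1]
}
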