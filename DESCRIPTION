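Package: hriquant
Title: Quantifying the Adaptive Substitutions Lost to Hill-Robertson
    Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for estimating how much Hill-Robertson interference
    (HRi) reduces the rate of adaptive protein evolution in a Drosophila-like
    genome. From per-gene ortholog alignments it derives folded site frequency
    spectra and divergence at 0-fold, 4-fold and short-intron sites, fits a
    two-epoch demography and a gamma distribution of fitness effects per bin
    of genes to obtain the adaptive nonsynonymous substitution rate Ka+, splits
    synonymous divergence into independent variates by hypergeometric sampling,
    fits linear, curvilinear and LOESS models of Ka+ against recombination
    rate, and estimates the fraction f_HRi of adaptive substitutions lost to
    interference, with bootstrap-by-gene confidence intervals and permutation
    tests. A Poisson-random-field synthetic genome generator with known ground
    truth supports calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
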