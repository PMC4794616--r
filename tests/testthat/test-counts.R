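test_that("folding works by hand at n = 4", {
  # counts {1,3}, {2,2}, {0,4}: folded = [1, 1] plus one monomorphic column
  bc <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  bc["A", 1] <- 1L; bc["G", 1] <- 3L
  bc["A", 2] <- 2L; bc["T", 2] <- 2L
  bc["C", 3] <- 4L
  fc <- fold_columns(bc, 4L)
  expect_equal(fc$sfs, c(1L, 1L))
  expect_equal(fc$n_monomorphic, 1L)
  expect_equal(fc$n_excluded, 0L)
})

test_that("monomorphic data give a zero SFS of length floor(n/2)", {
  bc <- matrix(0L, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  bc["G", ] <- 128L
  fc <- fold_columns(bc, 128L)
  expect_equal(fc$sfs, integer(64))
  expect_equal(fc$n_monomorphic, 10L)
})

test_that("tri-allelic columns are excluded (or an error in strict mode)", {
  bc <- matrix(0L, 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  bc[c("A", "C", "G"), 1] <- c(2L, 2L, 4L)
  expect_equal(fold_columns(bc, 8L)$n_excluded, 1L)
  expect_error(fold_columns(bc, 8L, strict = TRUE), "more than two")
})

test_that("neutral columns sampled from the 1/x frequency law fold to the Watterson shape", {
  # independent construction: population frequencies on a fine grid with
  # density 1/x, binomial sampling of n chromosomes, folding
  set.seed(7)
  n <- 10L
  xgrid <- (1:1999) / 2000
  x <- sample(xgrid, 4e4, replace = TRUE, prob = 1 / xgrid)
  k <- rbinom(length(x), n, x)
  k <- k[k >= 1 & k <= n - 1]
  minor <- pmin(k, n - k)
  sfs <- build_folded_sfs(minor, n)
  i <- 1:5
  expected <- (1 / i + 1 / (n - i)); expected[5] <- 1 / 5  # i = n/2 once
  expected <- expected / sum(expected)
  observed <- sfs / sum(sfs)
  se <- sqrt(expected * (1 - expected) / sum(sfs))
  expect_true(all(abs(observed - expected) < 4 * se))
})

test_that("substitution counting respects comparability", {
  expect_equal(count_substitutions(c("A", "C"), c("A", "C"))$D, 0)
  r <- count_substitutions(c(rep("A", 98), "C", "G"),
                           c(rep("A", 98), "T", "G"))
  expect_equal(r$D, 1); expect_equal(r$L, 100)
  r2 <- count_substitutions(c("A", "C"), c("N", "C"))
  expect_equal(r2$L, 1)
  # ts/tv split
  r3 <- count_substitutions(c("A", "A", "A"), c("G", "C", "T"))
  expect_equal(r3$D_ts, 1); expect_equal(r3$D_tv, 2)
})

test_that("Jukes-Cantor correction matches the closed form and dominates p", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.10), 0.1073256, tolerance = 1e-6)
  expect_equal(jc_correct(0.05), 0.0517447, tolerance = 1e-6)
  p <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(jc_correct(p) >= p))
  expect_true(all(diff(jc_correct(p)) > 0))
  expect_error(jc_correct(0.75), "saturated")
})

test_that("Tamura correction reduces to Kimura 2P at GC = 0.5 and is continuous there", {
  P <- 0.1; Q <- 0.05
  k2p <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(tamura_correct(P, Q, 0.5), k2p, tolerance = 1e-12)
  expect_equal(tamura_correct(0, 0, 0.5), 0)
  # continuity in theta_gc near 0.5
  ks <- vapply(seq(0.45, 0.55, by = 0.01),
               function(th) tamura_correct(P, Q, th), numeric(1))
  expect_true(all(abs(diff(ks)) < 0.01))
  expect_true(all(tamura_correct(P, Q, seq(0.2, 0.8, 0.1)) >= P + Q))
  expect_error(tamura_correct(0.5, 0.3, 0.5), "saturated")
})

test_that("Fop is the optimal fraction of degenerate codons", {
  opt <- c("GCC", "ACC")
  expect_equal(compute_fop(strrep("GCC", 5), opt), 1.0)
  expect_equal(compute_fop(strrep("GCT", 5), opt), 0.0)
  expect_equal(compute_fop(paste0(strrep("GCC", 3), strrep("GCT", 7)), opt), 0.3)
  # Met/Trp excluded from the denominator
  expect_equal(compute_fop(paste0("ATG", "TGG", "GCC"), opt), 1.0)
  expect_warning(fp <- compute_fop("ATGTGG", opt), "undefined")
  expect_true(is.na(fp))
})

test_that("Fop is invariant to synonymous shuffles that preserve the optimal split", {
  opt <- dmel_optimal_codons()
  s1 <- paste0("GCC", "GCT", "AAG", "AAA", "TTC")
  s2 <- paste0("GCT", "GCC", "AAA", "AAG", "TTC")  # same split, reordered
  expect_equal(compute_fop(s1, opt), compute_fop(s2, opt))
})

test_that("gene density is an interval union per 100 kb with end truncation", {
  expect_equal(gene_density(data.frame(start = integer(0), end = integer(0)),
                            50000), 0)
  expect_equal(gene_density(data.frame(start = 49000, end = 52000), 50000),
               3000)
  # two 1000-bp exons overlapping by 100 count 1900 once
  expect_equal(gene_density(data.frame(start = c(10000, 10900),
                                       end = c(11000, 11900)), 50000), 1900)
  # window truncated at the arm start: 3000 covered of 60 kb surveyed
  expect_equal(gene_density(data.frame(start = 0, end = 3000), 10000,
                            arm_length = 1e6), 3000 / 60000 * 1e5)
  expect_error(gene_density(data.frame(start = 1, end = 2), -5), "outside")
})

test_that("gene density equals a brute-force coverage oracle on random annotations", {
  set.seed(13)
  for (i in 1:50) {
    n_ex <- sample(1:20, 1)
    start <- sample(0:99000, n_ex)
    end <- start + sample(50:5000, n_ex, replace = TRUE)
    mid <- sample(50000:90000, 1)  # window clear of the arm start
    # oracle: mark covered positions in the window directly
    lo <- mid - 50000; hi <- mid + 50000
    covered <- logical(hi - lo)
    for (j in seq_len(n_ex)) {
      a <- max(start[j], lo); b <- min(end[j], hi)
      if (a < b) covered[(a - lo + 1):(b - lo)] <- TRUE
    }
    expect_equal(gene_density(data.frame(start = start, end = end), mid),
                 sum(covered) / (hi - lo) * 1e5)
  }
})

test_that("recombination lookup uses half-open 100-kb windows without smoothing", {
  recmap <- data.frame(arm = "2L", start = c(1e5, 2e5), end = c(2e5, 3e5),
                       cM_per_Mb = c(2.5, 4))
  expect_equal(assign_rr(recmap, "2L", 150000), 2.5)
  expect_equal(assign_rr(recmap, "2L", 200000), 4)    # boundary: right window
  expect_warning(rr <- assign_rr(recmap, "2L", 5e5), "not covered")
  expect_true(is.na(rr))
})

test_that("SFS bookkeeping conserves sites per class on a simulated gene", {
  p <- sim_params(n_genes = 4L, n_chromosomes = 8L, G = 64L,
                  theta4 = 0.02, demog = demography())
  fx <- emit_fixtures(p, seed = 5, out_dir = file.path(tempdir(), "cons"))
  gs <- read_fixture_counts(file.path(tempdir(), "cons"), 8L, seed = 5)
  # every segregating site counted in the SFS is one of the class's sites
  expect_true(all(rowSums(gs$sfs4) <= gs$tab$L4))
  expect_true(all(rowSums(gs$sfs0) <= gs$tab$L0))
})
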