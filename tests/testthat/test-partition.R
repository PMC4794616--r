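test_that("hypergeometric split parts always sum to D4 (closure identity)", {
  for (s in 1:50) {
    sp3 <- split_k4(c(0L, 30L, 300L, 17L), c(10L, 300L, 300L, 60L),
                    parts = 3, seed = s)
    expect_true(all(sp3$d4_1 + sp3$d4_2 + sp3$d4_3 ==
                    c(0L, 30L, 300L, 17L)))
    expect_true(all(sp3$d4_1 >= 0 & sp3$d4_2 >= 0 & sp3$d4_3 >= 0))
    sp2 <- split_k4(c(10L, 100L), c(100L, 100L), parts = 2, seed = s)
    expect_true(all(sp2$d4_1 + sp2$d4_2 == c(10L, 100L)))
  }
})

test_that("degenerate splits behave as expected", {
  sp <- split_k4(0L, 300L, parts = 3, seed = 1)
  expect_equal(unlist(sp[1, 1:3]), c(d4_1 = 0L, d4_2 = 0L, d4_3 = 0L))
  # saturated gene: every part at rate 1
  sp2 <- split_k4(100L, 100L, parts = 2, seed = 9)
  expect_equal(sp2$k4_1, 1); expect_equal(sp2$k4_2, 1)
  expect_error(split_k4(301L, 300L), "exceeds")
})

test_that("split means match the hypergeometric oracle", {
  # D4 = 30 of L4 = 300; draw round(0.33*300) = 99 sites:
  # E[d4_1] = 99 * 30/300 = 9.9, so E[K4_1] = 9.9 / 100 = 0.099
  d1 <- vapply(1:10000, function(s)
    split_k4(30L, 300L, parts = 3, seed = s)$k4_1, numeric(1))
  v <- 99 * (30 / 300) * (270 / 300) * (300 - 99) / 299 / 100^2
  expect_lt(abs(mean(d1) - 0.099), 3 * sqrt(v / 10000))
})

test_that("rank binning reproduces the 45 x 136 layout and handles ties deterministically", {
  set.seed(2)
  key <- runif(6141)
  rb <- rank_bin(key, sprintf("g%05d", 1:6141), 45)
  expect_length(rb$bins, 45)
  expect_true(all(lengths(rb$bins) == 136))
  expect_length(rb$discarded, 21)
  # discarded genes are the highest-ranked leftovers
  expect_true(min(key[rb$discarded]) >= max(key[rb$bins[[45]]]))

  rb2 <- rank_bin(runif(10), sprintf("g%02d", 1:10), 2)
  expect_true(all(lengths(rb2$bins) == 5))
  expect_length(rb2$discarded, 0)

  # all-equal keys: assignment fixed by gene_id, invariant to input order
  ids <- sprintf("g%02d", 1:10)
  perm <- sample(10)
  rb_a <- rank_bin(rep(1, 10), ids, 2)
  rb_b <- rank_bin(rep(1, 10), ids[perm], 2)
  expect_equal(sort(ids[rb_a$bins[[1]]]), sort(ids[perm][rb_b$bins[[1]]]))
  expect_error(rank_bin(1:3, n_bins = 5), "more bins")
})

test_that("nested partition produces the 2x2 categories and per-category bins", {
  set.seed(3)
  n <- 6144
  df <- data.frame(gene_id = sprintf("g%05d", 1:n), density = runif(n),
                   k4_1 = runif(n), rr = runif(n, 0, 10))
  np <- nested_partition(df, list(list(key = "density", levels = 2),
                                  list(key = "k4_1", levels = 2),
                                  list(key = "rr", bins = 12)))
  expect_setequal(vapply(np, `[[`, character(1), "label"),
                  c("GenH-MutH", "GenH-MutL", "GenL-MutH", "GenL-MutL"))
  expect_true(all(unlist(lapply(np, function(g) lengths(g$bins))) == 128))
  # density halves really split on density
  labs <- vapply(np, `[[`, character(1), "label")
  hi <- unlist(lapply(np[grep("GenH", labs)], function(g) unlist(g$bins)))
  lo <- unlist(lapply(np[grep("GenL", labs)], function(g) unlist(g$bins)))
  expect_gt(min(df$density[hi]), max(df$density[lo]) - 1e-12)

  # a single-factor spec reduces to rank_bin
  np1 <- nested_partition(df, list(list(key = "rr", bins = 12)))
  rb <- rank_bin(df$rr, df$gene_id, 12)
  expect_equal(np1[[1]]$bins, rb$bins)
  expect_error(nested_partition(df[1:100, ],
                                list(list(key = "density", levels = 2),
                                     list(key = "rr", bins = 12)),
                                bin_size = 128), "too few")
})

test_that("pooled bin counts equal per-gene sums", {
  p <- sim_params(n_genes = 200L)
  gs <- simulate_genes(p, seed = 8)
  gs$tab <- cbind(gs$tab, split_k4(gs$tab$D4, gs$tab$L4, 3, seed = 9))
  idx <- sample(200, 40)
  bin <- pool_genes(gs, idx, estimate_part = 2, n_parts = 3)
  expect_equal(bin$D0, sum(gs$tab$D0[idx]))
  expect_equal(bin$L0, sum(gs$tab$L0[idx]))
  expect_equal(bin$D4, sum(gs$tab$d4_2[idx]))
  expect_equal(bin$L4, sum(gs$tab$L4[idx]) / 3)
  expect_equal(bin$sfs4, colSums(gs$sfs4[idx, ]))
  expect_equal(bin$mean_rr, mean(gs$tab$rr[idx]))
})

test_that("splitting decouples the ranking variate from the estimate (artifact avoidance)", {
  # no mutation heterogeneity and no true mutation-adaptation link: the
  # correlation between bin mean K4_3 and bin Ka+ must be centred at zero
  # when ranking uses K4_1 and estimation K4_2, whereas reusing the same
  # part for both induces the negative sampling artifact
  p <- sim_params(n_genes = 900L, mut_sdlog = 0)
  split_cor <- function(seed, same_part) {
    gs <- simulate_genes(p, seed = seed)
    ff <- gs$truth$fixation_factor
    gs$tab <- cbind(gs$tab, split_k4(gs$tab$D4, gs$tab$L4, 3,
                                     seed = seed + 1000))
    rb <- rank_bin(gs$tab$k4_1, gs$tab$gene_id, 10)
    est <- vapply(rb$bins, function(b) {
      part <- if (same_part) "d4_1" else "d4_2"
      ka <- jc_correct(sum(gs$tab$D0[b]) / sum(gs$tab$L0[b]))
      k4 <- jc_correct(sum(gs$tab[[part]][b]) / (sum(gs$tab$L4[b]) / 3))
      ka - k4 * ff
    }, numeric(1))
    k43 <- vapply(rb$bins, function(b)
      sum(gs$tab$d4_3[b]) / (sum(gs$tab$L4[b]) / 3), numeric(1))
    k4rank <- vapply(rb$bins, function(b)
      sum(gs$tab[[if (same_part) "d4_1" else "d4_1"]][b]) /
        (sum(gs$tab$L4[b]) / 3), numeric(1))
    cor(if (same_part) k4rank else k43, est, method = "spearman")
  }
  decoupled <- vapply(1:20, split_cor, numeric(1), same_part = FALSE)
  coupled <- vapply(1:20, split_cor, numeric(1), same_part = TRUE)
  # sign test: decoupled correlations straddle zero
  expect_gte(sum(decoupled > 0), 4)
  expect_lte(sum(decoupled > 0), 16)
  # reusing the ranking part induces predominantly negative correlation
  expect_gte(sum(coupled < 0), 15)
})
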