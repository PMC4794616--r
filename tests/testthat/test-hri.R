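test_that("linear fit is exact on noiseless lines", {
  x <- seq(0, 9, length.out = 45)
  f <- fit_linear(x, 1 + 2 * x)
  expect_equal(f$a, 1, tolerance = 1e-10)
  expect_equal(f$b, 2, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_error(fit_linear(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_linear(rep(1, 5), 1:5), "degenerate")
})

test_that("curvilinear fit nests the line and flags an unidentifiable decay", {
  x <- seq(0.1, 9, length.out = 45)
  lin_y <- 0.002 + 0.001 * x
  flin <- fit_linear(x, lin_y)
  fcur <- fit_curvilinear(x, lin_y)
  expect_lte(fcur$rss, flin$rss + 1e-12)
  # constant data: a recovered as the mean, c not identifiable
  fconst <- fit_curvilinear(x, rep(0.01, 45))
  expect_equal(fconst$a + fconst$b * mean(exp(-fconst$c * x)), 0.01,
               tolerance = 1e-6)
  expect_false(fconst$c_identifiable)
  expect_error(fit_curvilinear(1:3, 1:3), "at least 4")
})

test_that("model comparison degenerates and concords correctly", {
  x <- seq(0.1, 9, length.out = 20)
  y <- 0.01 - 0.008 * exp(-1.5 * x)
  flin <- fit_linear(x, y)
  fsame <- flin; fsame$rss <- flin$rss; fsame$df_resid <- flin$n - 3L
  fsame$aic <- flin$aic; fsame$n <- flin$n
  cmp0 <- compare_fits(flin, fsame)
  expect_equal(cmp0$F, 0); expect_equal(cmp0$p, 1)

  # concordance of delta AIC with the F test, and nominal size of the F
  # test on linear-truth data
  set.seed(11)
  agree <- logical(1000); reject <- logical(1000)
  for (i in 1:1000) {
    yy <- 0.005 + 0.0008 * x + rnorm(20, 0, 0.001)
    fl <- fit_linear(x, yy); fc <- fit_curvilinear(x, yy)
    cmp <- suppressWarnings(compare_fits(fl, fc))
    agree[i] <- (cmp$delta_aic > 0) == (cmp$p < 0.157)  # AIC ~ F at 2 units
    reject[i] <- cmp$p < 0.05
  }
  expect_gte(mean(agree), 0.95)
  # rejection rate within the binomial band around the nominal 5 %
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("LOESS predictions are exact where local quadratics are exact", {
  x <- seq(0, 10, length.out = 20)
  expect_equal(loess_predict(x, rep(3, 20)), rep(3, 20), tolerance = 1e-9)
  y <- 1 + 0.5 * x - 0.03 * x^2
  expect_equal(loess_predict(x, y), y, tolerance = 1e-7)
  expect_error(loess_predict(x, y, span = 0), "span")
  expect_error(loess_predict(x, y, span = 1.2), "span")
  expect_error(loess_predict(1:4, 1:4), "at least 5")
})

test_that("LOESS agrees with an independently coded tricube weighted fit", {
  set.seed(5)
  x <- sort(runif(25, 0, 8))
  y <- 0.012 - 0.01 * exp(-1.2 * x) + rnorm(25, 0, 5e-4)
  pred <- loess_predict(x, y, span = 1)
  for (q in c(3, 12, 24))
    expect_equal(pred[q], oracle_loess_at(x, y, x[q]), tolerance = 1e-6)
})

test_that("asymptote is the mean over eligible bins", {
  expect_equal(asymptotic_ka(c(3, 4, 5), rep(0.01, 3), 2), 0.01)
  expect_equal(asymptotic_ka(c(1.5, 3, 4), c(0.002, 0.01, 0.012), 2), 0.011)
  expect_error(asymptotic_ka(c(1, 2, 3), 1:3 / 100, 5), "threshold")
})

test_that("loss accounting satisfies the ratio identity and clamping bounds", {
  L0 <- c(1e5, 2e5, 3e5); rr <- c(0.5, 1.5, 4); ka0 <- 0.01
  pred <- c(-0.002, 0.004, 0.0101)
  r <- estimate_fhri(L0, rr, pred, ka0, rr_threshold = 2, clamp = FALSE)
  expect_equal(r$f_hri, r$total_lost / r$total_no_hri)
  expect_equal(r$total_no_hri, sum(L0) * ka0)
  expect_equal(r$total_lost, 1e5 * (ka0 + 0.002) + 2e5 * (ka0 - 0.004))
  rc <- estimate_fhri(L0, rr, pred, ka0, rr_threshold = 2, clamp = TRUE)
  expect_equal(rc$total_lost, 1e5 * ka0 + 2e5 * (ka0 - 0.004))
  expect_true(rc$f_hri >= 0 && rc$f_hri <= 1)
  # clamping with all below-threshold predictions <= 0: the whole
  # below-threshold expectation is lost
  rall <- estimate_fhri(L0, rr, c(-1e-3, -2e-3, 0.01), ka0, 2, clamp = TRUE)
  expect_equal(rall$f_hri, (1e5 + 2e5) * ka0 / (sum(L0) * ka0))
  # predictions at the asymptote: nothing lost
  r0 <- estimate_fhri(L0, rr, rep(ka0, 3), ka0, 2)
  expect_equal(r0$f_hri, 0)
})

test_that("category loss totals reproduce ratios from printed-style inputs", {
  expect_equal(fhri_from_totals(9.97, 15.46), 15.46 / 25.43, tolerance = 1e-12)
  expect_equal(round(fhri_from_totals(9.97, 15.46), 2), 0.61, tolerance = 0.02)
})

test_that("Spearman correlation matches a brute-force rank computation", {
  expect_equal(spearman_rho(1:10, 1:10)$rho, 1)
  expect_equal(spearman_rho(1:10, 10:1)$rho, -1)
  set.seed(6)
  x <- rnorm(10); y <- rnorm(10)
  brute <- {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(spearman_rho(x, y)$rho, brute, tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("ANCOVA distinguishes intercept shifts from slope heterogeneity", {
  set.seed(42)
  x <- rep(seq(1, 10), 2)
  g <- rep(c("a", "b"), each = 10)
  # statistically identical groups: group tests null
  y_same <- 2 + 0.5 * x + rnorm(20, 0, 0.1)
  t_same <- ancova_tests(y_same, x, g)
  expect_gt(t_same$p[t_same$test == "intercepts"], 0.1)
  # parallel offset, noiseless: intercepts significant, slopes not
  y_off <- 2 + 0.5 * x + ifelse(g == "b", 3, 0) + rnorm(20, 0, 0.05)
  t_off <- ancova_tests(y_off, x, g)
  expect_lt(t_off$p[t_off$test == "intercepts"], 1e-6)
  expect_gt(t_off$p[t_off$test == "slope_heterogeneity"], 0.01)
  expect_error(ancova_tests(1:6, 1:6, rep("a", 6)), "2 groups")

  # power for heterogeneous slopes at a strong configured effect
  set.seed(7)
  hits <- vapply(1:20, function(i) {
    y <- 2 + ifelse(g == "b", 1.0, 0.5) * x + rnorm(20, 0, 0.2)
    ancova_tests(y, x, g)$p[3] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
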