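## Interference quantification: curve fits of Ka+ against recombination,
## LOESS predictions, the no-HRi asymptote and the fraction of adaptive
## substitutions lost.

gauss_aic <- function(rss, n, k) n * log(2 * pi * rss / n) + n + 2 * k

#' Linear fit of bin Ka+ against recombination rate
#'
#' Ordinary least squares \eqn{y = a + b x} with \eqn{R^2} and Gaussian AIC
#' (the error variance counted as a parameter, so k = 3).
#'
#' @param x,y Bin-level recombination rates and Ka+ estimates (>= 3 points).
#' @return A list of class `curve_fit` with `kind = "linear"`, `a`, `b`,
#'   `r2`, `aic`, `rss`, `df_resid`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("linear fit needs at least 3 points")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  fit <- lm(y ~ x)
  rss <- sum(resid(fit)^2)
  structure(list(kind = "linear", a = unname(coef(fit)[1]),
                 b = unname(coef(fit)[2]), c = NA_real_,
                 r2 = 1 - rss / sum((y - mean(y))^2),
                 aic = gauss_aic(rss, length(x), 3),
                 rss = rss, df_resid = length(x) - 2L, n = length(x)),
            class = "curve_fit")
}

# RSS of the conditional linear solve of y ~ a + b*exp(-c*x) at fixed c.
curvi_profile <- function(cc, x, y) {
  z <- exp(-cc * x)
  fit <- lm(y ~ z)
  list(rss = sum(resid(fit)^2), a = unname(coef(fit)[1]),
       b = unname(coef(fit)[2]))
}

#' Curvilinear fit y = a + b exp(-c x)
#'
#' Profile nonlinear least squares: for each candidate decay rate `c` the
#' conditionally linear `a`, `b` come from an exact least-squares solve, and
#' `c` is optimised over a bracket around each start; the best profile
#' solution over all starts is kept. As x grows the prediction approaches
#' the asymptote `a`.
#'
#' @param x,y Data (>= 4 points).
#' @param starts Multi-start grid for `c`.
#' @return A `curve_fit` list with `kind = "curvilinear"`, coefficients
#'   `a`, `b`, `c`, `r2`, Gaussian `aic` (k = 4), `rss`, `df_resid`, and
#'   `c_identifiable` (FALSE when `b` is essentially 0).
#' @export
fit_curvilinear <- function(x, y, starts = c(0.25, 0.5, 1, 2, 4)) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("curvilinear fit needs at least 4 points")
  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    res <- tryCatch({
      opt <- optimize(function(lc) curvi_profile(exp(lc), x, y)$rss,
                      interval = log(c(st / 16, st * 16)), tol = 1e-12)
      cc <- exp(opt$minimum)
      c(list(c = cc), curvi_profile(cc, x, y))
    }, error = function(e) {
      diagnostics <<- c(diagnostics, sprintf("start %.3g: %s", st, conditionMessage(e)))
      NULL
    })
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  # small-decay candidates cover the linear limit, where the model nests
  # the straight line
  for (cc in c(1e-5, 1e-4, 1e-3)) {
    res <- tryCatch(c(list(c = cc), curvi_profile(cc, x, y)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  if (is.null(best))
    stop("curvilinear fit failed from all starts: ",
         paste(diagnostics, collapse = "; "))
  n <- length(x)
  tss <- sum((y - mean(y))^2)
  structure(list(kind = "curvilinear", a = best$a, b = best$b, c = best$c,
                 r2 = 1 - best$rss / tss,
                 aic = gauss_aic(best$rss, n, 4),
                 rss = best$rss, df_resid = n - 3L, n = n,
                 c_identifiable = abs(best$b) > 1e-10 * max(1, sd(y))),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  if (x$kind == "linear")
    cat(sprintf("linear fit: a = %.6g, b = %.6g, R2 = %.3f, AIC = %.2f\n",
                x$a, x$b, x$r2, x$aic))
  else
    cat(sprintf("curvilinear fit: a = %.6g, b = %.6g, c = %.6g, R2 = %.3f, AIC = %.2f\n",
                x$a, x$b, x$c, x$r2, x$aic))
  invisible(x)
}

#' Compare the linear and curvilinear fits
#'
#' Extra-sum-of-squares F test (the curvilinear model has one extra
#' parameter) with (1, n - 3) degrees of freedom, plus the AIC difference.
#'
#' @param linear,curvilinear Fits from [fit_linear()] and
#'   [fit_curvilinear()] on the same data.
#' @return A list with `F`, `p`, `delta_aic` (linear minus curvilinear; a
#'   positive value favours the curvilinear model).
#' @export
compare_fits <- function(linear, curvilinear) {
  stopifnot(linear$n == curvilinear$n)
  df2 <- curvilinear$df_resid
  Fstat <- (linear$rss - curvilinear$rss) / (curvilinear$rss / df2)
  if (Fstat < 0) {
    warning("curvilinear RSS exceeds linear RSS; F floored at 0")
    Fstat <- 0
  }
  list(F = Fstat, p = pf(Fstat, 1, df2, lower.tail = FALSE),
       delta_aic = linear$aic - curvilinear$aic)
}

#' LOESS predictions of bin Ka+ at the observed recombination rates
#'
#' Local quadratic regression with tricube weights; the smoothing span
#' defaults to 1 (every local fit sees all points, weighted by distance),
#' which keeps the curve stable across bootstrap replicates.
#'
#' @param x,y Data (>= 5 points).
#' @param span Fraction of points in each local fit, in (0, 1].
#' @return Numeric vector of predictions at the observed `x`.
#' @export
loess_predict <- function(x, y, span = 1.0) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(x) < 5) stop("LOESS needs at least 5 points")
  fit <- loess(y ~ x, span = span, degree = 2, family = "gaussian",
               control = loess.control(surface = "direct",
                                       statistics = "exact"))
  as.numeric(predict(fit, data.frame(x = x)))
}

#' Asymptotic Ka+ in the absence of interference
#'
#' The unweighted mean of the bin Ka+ estimates over bins whose mean
#' recombination rate exceeds the threshold, where the Ka+/recombination
#' relationship has reached its asymptote.
#'
#' @param bin_rr Bin mean recombination rates (cM/Mb).
#' @param bin_ka Bin Ka+ estimates.
#' @param rr_threshold Threshold in cM/Mb (2 by default; 5 is used for gene
#'   categories that show no asymptote by 2).
#' @return The asymptotic Ka+.
#' @export
asymptotic_ka <- function(bin_rr, bin_ka, rr_threshold = 2) {
  eligible <- bin_rr > rr_threshold
  if (!any(eligible))
    stop("no bin has mean recombination rate above ", rr_threshold,
         " cM/Mb; lower the threshold")
  mean(bin_ka[eligible])
}

#' Adaptive substitutions lost to Hill-Robertson interference
#'
#' Given per-bin 0-fold site totals, mean recombination rates, smoothed
#' Ka+ predictions and the no-HRi asymptote, computes the expected total
#' number of adaptive nonsynonymous substitutions without interference
#' (summed over all bins), the number lost (summed over bins below the
#' recombination threshold), and their ratio \eqn{f_{HRi}}.
#'
#' @param bin_L0 Total 0-fold sites per bin.
#' @param bin_rr Mean recombination rate per bin.
#' @param predictions Smoothed per-bin Ka+ (from [loess_predict()]).
#' @param ka_no_hri The asymptotic Ka+ (from [asymptotic_ka()]).
#' @param rr_threshold Bins below this rate contribute to the loss (default
#'   2 cM/Mb).
#' @param clamp Replace negative predictions by 0 before computing the loss.
#' @return A list of class `hri_result`: `ka_no_hri`, `total_no_hri`,
#'   `total_lost`, `f_hri`, `clamped`, `per_bin_predictions`.
#' @export
estimate_fhri <- function(bin_L0, bin_rr, predictions, ka_no_hri,
                          rr_threshold = 2, clamp = FALSE) {
  stopifnot(length(bin_L0) == length(bin_rr),
            length(predictions) == length(bin_rr), all(bin_L0 > 0))
  pred <- if (clamp) pmax(predictions, 0) else predictions
  total_no_hri <- sum(bin_L0 * ka_no_hri)
  if (total_no_hri <= 0) stop("total expected adaptive substitutions is zero")
  below <- bin_rr < rr_threshold
  total_lost <- sum(bin_L0[below] * (ka_no_hri - pred[below]))
  structure(list(ka_no_hri = ka_no_hri, total_no_hri = total_no_hri,
                 total_lost = total_lost, f_hri = total_lost / total_no_hri,
                 clamped = clamp, per_bin_predictions = pred),
            class = "hri_result")
}

#' @export
print.hri_result <- function(x, ...) {
  cat(sprintf("HRi: Ka+ without HRi = %.5g; substitutions expected %.4g, lost %.4g; f_HRi = %.3f%s\n",
              x$ka_no_hri, x$total_no_hri, x$total_lost, x$f_hri,
              if (x$clamped) " (negative predictions clamped)" else ""))
  invisible(x)
}

#' f_HRi from fixed and lost substitution totals
#'
#' The identity behind the headline statistic: when the adaptive
#' substitutions actually fixed (`fixed`) and those lost to interference
#' (`lost`) are known, the total that would fix under free recombination is
#' their sum, and \eqn{f_{HRi} = lost / (fixed + lost)}. Vectorised; pass
#' category totals to get per-category values, or their sums for the global
#' value.
#'
#' @param fixed,lost Substitution totals (any common unit, e.g. kb).
#' @return \eqn{f_{HRi}} values.
#' @export
fhri_from_totals <- function(fixed, lost) {
  stopifnot(length(fixed) == length(lost), all(fixed + lost > 0))
  lost / (fixed + lost)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t approximation (as `stats::cor.test` does for n this size with ties).
#'
#' @param x,y Paired observations (>= 4 pairs).
#' @return A list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Analysis of covariance across gene groups
#'
#' Fits the nested least-squares models y ~ group, y ~ group + x (parallel
#' lines) and y ~ group * x, and reports F tests for (i) the common slope,
#' (ii) intercept differences between groups at fixed x, and (iii) slope
#' heterogeneity.
#'
#' @param y,x Numeric vectors.
#' @param group Factor (>= 2 groups, each with >= 3 points).
#' @return A data.frame with one row per test (`test`, `F`, `df1`, `df2`,
#'   `p`).
#' @export
ancova_tests <- function(y, x, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 3)) stop("each group needs at least 3 points")
  m_g <- lm(y ~ group)
  m_x <- lm(y ~ x)
  m_par <- lm(y ~ group + x)
  m_int <- lm(y ~ group * x)
  row_of <- function(test, a) {
    data.frame(test = test, F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
               p = a$`Pr(>F)`[2])
  }
  rbind(row_of("common_slope", anova(m_g, m_par)),
        row_of("intercepts", anova(m_x, m_par)),
        row_of("slope_heterogeneity", anova(m_par, m_int)))
}
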