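## DFE-alpha-style inference: two-epoch demography from the neutral folded
## SFS, gamma DFE from the selected folded SFS, then alpha / omega_a / Ka+.

folded_loglik <- function(counts, proportions) {
  keep <- counts > 0
  if (!any(keep)) return(NA_real_)
  p <- pmax(proportions[keep], 1e-300)
  sum(counts[keep] * log(p))
}

#' Fit a two-epoch demography to a neutral folded SFS
#'
#' Maximum-likelihood fit (multinomial over folded frequency bins) of
#' `size_ratio` and `t2` to the folded SFS of a putatively neutral site
#' class, by Nelder-Mead over \eqn{(\log N_2/N_1, \log t_2)} from several
#' fixed starting points.
#'
#' @param sfs Folded SFS counts, length `floor(n/2)` (see [build_folded_sfs()]).
#' @param n_chromosomes Sample size the SFS was built at.
#' @param G Wright-Fisher grid size in alleles.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return A [demography()] with attributes `loglik` and `convergence`.
#' @export
fit_neutral_demography <- function(sfs, n_chromosomes, G = 200L,
                                   reltol = 1e-8) {
  if (sum(sfs) < 1) stop("neutral SFS has no segregating sites; demography unidentifiable")
  nll <- function(par) {
    dem <- demography(exp(par[1]), exp(par[2]))
    pr <- expected_folded_sfs(0, dem, n_chromosomes, G)$proportions
    -folded_loglik(sfs, pr)
  }
  starts <- list(c(0, log(0.05)), c(log(2), log(0.1)), c(log(0.5), log(0.1)),
                 c(log(4), log(0.4)), c(0, log(0.5)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("demography fit failed from all starting points")
  out <- demography(exp(best$par[1]), exp(best$par[2]))
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Fit a gamma DFE to a selected folded SFS
#'
#' Two-step fit in the DFE-alpha manner: the demography is taken as given
#' (fitted first on the neutral class), and the gamma DFE over deleterious
#' selection strengths is fitted by maximum likelihood to the folded SFS of
#' the selected class, with the DFE integrated over a fixed quadrature grid
#' of \eqn{|4 N_e s|} mass points.
#'
#' @param sfs Folded SFS counts of the selected (0-fold) class.
#' @param demog A fitted [demography()].
#' @param n_chromosomes Sample size.
#' @param G Wright-Fisher grid size in alleles.
#' @param grid Quadrature grid from [selection_grid()].
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return A [gamma_dfe()] with attributes `loglik` and `convergence`.
#' @export
fit_gamma_dfe <- function(sfs, demog, n_chromosomes, G = 200L,
                          grid = selection_grid(), reltol = 1e-8) {
  if (sum(sfs) < 1) stop("selected SFS has no segregating sites; DFE unidentifiable")
  C <- sfs_count_matrix(demog, n_chromosomes, G, grid)
  nll <- function(par) {
    dfe <- gamma_dfe(exp(par[1]), exp(par[2]))
    w <- dfe_weights(dfe, grid)
    mix <- as.numeric(C %*% w)
    tot <- sum(mix)
    if (!is.finite(tot) || tot <= 0) return(1e12)
    -folded_loglik(sfs, mix / tot)
  }
  starts <- list(c(log(10), log(0.5)), c(log(100), log(0.3)),
                 c(log(1000), log(0.3)), c(log(5000), log(0.2)),
                 c(log(200), log(1)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 600)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("gamma DFE fit failed from all starting points")
  out <- gamma_dfe(exp(best$par[1]), exp(best$par[2]))
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Adaptation estimates from a fitted DFE and divergence counts
#'
#' Predicts the nonadaptive (neutral plus deleterious) nonsynonymous
#' divergence as \eqn{d_{exp} = K_4 \, E_f[r(S)]}, where \eqn{r(S)} is the
#' relative fixation probability [fixation_relative()] averaged over the
#' fitted DFE, and attributes the excess of the observed corrected
#' nonsynonymous divergence to adaptation: \eqn{\alpha = (K_a - d_{exp})/K_a},
#' \eqn{K_{a+} = \alpha K_a}, \eqn{\omega_A = K_{a+}/K_4}.
#'
#' @param dfe A [gamma_dfe()].
#' @param demog The [demography()] it was fitted under.
#' @param D0,L0 0-fold divergent sites and 0-fold sites (Jukes-Cantor
#'   corrected internally).
#' @param D4,L4 4-fold divergent sites and 4-fold sites (used for the
#'   transition/transversion proportions when `P4_ts`/`P4_tv` are not given).
#' @param gc4 GC fraction at 4-fold sites, for the Tamura correction.
#' @param P4_ts,P4_tv Transition and transversion difference proportions at
#'   4-fold sites; default to a 1:2 ts:tv split of `D4/L4`.
#' @param grid Quadrature grid for the DFE integral.
#' @return A list of class `dfe_fit` with elements `demography`, `dfe`,
#'   `alpha`, `omega_a`, `ka`, `k4`, `ka_plus`, `d_exp` and `loglik`.
#' @export
estimate_alpha_ka_plus <- function(dfe, demog, D0, L0, D4, L4, gc4 = 0.5,
                                   P4_ts = NULL, P4_tv = NULL,
                                   grid = selection_grid()) {
  stopifnot(L0 > 0, L4 > 0)
  ka <- jc_correct(D0 / L0)
  if (is.null(P4_ts)) P4_ts <- (D4 / L4) / 3
  if (is.null(P4_tv)) P4_tv <- 2 * (D4 / L4) / 3
  k4 <- tamura_correct(P4_ts, P4_tv, gc4)
  if (ka <= 0) stop("ka is zero: alpha undefined for this bin")
  d_exp <- k4 * dfe_fixation_factor(dfe, grid)
  alpha <- (ka - d_exp) / ka
  ka_plus <- alpha * ka
  structure(list(demography = demog, dfe = dfe, alpha = alpha,
                 omega_a = ka_plus / k4, ka = ka, k4 = k4,
                 ka_plus = ka_plus, d_exp = d_exp,
                 loglik = sum(c(attr(demog, "loglik"), attr(dfe, "loglik")))),
            class = "dfe_fit")
}

#' @export
print.dfe_fit <- function(x, ...) {
  cat(sprintf("DFE fit: alpha = %.3f, Ka+ = %.5f, omega_A = %.3f (Ka = %.5f, K4 = %.5f)\n",
              x$alpha, x$ka_plus, x$omega_a, x$ka, x$k4))
  invisible(x)
}

#' Full DFE stage for one pooled bin
#'
#' Convenience wrapper running the two-step fit on a pooled bin: demography
#' on the 4-fold folded SFS, gamma DFE on the 0-fold folded SFS, then
#' [estimate_alpha_ka_plus()] on the pooled divergence counts.
#'
#' @param bin A pooled bin as produced by [rank_bin()]/[pool_genes()]: a list
#'   with `sfs4`, `sfs0`, `D0`, `L0`, `D4`, `L4`, `gc4`, `P4_ts`, `P4_tv`
#'   (the divergence slots may carry split-K4 parts).
#' @param n_chromosomes Sample size.
#' @param G Wright-Fisher grid size in alleles.
#' @param grid Quadrature grid.
#' @return A `dfe_fit` (see [estimate_alpha_ka_plus()]).
#' @export
fit_bin_dfe <- function(bin, n_chromosomes, G = 200L, grid = selection_grid()) {
  dem <- fit_neutral_demography(bin$sfs4, n_chromosomes, G)
  dfe <- fit_gamma_dfe(bin$sfs0, dem, n_chromosomes, G, grid)
  estimate_alpha_ka_plus(dfe, dem, bin$D0, bin$L0, bin$D4, bin$L4,
                         gc4 = if (is.null(bin$gc4)) 0.5 else bin$gc4,
                         P4_ts = bin$P4_ts, P4_tv = bin$P4_tv, grid = grid)
}

#' Plug-in adaptation estimate with a fixed DFE correction factor
#'
#' Fast variant of [estimate_alpha_ka_plus()] for resampling loops: the DFE
#' correction factor \eqn{E_f[r(S)]} is computed once from a fit to the full
#' data and reused, so each bin only needs its corrected divergence rates.
#' Suitable inside bootstrap or permutation replicates where refitting the
#' DFE per replicate is not affordable; the point estimates always come from
#' the full fit.
#'
#' @param D0,L0,D4,L4,gc4,P4_ts,P4_tv As in [estimate_alpha_ka_plus()].
#' @param fixation_factor Fixed \eqn{E_f[r(S)]} (see `dfe_fixation_factor`
#'   via [estimate_alpha_ka_plus()]'s `d_exp/k4`).
#' @return A list with `alpha`, `ka`, `k4`, `ka_plus`, `omega_a`.
#' @export
plugin_ka_plus <- function(D0, L0, D4, L4, fixation_factor, gc4 = 0.5,
                           P4_ts = NULL, P4_tv = NULL) {
  ka <- jc_correct(D0 / L0)
  if (is.null(P4_ts)) P4_ts <- (D4 / L4) / 3
  if (is.null(P4_tv)) P4_tv <- 2 * (D4 / L4) / 3
  k4 <- tamura_correct(P4_ts, P4_tv, gc4)
  d_exp <- k4 * fixation_factor
  alpha <- if (ka > 0) (ka - d_exp) / ka else NA_real_
  ka_plus <- ka - d_exp
  list(alpha = alpha, ka = ka, k4 = k4, ka_plus = ka_plus,
       omega_a = ka_plus / k4)
}
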