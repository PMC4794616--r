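## End-to-end analysis of a gene set: recombination bins, per-bin DFE fits,
## curve fits and the interference loss estimate.

#' Bin-level adaptation estimates along the recombination gradient
#'
#' Ranks genes into equal-size recombination-rate bins, pools counts per
#' bin, and runs the DFE stage on every bin (or the fast plug-in estimator
#' when a fixed `fixation_factor` is supplied).
#'
#' @param gs Gene set (see [simulate_genes()] / [genes_from_alignments()]).
#' @param n_bins Number of recombination bins (default 45).
#' @param n_chromosomes Sample size of the folded SFS.
#' @param G Wright-Fisher grid size.
#' @param estimate_part,n_parts Optional hypergeometric split part used for
#'   divergence-rate estimation (see [pool_genes()]).
#' @param fixation_factor If non-`NULL`, skip the per-bin DFE fit and use
#'   [plugin_ka_plus()] with this fixed DFE correction factor.
#' @param grid DFE quadrature grid.
#' @return A data.frame with one row per bin: `bin`, `n_genes`, `mean_rr`,
#'   `mean_density`, `mean_fop`, `L0`, `L4`, `D0`, `D4`, `alpha`, `ka`,
#'   `k4`, `ka_plus`, `omega_a` (plus `mean_k4_3` when a 3-part split is
#'   present), with the bin memberships in attribute `"bins"` and discarded
#'   gene indices in attribute `"discarded"`.
#' @export
bin_ka_estimates <- function(gs, n_bins = 45L, n_chromosomes,
                             G = 200L, estimate_part = NULL, n_parts = 3L,
                             fixation_factor = NULL, grid = selection_grid()) {
  rb <- rank_bin(gs$tab$rr, gs$tab$gene_id, n_bins)
  rows <- lapply(seq_along(rb$bins), function(i) {
    bin <- pool_genes(gs, rb$bins[[i]], estimate_part, n_parts)
    est <- if (is.null(fixation_factor)) {
      fit <- fit_bin_dfe(bin, n_chromosomes, G, grid)
      list(alpha = fit$alpha, ka = fit$ka, k4 = fit$k4,
           ka_plus = fit$ka_plus, omega_a = fit$omega_a)
    } else {
      plugin_ka_plus(bin$D0, bin$L0, bin$D4, bin$L4, fixation_factor,
                     gc4 = bin$gc4, P4_ts = bin$P4_ts, P4_tv = bin$P4_tv)
    }
    data.frame(bin = i, n_genes = length(rb$bins[[i]]),
               mean_rr = bin$mean_rr, mean_density = bin$mean_density,
               mean_fop = bin$mean_fop,
               L0 = bin$L0, L4 = bin$L4, D0 = bin$D0, D4 = bin$D4,
               alpha = est$alpha, ka = est$ka, k4 = est$k4,
               ka_plus = est$ka_plus, omega_a = est$omega_a,
               mean_k4_3 = if (is.null(bin$mean_k4_3)) NA_real_
                           else bin$mean_k4_3)
  })
  out <- do.call(rbind, rows)
  attr(out, "bins") <- rb$bins
  attr(out, "discarded") <- rb$discarded
  out
}

#' Full interference analysis of a gene set
#'
#' Runs [bin_ka_estimates()], fits the linear and curvilinear models of
#' Ka+ against recombination rate, fits the LOESS curve, takes the no-HRi
#' asymptote as the mean Ka+ of bins above the recombination threshold, and
#' computes the loss estimate with and without clamping of negative LOESS
#' predictions.
#'
#' @inheritParams bin_ka_estimates
#' @param rr_threshold Asymptote/loss threshold in cM/Mb.
#' @param span LOESS span.
#' @return A list of class `hri_analysis` with `bins` (the bin table),
#'   `linear`, `curvilinear`, `model_comparison`, `loess_predictions`,
#'   `ka_no_hri`, `hri` (unclamped) and `hri_clamped`.
#' @export
hri_analysis <- function(gs, n_bins = 45L, n_chromosomes, G = 200L,
                         rr_threshold = 2, span = 1.0,
                         estimate_part = NULL, n_parts = 3L,
                         fixation_factor = NULL, grid = selection_grid()) {
  bins <- bin_ka_estimates(gs, n_bins, n_chromosomes, G, estimate_part,
                           n_parts, fixation_factor, grid)
  lin <- fit_linear(bins$mean_rr, bins$ka_plus)
  cur <- fit_curvilinear(bins$mean_rr, bins$ka_plus)
  cmp <- compare_fits(lin, cur)
  pred <- loess_predict(bins$mean_rr, bins$ka_plus, span = span)
  ka0 <- asymptotic_ka(bins$mean_rr, bins$ka_plus, rr_threshold)
  structure(list(
    bins = bins, linear = lin, curvilinear = cur, model_comparison = cmp,
    loess_predictions = pred, ka_no_hri = ka0,
    hri = estimate_fhri(bins$L0, bins$mean_rr, pred, ka0, rr_threshold,
                        clamp = FALSE),
    hri_clamped = estimate_fhri(bins$L0, bins$mean_rr, pred, ka0,
                                rr_threshold, clamp = TRUE)),
    class = "hri_analysis")
}

#' @export
print.hri_analysis <- function(x, ...) {
  cat(sprintf("HRi analysis over %d bins (%d genes/bin):\n",
              nrow(x$bins), x$bins$n_genes[1]))
  cat(sprintf("  curvilinear fit a = %.5g, b = %.5g, c = %.4g (R2 = %.2f; linear R2 = %.2f, Pr(>F) = %.3g)\n",
              x$curvilinear$a, x$curvilinear$b, x$curvilinear$c,
              x$curvilinear$r2, x$linear$r2, x$model_comparison$p))
  cat(sprintf("  Ka+ without HRi = %.5g\n", x$ka_no_hri))
  cat(sprintf("  f_HRi = %.3f (clamped %.3f)\n",
              x$hri$f_hri, x$hri_clamped$f_hri))
  invisible(x)
}

#' Pooled DFE correction factor from the full data
#'
#' Fits the DFE stage once on the entire gene set pooled into a single bin
#' and returns the fitted mean relative fixation probability
#' \eqn{E_f[r(S)]}, for use as the fixed correction factor of the plug-in
#' estimator inside resampling loops.
#'
#' @param gs Gene set.
#' @param n_chromosomes Sample size.
#' @param G Wright-Fisher grid size.
#' @param grid DFE quadrature grid.
#' @return A list with `fixation_factor`, `fit` (the pooled `dfe_fit`).
#' @export
pooled_fixation_factor <- function(gs, n_chromosomes, G = 200L,
                                   grid = selection_grid()) {
  bin <- pool_genes(gs, seq_len(nrow(gs$tab)))
  fit <- fit_bin_dfe(bin, n_chromosomes, G, grid)
  list(fixation_factor = fit$d_exp / fit$k4, fit = fit)
}
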