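## Synthetic genome generator: gene-level counts with the statistical
## structure the analysis assumes (Poisson random field SFS, divergence with
## an adaptive component that depends on local recombination), with known
## ground truth.

#' Parameters for the synthetic genome generator
#'
#' Defaults emulate a Drosophila-melanogaster-like autosomal data set:
#' 6,120 genes sampled at 128 chromosomes, 4-fold nucleotide diversity
#' around 1.5%, a leptokurtic gamma DFE (shape 0.35, mean \eqn{-N_e s}
#' = 2000), a modest recent expansion, 4-fold divergence around 0.18
#' substitutions per site, and a true adaptive rate following the
#' curvilinear law \eqn{K_{a+}(rr) = a + b e^{-c \cdot rr}} (coefficients
#' near the fitted genome-wide curve, with `b` shrunk so the curve stays
#' nonnegative at zero recombination).
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Sample size (default 128).
#' @param theta4 Per-site neutral mutation intensity at 4-fold sites
#'   (Watterson scale).
#' @param theta0_scale Multiplier for the 0-fold mutation intensity.
#' @param dfe A [gamma_dfe()] for new 0-fold mutations.
#' @param demog A [demography()].
#' @param adaptive_curve Numeric `c(a, b, c)` of the true Ka+(rr) law;
#'   must be nonnegative over the recombination support.
#' @param t_div 4-fold divergence per site at mutation multiplier 1.
#' @param rr_mix List with `w0` (weight of the low-recombination component),
#'   `mean0` (its exponential mean), `shape`, `scale` (gamma component) and
#'   `max` (truncation, cM/Mb).
#' @param L4_meanlog,L4_sdlog Log-normal site-count law for L4 (L0 is
#'   `l0_ratio` times L4, Li `li_ratio` times).
#' @param l0_ratio,li_ratio Site-count ratios.
#' @param mut_sdlog Log-normal sd of the per-gene mutation multiplier
#'   (0 disables mutation heterogeneity).
#' @param adaptation_mutation_link If `TRUE` (default) the adaptive rate of
#'   a gene scales with its mutation multiplier, making adaptation
#'   mutation-limited: genes supplying more mutations fix more adaptive
#'   substitutions at a given recombination rate.
#' @param density_meanlog,density_sdlog Log-normal gene-density law
#'   (coding sites per 100 kb, capped at 1e5).
#' @param immune_frac Fraction of genes flagged as immune/testes.
#' @param immune_ka_factor Multiplier on the adaptive rate of flagged genes.
#' @param G Wright-Fisher grid size used for the expected SFS.
#' @param grid DFE quadrature grid.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 6120L, n_chromosomes = 128L,
                       theta4 = 0.015, theta0_scale = 1,
                       dfe = gamma_dfe(2000, 0.35),
                       demog = demography(2, 0.1),
                       adaptive_curve = c(a = 0.0126, b = -0.012, c = 2.1237),
                       t_div = 0.18,
                       rr_mix = list(w0 = 0.25, mean0 = 0.15,
                                     shape = 2, scale = 1.25, max = 10),
                       L4_meanlog = log(280), L4_sdlog = 0.45,
                       l0_ratio = 3.5, li_ratio = 0.3,
                       mut_sdlog = 0.3, adaptation_mutation_link = TRUE,
                       density_meanlog = log(20000), density_sdlog = 0.5,
                       immune_frac = 0, immune_ka_factor = 1.5,
                       G = 200L, grid = selection_grid()) {
  ac <- unname(adaptive_curve)
  rr_probe <- seq(0, rr_mix$max, length.out = 512)
  if (any(ac[1] + ac[2] * exp(-ac[3] * rr_probe) < 0))
    stop("adaptive curve is negative somewhere on the recombination support")
  structure(as.list(environment()), class = "sim_params")
}

curve_ka <- function(ac, rr) ac[1] + ac[2] * exp(-ac[3] * rr)

# Calibration constant mapping the grid's per-influx expected SFS to the
# Watterson scale: theta * H_{n-1} expected segregating sites per site.
sfs_scale <- function(params) {
  neutral <- expected_folded_sfs(0, params$demog, params$n_chromosomes,
                                 params$G)
  Hn <- sum(1 / seq_len(params$n_chromosomes - 1L))
  Hn / neutral$total
}

#' Simulate a synthetic gene set
#'
#' Draws per-gene covariates and Poisson-random-field counts: folded SFS
#' entries are Poisson around `L * theta *` (the model's expected folded
#' spectrum under the demography, integrated over the DFE for 0-fold
#' sites), divergent-site counts are binomial with the multiple-hit-forward
#' probability of the true per-site substitution rate, and the 0-fold rate
#' is the sum of a nonadaptive component (DFE fixations) and the adaptive
#' component `Ka+(rr)` imposed by the generator's curvilinear law.
#'
#' @param params A [sim_params()].
#' @param seed RNG seed.
#' @return A gene set: list with `tab` (data.frame of per-gene scalars:
#'   ids, site and divergence counts, covariates), `sfs0`, `sfs4`, `sfsi`
#'   (gene x folded-bin count matrices) and `truth` (per-gene true rates,
#'   the generating parameters, and the true f_HRi from [true_fhri()]).
#' @export
simulate_genes <- function(params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  half <- p$n_chromosomes %/% 2L
  # model expectations (deterministic, shared with the fitting stage)
  scale <- sfs_scale(p)
  e4 <- expected_folded_sfs(0, p$demog, p$n_chromosomes, p$G)$counts * scale
  C <- sfs_count_matrix(p$demog, p$n_chromosomes, p$G, p$grid)
  w <- dfe_weights(p$dfe, p$grid)
  e0 <- as.numeric(C %*% w) * scale
  fix_factor <- dfe_fixation_factor(p$dfe, p$grid)
  ac <- unname(p$adaptive_curve)
  with_seed(seed, function() {
    n <- p$n_genes
    # covariates
    low <- runif(n) < p$rr_mix$w0
    rr <- ifelse(low, rexp(n, 1 / p$rr_mix$mean0),
                 rgamma(n, shape = p$rr_mix$shape, scale = p$rr_mix$scale))
    rr <- pmin(rr, p$rr_mix$max)
    density <- pmin(rlnorm(n, p$density_meanlog, p$density_sdlog), 1e5)
    fop <- rbeta(n, 5, 4)
    L4 <- pmax(60L, as.integer(round(rlnorm(n, p$L4_meanlog, p$L4_sdlog))))
    L0 <- as.integer(round(p$l0_ratio * L4))
    Li <- as.integer(round(p$li_ratio * L4))
    mut <- if (p$mut_sdlog > 0) rlnorm(n, 0, p$mut_sdlog) else rep(1, n)
    immune <- runif(n) < p$immune_frac
    # true rates
    adapt_mult <- ifelse(immune, p$immune_ka_factor, 1) *
      (if (p$adaptation_mutation_link) mut else 1)
    ka_plus_true <- curve_ka(ac, rr) * adapt_mult
    k4_true <- p$t_div * mut
    k0_na_true <- p$theta0_scale * k4_true * fix_factor
    k0_true <- k0_na_true + ka_plus_true
    if (any(k0_true < 0)) stop("negative 0-fold substitution rate")
    # folded SFS (PRF)
    theta_g <- p$theta4 * mut
    sfs4 <- matrix(rpois(n * half, outer(L4 * theta_g, e4)), n, half)
    sfsi <- matrix(rpois(n * half, outer(Li * theta_g, e4)), n, half)
    sfs0 <- matrix(rpois(n * half,
                         outer(L0 * theta_g * p$theta0_scale, e0)), n, half)
    # divergence, drawn on the observed-difference scale (Jukes-Cantor
    # forward map; the ts share of 1/3 makes the Tamura correction at GC=0.5
    # coincide with Jukes-Cantor)
    jc_fwd <- function(K) 0.75 * (1 - exp(-4 * K / 3))
    D4 <- rbinom(n, L4, jc_fwd(k4_true))
    D4_ts <- rbinom(n, D4, 1 / 3)
    Di <- rbinom(n, Li, jc_fwd(k4_true))
    D0 <- rbinom(n, L0, jc_fwd(k0_true))
    tab <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n)), arm = rep("2L", n),
      L0 = L0, L4 = L4, Li = Li, D0 = D0, D4 = D4, D4_ts = D4_ts, Di = Di,
      gc4 = rep(0.5, n), rr = rr, density = density, fop = fop,
      immune_testes = immune, stringsAsFactors = FALSE)
    truth <- list(params = p, fixation_factor = fix_factor,
                  per_gene = data.frame(gene_id = tab$gene_id, rr = rr,
                                        theta_mult = mut, L0 = L0,
                                        ka_plus_true = ka_plus_true,
                                        k4_true = k4_true,
                                        k0_na_true = k0_na_true),
                  f_hri = true_fhri(ac, rr, L0 * adapt_mult))
    list(tab = tab, sfs0 = sfs0, sfs4 = sfs4, sfsi = sfsi, truth = truth)
  })
}

#' True f_HRi implied by the generating curve
#'
#' Applies the loss accounting to the generator's own curve: the no-HRi
#' rate is the curve's asymptote `a`, the expected substitutions without
#' interference total \eqn{\sum_g L_0(g) \, a} over all genes, and the loss
#' is \eqn{\sum_g L_0(g) (a - K_{a+}(rr_g))} over genes below the
#' recombination threshold.
#'
#' @param adaptive_curve Numeric `c(a, b, c)`.
#' @param rr Per-gene recombination rates.
#' @param L0 Per-gene 0-fold site counts, optionally multiplied by any
#'   per-gene adaptive-rate multiplier (mutation supply, gene-function
#'   effects) so the accounting weights genes by their expected adaptive
#'   substitutions.
#' @param rr_threshold Loss threshold in cM/Mb (default 2).
#' @return The true f_HRi (0 when `b = 0` or no gene lies below the
#'   threshold).
#' @export
true_fhri <- function(adaptive_curve, rr, L0, rr_threshold = 2) {
  ac <- unname(adaptive_curve)
  stopifnot(length(rr) == length(L0))
  if (length(rr) == 0L) return(0)
  total <- sum(L0 * ac[1])
  below <- rr < rr_threshold
  lost <- sum(L0[below] * (ac[1] - curve_ka(ac, rr[below])))
  if (total <= 0) {
    # a validated-nonnegative curve with zero asymptote is flat at zero:
    # nothing to lose
    if (abs(lost) < 1e-15) return(0)
    stop("curve asymptote must be positive")
  }
  lost / total
}

#' Subset a gene set
#'
#' @param gs Gene set (see [simulate_genes()]); `truth` is dropped.
#' @param idx Row indices (duplicates allowed, e.g. bootstrap resamples).
#' @return The subsetted gene set.
#' @export
gene_subset <- function(gs, idx) {
  list(tab = gs$tab[idx, , drop = FALSE],
       sfs0 = gs$sfs0[idx, , drop = FALSE],
       sfs4 = gs$sfs4[idx, , drop = FALSE],
       sfsi = if (!is.null(gs$sfsi)) gs$sfsi[idx, , drop = FALSE])
}
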