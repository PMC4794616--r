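#' Two-epoch demography
#'
#' A single instantaneous change in population size from an ancestral size
#' \eqn{N_1} to a present size \eqn{N_2}, \eqn{t_2} generations ago.
#'
#' @param size_ratio \eqn{N_2/N_1} (> 0); 1 means constant size.
#' @param t2 Time since the size change in units of \eqn{N_2} generations
#'   (>= 0). With `size_ratio = 1` the value of `t2` is irrelevant.
#' @return An object of class `demography`.
#' @export
demography <- function(size_ratio = 1, t2 = 0) {
  stopifnot(is.numeric(size_ratio), length(size_ratio) == 1L, size_ratio > 0,
            is.numeric(t2), length(t2) == 1L, t2 >= 0)
  structure(list(size_ratio = size_ratio, t2 = t2), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("two-epoch demography: N2/N1 = %.4g, t2 = %.4g N2 generations\n",
              x$size_ratio, x$t2))
  invisible(x)
}

#' Gamma distribution of fitness effects
#'
#' The DFE of new mutations at functional sites, a gamma distribution over
#' the scaled strength of selection against them.
#'
#' @param gamma_mean Mean of \eqn{\gamma = -N_e s} (>= 0; deleterious effects
#'   are positive on this scale).
#' @param shape_beta Gamma shape \eqn{\beta} (> 0). Small values give a
#'   leptokurtic DFE, large values a platykurtic one.
#' @return An object of class `gamma_dfe`.
#' @export
gamma_dfe <- function(gamma_mean, shape_beta) {
  stopifnot(is.finite(gamma_mean), gamma_mean >= 0,
            is.finite(shape_beta), shape_beta > 0)
  structure(list(gamma_mean = gamma_mean, shape_beta = shape_beta),
            class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf("gamma DFE: mean -Ne*s = %.4g, shape beta = %.4g\n",
              x$gamma_mean, x$shape_beta))
  invisible(x)
}

## ---- Wright-Fisher grid machinery -----------------------------------------

# Deterministic allele-frequency update under genic selection with
# per-generation coefficient s (allele fitness 1 + s); multiplicative form
# keeps frequencies in [0, 1] for s > -1.
wf_update_freq <- function(x, s) x * (1 + s) / (1 + s * x)

# Per-generation grid selection coefficient for scaled S = 4*Ne*s on a grid
# of G alleles (diploid grid size G/2).  Capped so the update stays sane for
# the strongly deleterious tail of the DFE quadrature; on the grid anything
# below the cap is effectively lethal for the SFS anyway.
grid_sel <- function(S, G) max(S / (2 * G), -0.98)

# Transition matrix among segregating counts 1..G-1 for a WF population of
# G alleles; columns are current counts, rows next-generation counts.  Mass
# lost to counts 0 and G is absorbed (not renormalised).
wf_transition <- function(G, s, cache = TRUE) {
  build <- function() {
    x <- (1:(G - 1)) / G
    p <- wf_update_freq(x, s)
    vapply(p, function(pp) dbinom(1:(G - 1), G, pp), numeric(G - 1))
  }
  # only transition matrices on the fixed selection grid are worth keeping;
  # epoch-2 matrices are rescaled by a continuously fitted size ratio and
  # would accumulate without bound
  if (!cache) return(build())
  cache_get(sprintf("A_%d_%.12g", G, s), build)
}

# Equilibrium expected SFS (counts 1..G-1) under mutation inflow of one new
# mutation (count 1) per generation: n = (I - A)^-1 e1.
wf_equilibrium <- function(G, s) {
  key <- sprintf("eq_%d_%.12g", G, s)
  cache_get(key, function() {
    A <- wf_transition(G, s)
    e1 <- c(1, numeric(G - 2))
    as.numeric(solve(diag(G - 1) - A, e1))
  })
}

# Binomial sampling matrix from grid frequencies to a sample of n
# chromosomes; rows are sample counts 0..n.
sampling_matrix <- function(n, G) {
  key <- sprintf("B_%d_%d", n, G)
  cache_get(key, function() {
    x <- (1:(G - 1)) / G
    vapply(x, function(q) dbinom(0:n, n, q), numeric(n + 1))
  })
}

fold_spectrum <- function(unfolded) {
  # unfolded: expected counts at sample counts 1..n-1
  n <- length(unfolded) + 1L
  half <- n %/% 2L
  folded <- numeric(half)
  for (k in seq_len(half)) {
    folded[k] <- if (k == n - k) unfolded[k] else unfolded[k] + unfolded[n - k]
  }
  folded
}

#' Expected folded sample SFS under selection and a two-epoch demography
#'
#' Iterates a discretised Wright-Fisher mutation-inflow recursion on a fixed
#' grid of `G` alleles: epoch 1 is solved to equilibrium, the second epoch is
#' emulated on the same grid by diffusion rescaling (selection multiplied by
#' `size_ratio`, mutation inflow by `size_ratio^2`, `round(t2 * G / 2)` grid
#' generations), after which `n_chromosomes` are sampled binomially and the
#' spectrum is folded.
#'
#' @param S Scaled selection coefficient \eqn{4 N_e s} of the mutations
#'   (0 = neutral, negative = deleterious).
#' @param demog A [demography()].
#' @param n_chromosomes Sample size (number of sequenced chromosomes).
#' @param G Population grid size in alleles (default 200); must be at least
#'   `n_chromosomes`.
#' @return A list with `counts` (expected folded counts per unit mutation
#'   influx, length `floor(n/2)`), `proportions` (normalised over segregating
#'   bins) and `total` (expected segregating sites per unit influx).
#' @export
expected_folded_sfs <- function(S, demog = demography(), n_chromosomes,
                                G = 200L) {
  stopifnot(n_chromosomes >= 2L, G >= n_chromosomes)
  s1 <- grid_sel(S, G)
  nvec <- wf_equilibrium(G, s1)
  r <- demog$size_ratio
  g2 <- as.integer(round(demog$t2 * G / 2))
  if (r != 1 || g2 > 0L) {
    s2 <- grid_sel(r * S, G)
    A2 <- wf_transition(G, s2, cache = (s2 == s1 || s2 == 0))
    inflow <- c(r^2, numeric(G - 2))
    for (g in seq_len(g2)) nvec <- as.numeric(A2 %*% nvec) + inflow
  }
  B <- sampling_matrix(n_chromosomes, G)
  samp <- as.numeric(B %*% nvec)        # counts at 0..n
  unfolded <- samp[2:n_chromosomes]     # segregating 1..n-1
  folded <- fold_spectrum(unfolded)
  total <- sum(folded)
  if (!is.finite(total) || total <= 0)
    stop("expected SFS computation failed: no segregating mass (residual ",
         format(total), ")")
  list(counts = folded, proportions = folded / total, total = total)
}

## ---- DFE quadrature --------------------------------------------------------

#' Quadrature grid over deleterious selection strengths
#'
#' Log-spaced mass points for integrating the gamma DFE, expressed as
#' magnitudes of \eqn{S = 4 N_e s} (so `S_mag/4` is on the \eqn{-N_e s}
#' scale of [gamma_dfe()]), plus a point at 0 that absorbs the effectively
#' neutral mass below the smallest point.
#'
#' @param n_points Number of log-spaced points (default 64).
#' @param s_min,s_max Range of |S| covered (defaults 1e-4 and 1e4).
#' @return A list with `S_mag` (length `n_points + 1`, first entry 0) and
#'   `breaks` (integration bin boundaries on the |S| scale).
#' @export
selection_grid <- function(n_points = 64L, s_min = 1e-4, s_max = 1e4) {
  lg <- seq(log(s_min), log(s_max), length.out = n_points)
  pts <- exp(lg)
  mid <- exp((lg[-1] + lg[-n_points]) / 2)
  breaks <- c(0, pts[1] * sqrt(pts[1] / pts[2]), mid, Inf)
  list(S_mag = c(0, pts), breaks = breaks)
}

# Probability mass of a gamma DFE on each grid point (gamma over -Ne*s, grid
# over |4*Ne*s|).
dfe_weights <- function(dfe, grid) {
  shape <- dfe$shape_beta
  if (dfe$gamma_mean <= 0) {
    w <- numeric(length(grid$S_mag)); w[1] <- 1
    return(w)
  }
  rate <- shape / dfe$gamma_mean
  p <- pgamma(grid$breaks / 4, shape = shape, rate = rate)
  diff(p)
}

#' Relative fixation probability of a semidominant mutation
#'
#' \eqn{r(S) = S / (1 - e^{-S})} with \eqn{r(0) = 1}: the fixation
#' probability of a new mutation with scaled selection \eqn{S = 4 N_e s}
#' relative to a neutral mutation.
#'
#' @param S Scaled selection coefficient(s).
#' @return Numeric vector of relative fixation probabilities.
#' @export
fixation_relative <- function(S) {
  out <- ifelse(abs(S) < 1e-8,
                1 + S / 2,              # series about 0
                S / (1 - exp(-S)))
  out[S < -500] <- 0                    # underflow guard for strong selection
  out
}

# Mean relative fixation probability over a fitted DFE (deleterious S < 0).
dfe_fixation_factor <- function(dfe, grid = selection_grid()) {
  w <- dfe_weights(dfe, grid)
  sum(w * fixation_relative(-grid$S_mag))
}

# Expected folded count matrix over the selection grid: one column per |S|
# mass point, under a given demography.  The heavy object behind the gamma
# fit; cached on (G, n, demography).
sfs_count_matrix <- function(demog, n_chromosomes, G = 200L,
                             grid = selection_grid()) {
  key <- sprintf("C_%d_%d_%.10g_%.10g_%d", G, n_chromosomes,
                 demog$size_ratio, demog$t2, length(grid$S_mag))
  cache_get(key, function() {
    vapply(grid$S_mag, function(Sm) {
      expected_folded_sfs(-Sm, demog, n_chromosomes, G)$counts
    }, numeric(n_chromosomes %/% 2L))
  })
}
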