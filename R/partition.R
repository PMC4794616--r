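## Hypergeometric splitting of K4 and gene binning.

#' Split 4-fold divergence into independent variates
#'
#' Splits a gene's 4-fold divergent-site count \eqn{D_4} into 2 or 3
#' statistically independent parts by multivariate hypergeometric sampling
#' of the \eqn{L_4} sites, so that one part can rank genes into bins while
#' another estimates the adaptive rate without the two sharing sampling
#' error. For three parts, draws of `round(0.33 * L4)` sites are taken twice
#' and the remainder forms the third part; per-site rates divide the parts
#' by \eqn{L_4/3}. For two parts the draw is `round(0.5 * L4)` and rates
#' divide by \eqn{L_4/2}.
#'
#' @param D4,L4 Integer vectors (parallel over genes) of 4-fold divergent
#'   sites and 4-fold sites, `0 <= D4 <= L4`.
#' @param parts 2 or 3.
#' @param seed RNG seed.
#' @return A data.frame with columns `d4_1`, `d4_2` (and `d4_3`), and
#'   `k4_1`, `k4_2` (and `k4_3`); parts always sum exactly to `D4`.
#' @export
split_k4 <- function(D4, L4, parts = 3L, seed = 1L) {
  stopifnot(parts %in% c(2L, 3L), length(D4) == length(L4))
  if (any(D4 > L4)) stop("D4 exceeds L4")
  with_seed(seed, function() {
    n <- length(D4)
    if (parts == 3L) {
      k1 <- round(0.33 * L4)
      d1 <- rhyper(n, m = D4, n = L4 - D4, k = k1)
      # second draw from the remaining sites
      rem_white <- D4 - d1
      rem_black <- (L4 - D4) - (k1 - d1)
      k2 <- pmin(round(0.33 * L4), rem_white + rem_black)
      d2 <- rhyper(n, m = rem_white, n = rem_black, k = k2)
      d3 <- D4 - d1 - d2
      share <- L4 / 3
      data.frame(d4_1 = d1, d4_2 = d2, d4_3 = d3,
                 k4_1 = d1 / share, k4_2 = d2 / share, k4_3 = d3 / share)
    } else {
      k1 <- round(0.5 * L4)
      d1 <- rhyper(n, m = D4, n = L4 - D4, k = k1)
      d2 <- D4 - d1
      share <- L4 / 2
      data.frame(d4_1 = d1, d4_2 = d2,
                 k4_1 = d1 / share, k4_2 = d2 / share)
    }
  })
}

#' Rank genes and assign them to equal-size bins
#'
#' Genes are sorted ascending by `key` (ties broken by `gene_id` for
#' determinism); bin size is `floor(N / n_bins)` and the `N %% n_bins`
#' genes with the highest key values are discarded.
#'
#' @param key Numeric ranking covariate, one per gene.
#' @param gene_id Character ids used for the deterministic tie-break.
#' @param n_bins Number of bins.
#' @return A list with `bins` (list of integer index vectors into the input
#'   order), `discarded` (indices of dropped genes) and `bin_size`.
#' @export
rank_bin <- function(key, gene_id = as.character(seq_along(key)), n_bins) {
  N <- length(key)
  if (n_bins > N) stop("more bins than genes")
  stopifnot(!anyNA(key))
  ord <- order(key, gene_id)
  size <- N %/% n_bins
  used <- ord[seq_len(size * n_bins)]
  bins <- split(used, rep(seq_len(n_bins), each = size))
  list(bins = unname(bins),
       discarded = if (size * n_bins < N) ord[(size * n_bins + 1L):N]
                   else integer(0),
       bin_size = size)
}

# Split indices into k equal-size rank groups by a covariate (ascending);
# remainder genes (highest values) are discarded.
rank_split <- function(idx, key, gene_id, k) {
  rb <- rank_bin(key[idx], gene_id[idx], k)
  lapply(rb$bins, function(b) idx[b])
}

#' Nested partition of genes into factor categories and recombination bins
#'
#' Splits the gene set successively by ranked covariates (for example gene
#' density halves, then mutation-rate halves), then divides each resulting
#' category into equal-size recombination-rate bins. Two-level splits on
#' `density` and `k4_1` get the conventional category labels
#' `GenH`/`GenL` and `MutH`/`MutL`.
#'
#' @param df Data frame with one row per gene containing every covariate
#'   named in `spec` and a `gene_id` column.
#' @param spec List of `list(key =, levels =)` entries applied in order; the
#'   last entry must be `list(key =, bins =)` and produces the rank bins.
#' @param bin_size Optional required bin size; if supplied, a category whose
#'   bins would be smaller raises an error naming the category.
#' @return A list of groups, each `list(label, bins, mean_key)` where `bins`
#'   is a list of row-index vectors.
#' @export
nested_partition <- function(df, spec, bin_size = NULL) {
  stopifnot(length(spec) >= 1, !is.null(spec[[length(spec)]]$bins))
  label_for <- function(key, lvl, k) {
    if (k == 2L) {
      tag <- c("L", "H")[lvl]
      if (key == "density") return(paste0("Gen", tag))
      if (key %in% c("k4_1", "mut")) return(paste0("Mut", tag))
    }
    paste0(key, lvl)
  }
  groups <- list(list(label = character(0), idx = seq_len(nrow(df))))
  for (lv in head(spec, -1L)) {
    groups <- do.call(c, lapply(groups, function(g) {
      parts <- rank_split(g$idx, df[[lv$key]], df$gene_id, lv$levels)
      lapply(seq_along(parts), function(i)
        list(label = c(g$label, label_for(lv$key, i, lv$levels)),
             idx = parts[[i]]))
    }))
  }
  last <- spec[[length(spec)]]
  lapply(groups, function(g) {
    lab <- paste(g$label, collapse = "-")
    if (!is.null(bin_size) &&
        length(g$idx) %/% last$bins < bin_size)
      stop("category ", lab, " has too few genes for bins of ", bin_size)
    rb <- rank_bin(df[[last$key]][g$idx], df$gene_id[g$idx], last$bins)
    list(label = lab,
         bins = lapply(rb$bins, function(b) g$idx[b]),
         discarded = g$idx[rb$discarded])
  })
}

#' Pool per-gene counts over a bin
#'
#' Element-wise sums of the folded SFS matrices and scalar counts of the
#' member genes, plus covariate means. When hypergeometric split columns
#' (`d4_1`, `d4_2`, ...) are present, the pooled `D4`/`L4` used for rate
#' estimation are taken from the requested part and its site share.
#'
#' @param gs A gene set: `list(tab = data.frame, sfs0 = matrix, sfs4 = matrix)`
#'   with matrix rows parallel to `tab` rows (see [simulate_genes()]).
#' @param idx Row indices of the member genes.
#' @param estimate_part `NULL` to use total `D4`/`L4`, or the index of the
#'   split part (with `n_parts`) to use for divergence-rate estimation.
#' @param n_parts Number of parts `D4` was split into (2 or 3).
#' @return A list with pooled `sfs0`, `sfs4`, `D0`, `L0`, `D4`, `L4`,
#'   `gc4`, `P4_ts`, `P4_tv`, `gene_ids`, `mean_rr`, `mean_density`,
#'   `mean_fop` and (for 3-part splits) `mean_k4_3`.
#' @export
pool_genes <- function(gs, idx, estimate_part = NULL, n_parts = 3L) {
  tab <- gs$tab[idx, , drop = FALSE]
  if (is.null(estimate_part)) {
    D4 <- sum(tab$D4); L4 <- sum(tab$L4)
  } else {
    col <- paste0("d4_", estimate_part)
    stopifnot(col %in% names(tab))
    D4 <- sum(tab[[col]]); L4 <- sum(tab$L4) / n_parts
  }
  # ts/tv split of the estimating divergence keeps each gene's ts fraction
  ts_frac <- ifelse(tab$D4 > 0, tab$D4_ts / tab$D4, 1 / 3)
  d_est <- if (is.null(estimate_part)) tab$D4 else tab[[paste0("d4_", estimate_part)]]
  P4_ts <- sum(d_est * ts_frac) / L4
  P4_tv <- sum(d_est * (1 - ts_frac)) / L4
  mean_or_na <- function(v) if (is.null(v)) NA_real_ else mean(v, na.rm = TRUE)
  out <- list(
    gene_ids = tab$gene_id,
    sfs0 = colSums(gs$sfs0[idx, , drop = FALSE]),
    sfs4 = colSums(gs$sfs4[idx, , drop = FALSE]),
    D0 = sum(tab$D0), L0 = sum(tab$L0), D4 = D4, L4 = L4,
    gc4 = if (all(is.na(tab$gc4))) 0.5 else
      sum(tab$gc4 * tab$L4, na.rm = TRUE) / sum(tab$L4[!is.na(tab$gc4)]),
    P4_ts = P4_ts, P4_tv = P4_tv,
    mean_rr = mean_or_na(tab$rr), mean_density = mean_or_na(tab$density),
    mean_fop = mean_or_na(tab$fop))
  if ("k4_3" %in% names(tab)) out$mean_k4_3 <- sum(tab$d4_3) / (sum(tab$L4) / 3)
  out
}
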