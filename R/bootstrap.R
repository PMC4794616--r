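## Resampling inference: bootstrap-by-gene confidence intervals, paired
## category comparisons and the label permutation test.

#' Bootstrap-by-gene confidence intervals for a pipeline statistic
#'
#' Resamples genes with replacement to the original count, reruns the
#' supplied pipeline on every replicate, and reports percentile confidence
#' intervals (the CI endpoints are order statistics of the replicate
#' vector). Per-replicate seeds are derived deterministically from the
#' master seed; replicate-level failures are redrawn with a capped number
#' of retries and never silently dropped.
#'
#' @param gs Gene set.
#' @param pipeline_fn Function taking a (resampled) gene set and returning
#'   a single numeric statistic or a named numeric vector.
#' @param B Number of bootstrap replicates.
#' @param seed Master RNG seed.
#' @param conf Confidence level (default 0.95).
#' @param max_retries Redraw attempts per failed replicate.
#' @return A list of class `bootstrap_result` with `point` (pipeline on the
#'   original data), `replicates` (B x n_stat matrix), `ci_low`, `ci_high`,
#'   `B`, `seed` and `n_retried`.
#' @export
bootstrap_pipeline <- function(gs, pipeline_fn, B, seed = 1L, conf = 0.95,
                               max_retries = 5L) {
  stopifnot(B >= 1)
  n <- nrow(gs$tab)
  point <- pipeline_fn(gs)
  rep_seeds <- with_seed(seed, function()
    sample.int(.Machine$integer.max, B + max_retries * B))
  reps <- matrix(NA_real_, B, length(point))
  colnames(reps) <- names(point)
  n_retried <- 0L
  extra <- B
  for (b in seq_len(B)) {
    s <- rep_seeds[b]
    for (try in 0:max_retries) {
      val <- tryCatch({
        idx <- with_seed(s, function() sample.int(n, n, replace = TRUE))
        as.numeric(pipeline_fn(gene_subset(gs, idx)))
      }, error = function(e) NULL)
      if (!is.null(val)) break
      n_retried <- n_retried + 1L
      extra <- extra + 1L
      if (extra > length(rep_seeds)) stop("bootstrap replicate ", b,
                                          " failed after all retries")
      s <- rep_seeds[extra]
    }
    if (is.null(val)) stop("bootstrap replicate ", b, " failed after ",
                           max_retries, " retries")
    reps[b, ] <- val
  }
  a <- (1 - conf) / 2
  structure(list(point = point, replicates = reps,
                 ci_low = apply(reps, 2, quantile, probs = a, type = 1),
                 ci_high = apply(reps, 2, quantile, probs = 1 - a, type = 1),
                 B = B, seed = seed, n_retried = n_retried),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  for (j in seq_along(x$point)) {
    nm <- if (is.null(names(x$point))) sprintf("stat%d", j) else names(x$point)[j]
    cat(sprintf("%s = %.4g (95%% CI %.4g, %.4g; B = %d)\n",
                nm, x$point[j], x$ci_low[j], x$ci_high[j], x$B))
  }
  invisible(x)
}

#' Paired bootstrap comparison of two categories
#'
#' Computes the replicate-wise difference \eqn{Z = A - B} between two
#' bootstrap distributions of the same statistic (paired by replicate
#' index) and the one-tailed p-value as the fraction of differences on the
#' null side of zero. Ties at zero count towards the null (conservative).
#'
#' @param reps_a,reps_b Equal-length replicate vectors.
#' @param direction `"greater"` tests whether A exceeds B (p = fraction of
#'   Z <= 0); `"less"` the reverse.
#' @return A list of class `z_comparison` with `z_values` and
#'   `p_one_tailed`.
#' @export
z_category_test <- function(reps_a, reps_b, direction = "greater") {
  if (length(reps_a) != length(reps_b))
    stop("replicate vectors must be paired: lengths differ")
  z <- reps_a - reps_b
  p <- switch(direction,
              greater = mean(z <= 0),
              less = mean(z >= 0),
              stop("direction must be 'greater' or 'less'"))
  structure(list(z_values = z, p_one_tailed = p, direction = direction),
            class = "z_comparison")
}

#' All pairwise category comparisons
#'
#' @param reps_by_cat Named list of paired replicate vectors, one per
#'   category.
#' @param direction Passed to [z_category_test()].
#' @return Data frame with one row per ordered pair (`a`, `b`, `p`).
#' @export
z_all_pairs <- function(reps_by_cat, direction = "greater") {
  nms <- names(reps_by_cat)
  prs <- utils::combn(nms, 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    data.frame(a = pr[1], b = pr[2],
               p = z_category_test(reps_by_cat[[pr[1]]],
                                   reps_by_cat[[pr[2]]],
                                   direction)$p_one_tailed)
  }))
}

#' Permutation test for a gene-label contrast
#'
#' Shuffles the focal/control labels without replacement `B` times (class
#' sizes preserved), recomputes the pooled statistic for each class, and
#' records the control-minus-focal difference. The one-tailed p-value is
#' the fraction of null differences below the observed difference; the
#' observed statistic is not added to the null by default.
#'
#' @param gs Gene set.
#' @param labels Logical vector flagging focal (e.g. immune/testes) genes.
#' @param stat_fn Function `(gs, idx) -> numeric` giving the pooled
#'   statistic of a gene subset (e.g. plug-in pooled Ka+).
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @param add_observed Include the observed difference in the null
#'   (the +1 convention); off by default.
#' @return A list of class `permutation_test` with `observed` (control
#'   minus focal), `null` (length B), `p_one_tailed`.
#' @export
permutation_test_groups <- function(gs, labels, stat_fn, B, seed = 1L,
                                    add_observed = FALSE) {
  labels <- as.logical(labels)
  n_focal <- sum(labels)
  if (n_focal == 0L || n_focal == length(labels))
    stop("both label classes must be non-empty")
  idx_all <- seq_along(labels)
  observed <- stat_fn(gs, idx_all[!labels]) - stat_fn(gs, idx_all[labels])
  null <- with_seed(seed, function() {
    vapply(seq_len(B), function(b) {
      perm <- sample(labels)
      stat_fn(gs, idx_all[!perm]) - stat_fn(gs, idx_all[perm])
    }, numeric(1))
  })
  denom <- if (add_observed) B + 1L else B
  numer <- sum(null < observed) + if (add_observed) 1L else 0L
  structure(list(observed = observed, null = null,
                 p_one_tailed = numer / denom, B = B, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: observed control - focal = %.4g, one-tailed p = %.4g (B = %d)\n",
              x$observed, x$p_one_tailed, x$B))
  invisible(x)
}
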