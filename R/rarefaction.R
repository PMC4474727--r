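#' Rarefy inclusive phylogenetic diversity
#'
#' Estimates the expected inclusive PD of a random subsample of `k` leaves
#' from the group, for every `k` in `1..N`. Sampling effort differs wildly
#' between regions, so raw `PD_I` values are not comparable; the rarefaction
#' curve puts provinces on a common footing at matched sample size.
#'
#' Monte-Carlo mode draws `n_reps` random orderings of the group and scores
#' every prefix, so each k-prefix is a uniform without-replacement sample of
#' size `k` and the per-replicate PD trajectory — hence the mean curve — is
#' non-decreasing in `k` by construction. Exact mode enumerates all
#' `choose(N, k)` subsets (only sensible for small groups). In both modes the
#' value at `k = N` is exactly `pd_inclusive(tree, group)` with zero spread.
#'
#' @inheritParams pd_inclusive
#' @param n_reps Number of Monte-Carlo pseudoreplicates (default 1000).
#' @param seed Integer seed for reproducibility; the caller's RNG state is
#'   left untouched.
#' @param method `"montecarlo"` (default) or `"exact"` enumeration.
#' @param probs Two quantile probabilities for the reported envelope.
#' @return A tibble of class `rarefaction_curve` with columns `k`, `mean_pd`,
#'   `sd_pd`, `q05`, `q95`, `n_reps`, `seed`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):3,C:4);")
#' rarefy_pd(tr, c("A", "B", "C"), n_reps = 100, seed = 1)
rarefy_pd <- function(tree, group, n_reps = 1000, seed = NULL,
                      method = c("montecarlo", "exact"),
                      probs = c(0.05, 0.95)) {
  method <- match.arg(method)
  tree <- validate_tree(tree)
  idx <- group_index(tree, group)
  n <- length(idx)
  if (method == "montecarlo" && (!is.numeric(n_reps) || n_reps < 1)) {
    abort("`n_reps` must be >= 1.")
  }
  paths <- tip_root_paths(tree)
  stem <- tree$root.edge %||% 0
  lens <- tree$edge.length

  if (method == "exact") {
    per_k <- lapply(seq_len(n), function(k) {
      if (choose(n, k) > 2e5) {
        abort(sprintf("exact enumeration infeasible: choose(%d, %d) subsets.",
                      n, k))
      }
      subs <- combn(idx, k)
      pd <- apply(subs, 2, function(s) {
        sum(lens[unique(unlist(paths[s], use.names = FALSE))]) + stem
      })
      tibble(k = k, mean_pd = mean(pd), sd_pd = if (length(pd) > 1) sd(pd) else 0,
             q05 = unname(quantile(pd, probs[1])),
             q95 = unname(quantile(pd, probs[2])),
             n_reps = length(pd), seed = NA_integer_)
    })
    out <- bind_rows(per_k)
  } else {
    pd_mat <- with_seed(seed, {
      vapply(seq_len(n_reps), function(rep) {
        perm <- if (n > 1) sample(idx, n) else idx
        included <- logical(length(lens))
        pd <- numeric(n)
        acc <- stem
        for (j in seq_len(n)) {
          new_edges <- paths[[perm[j]]]
          new_edges <- new_edges[!included[new_edges]]
          acc <- acc + sum(lens[new_edges])
          included[new_edges] <- TRUE
          pd[j] <- acc
        }
        pd
      }, numeric(n))
    })
    pd_mat <- matrix(pd_mat, nrow = n)  # n (k) x n_reps, even when n == 1
    out <- tibble(
      k = seq_len(n),
      mean_pd = apply(pd_mat, 1, mean),
      sd_pd = apply(pd_mat, 1, sd),
      q05 = apply(pd_mat, 1, quantile, probs = probs[1], names = FALSE),
      q95 = apply(pd_mat, 1, quantile, probs = probs[2], names = FALSE),
      n_reps = as.integer(n_reps),
      seed = as.integer(seed %||% NA_integer_)
    )
    if (n_reps == 1) out$sd_pd <- 0
  }
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' Plot a rarefaction curve
#'
#' Mean inclusive PD against subsample size with the quantile envelope.
#'
#' @param object A `rarefaction_curve` (or a row-bound set of them with an
#'   extra `province` column).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  has_prov <- "province" %in% names(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$mean_pd))
  if (has_prov) {
    p <- p + ggplot2::aes(colour = .data$province, fill = .data$province)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "leaves sampled (k)",
                  y = "inclusive PD (substitutions/site)")
}
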