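#' Multi-class ReliefF feature weights
#'
#' Deterministic ReliefF (Kononenko's multi-class extension) over all sample
#' instances: features (probes) are min-max scaled to `[0, 1]` on the
#' `log2(value + 1)` scale; for each instance its `k` nearest hits (same
#' class) and, per other class `c`, `k` nearest misses are found by Euclidean
#' distance on the scaled features; each feature's weight is decreased by the
#' mean absolute difference to the hits and increased by
#' `sum_c P(c) / (1 - P(class_i))` times the mean difference to that class's
#' misses, averaged over instances. All samples are used (no subsampling), so
#' the ranking is a deterministic function of the data and labels; `k` is
#' shrunk to `min(class size) - 1` when a class is smaller than `k + 1`.
#'
#' @param data An [expr_set] (optionally pre-restricted to candidate probes
#'   via `probes`) or a samples-by-features numeric matrix.
#' @param labels Sample class labels; defaults to the expression set's group
#'   assignment.
#' @param k Number of neighbours per class (default 5).
#' @param probes Optional candidate probe ids to restrict to.
#' @return Tibble of class `relief_ranking`: `probe_id`, `weight`, `rank`
#'   (ties broken lexicographically by probe id); parameters in
#'   `attr(, "params")`.
#' @export
relieff_weights <- function(data, labels = NULL, k = 5, probes = NULL) {
  if (inherits(data, "expr_set")) {
    labels <- labels %||% sample_groups(data)
    x <- t(expr_matrix(data, log2 = TRUE))
    if (!is.null(probes)) x <- x[, probes, drop = FALSE]
    labels <- labels[rownames(x)]
  } else {
    x <- as.matrix(data)
    assert_that(!is.null(labels), "`labels` required for matrix input")
  }
  labels <- as.character(labels)
  n <- nrow(x)
  cls <- table(labels)
  assert_that(length(cls) >= 2, "need at least 2 classes")
  assert_that(min(cls) >= 2,
              "a class has a single sample; reduce `k` is impossible here")
  k_eff <- min(k, min(cls) - 1)
  priors <- as.numeric(cls) / n
  names(priors) <- names(cls)

  # Min-max scale features; constant features become all-zero (weight 0).
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  xs <- sweep(x, 2, rng[1, ], "-")
  xs <- sweep(xs, 2, ifelse(span == 0, 1, span), "/")

  d <- as.matrix(stats::dist(xs))
  w <- numeric(ncol(xs))
  for (i in seq_len(n)) {
    ci <- labels[i]
    hits <- setdiff(which(labels == ci), i)
    hits <- hits[order(d[i, hits], hits)][seq_len(k_eff)]
    w <- w - colMeans(abs(sweep(xs[hits, , drop = FALSE], 2, xs[i, ]))) / n
    for (cc in setdiff(names(cls), ci)) {
      mis <- which(labels == cc)
      mis <- mis[order(d[i, mis], mis)][seq_len(min(k_eff, length(mis)))]
      coef <- priors[cc] / (1 - priors[ci])
      w <- w + coef *
        colMeans(abs(sweep(xs[mis, , drop = FALSE], 2, xs[i, ]))) / n
    }
  }
  out <- tibble(probe_id = colnames(x), weight = as.numeric(w)) |>
    arrange(desc(.data$weight), .data$probe_id) |>
    mutate(rank = dplyr::row_number())
  attr(out, "params") <- list(k = k_eff, m = n, distance = "euclidean")
  class(out) <- c("relief_ranking", class(out))
  out
}

#' Select the top-ranked hub probes
#'
#' Top-`k` probes by ReliefF weight, ties broken lexicographically by probe
#' id. The default panel size of 25 matches the discovery screen.
#'
#' @param ranking A `relief_ranking` tibble from [relieff_weights()].
#' @param k Panel size (default 25).
#' @return Character vector of `k` probe ids in rank order.
#' @export
select_hub_probes <- function(ranking, k = 25) {
  assert_that(k <= nrow(ranking),
              sprintf("k = %d exceeds the %d ranked probes", k, nrow(ranking)))
  if (k == 0) return(character(0))
  head(ranking$probe_id, k)
}

#' Unsupervised sample clustering and separation score
#'
#' Average-linkage hierarchical clustering of samples on `1 - Pearson`
#' correlation between samples (computed on per-probe z-scored
#' `log2(value + 1)` values, the heatmap convention), cut to the number of
#' true groups, scored by the adjusted Rand index against the true groups.
#'
#' @param data An [expr_set], typically restricted via `probes` to a selected
#'   panel.
#' @param true_groups Named group vector over samples; defaults to the
#'   expression set's groups.
#' @param probes Optional probe ids to restrict to.
#' @return List of class `cluster_score`: `tree` (hclust), `clusters` tibble
#'   `(sample_id, cluster, group)`, and `ari`.
#' @export
cluster_and_score <- function(data, true_groups = NULL, probes = NULL) {
  stopifnot(inherits(data, "expr_set"))
  true_groups <- true_groups %||% sample_groups(data)
  m <- expr_matrix(data, log2 = TRUE)
  if (!is.null(probes)) m <- m[probes, , drop = FALSE]
  n_groups <- length(unique(true_groups))
  assert_that(ncol(m) >= n_groups, "fewer samples than groups")
  z <- t(scale(t(m)))
  z <- z[stats::complete.cases(z), , drop = FALSE]  # drop constant probes
  d <- as.dist(1 - cor(z))
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, k = n_groups)
  ari <- adjusted_rand_index(cl, true_groups[names(cl)])
  structure(
    list(tree = tree,
         clusters = tibble(sample_id = names(cl), cluster = unname(cl),
                           group = unname(true_groups[names(cl)])),
         ari = ari),
    class = "cluster_score"
  )
}

#' @export
print.cluster_score <- function(x, ...) {
  cat(sprintf("<cluster_score> %d samples, %d clusters, ARI = %.3f\n",
              nrow(x$clusters), length(unique(x$clusters$cluster)), x$ari))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b Two label vectors of equal length.
#' @return The ARI (1 = identical partitions, ~0 at random).
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
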