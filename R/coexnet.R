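#' Weighted co-expression adjacency
#'
#' Unsigned weighted adjacency `|cor|^power` between probes, computed with
#' Pearson correlation on the `log2(value + 1)` scale across samples. The
#' diagonal is zero (no self-connectivity). Probes with zero variance are
#' dropped with a warning (correlation is undefined for them).
#'
#' @param data An [expr_set] or a numeric probe-by-sample matrix already on
#'   the log scale.
#' @param power Soft-threshold exponent (beta), a positive number.
#' @return Symmetric adjacency matrix with probe ids as dimnames.
#' @export
adjacency_matrix <- function(data, power = 6) {
  assert_that(power > 0, "`power` must be positive")
  m <- if (inherits(data, "expr_set")) expr_matrix(data, log2 = TRUE) else
    as.matrix(data)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance probe(s)", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  a <- abs(cor(t(m)))^power
  diag(a) <- 0
  a
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each candidate power the unsigned adjacency is formed, per-probe
#' connectivity `k_i = sum_j a_ij` computed, and the scale-free fit R^2 taken
#' from the regression of `log10 p(k)` on `log10 k` over connectivity bins
#' (10 equal-width bins, empty bins dropped; at least 8 populated bins are
#' attempted by halving the bin count if needed). The chosen power is the
#' smallest one reaching `r2_goal`, falling back to the argmax of the fit.
#'
#' @inheritParams adjacency_matrix
#' @param powers Candidate integer powers.
#' @param r2_goal Target scale-free fit R^2 (default 0.85).
#' @return A tibble of class `soft_threshold_scan` with columns `power`,
#'   `fit_r2`, `mean_connectivity`; the chosen power is in
#'   `attr(, "chosen_power")`.
#' @export
soft_threshold_scan <- function(data, powers = 1:20, r2_goal = 0.85) {
  m <- if (inherits(data, "expr_set")) expr_matrix(data, log2 = TRUE) else
    as.matrix(data)
  assert_that(ncol(m) >= 4, "need at least 4 samples for a correlation network")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance probe(s)", sum(v == 0)))
    m <- m[v > 0, , drop = FALSE]
  }
  ac <- abs(cor(t(m)))
  diag(ac) <- 0
  res <- purrr::map_dfr(powers, function(b) {
    a <- ac^b
    diag(a) <- 0
    k <- rowSums(a)
    tibble(power = b, fit_r2 = scale_free_r2(k), mean_connectivity = mean(k))
  })
  chosen <- res$power[res$fit_r2 >= r2_goal]
  chosen <- if (length(chosen)) min(chosen) else res$power[which.max(res$fit_r2)]
  structure(res, chosen_power = chosen, class = c("soft_threshold_scan",
                                                  class(res)))
}

# R^2 of log10 p(k) ~ log10 k over equal-width connectivity bins.
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 4 || diff(range(k)) == 0) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  mk <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(mk[keep]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`: similarity combining the direct edge with the shared
#' neighbourhood of two probes.
#'
#' @param adjacency Symmetric adjacency with values in `[0, 1]` and zero
#'   diagonal, as from [adjacency_matrix()].
#' @return Symmetric TOM matrix, values in `[0, 1]`, unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  assert_that(isSymmetric(unname(a), tol = 1e-10),
              "adjacency must be symmetric")
  assert_that(all(a >= 0 & a <= 1), "adjacency values must lie in [0, 1]")
  assert_that(all(diag(a) == 0), "adjacency must have a zero diagonal")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut with a static height rule: by default the tree is cut at
#' dissimilarity 0.98, just below the plateau where unstructured probes
#' merge (pairs with near-zero topological overlap sit at `1 - TOM`
#' immediately under 1, while even weakly cohesive modules merge well
#' below). Clusters smaller than `min_module_size` are assigned to `grey`;
#' remaining modules are named by decreasing size with the conventional
#' colour sequence (turquoise, blue, brown, yellow, green, ...), size ties
#' broken by the lexicographically smallest member probe id.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Smallest cluster kept as a module (default 10).
#' @param cut_height Static dissimilarity cut height (default 0.98), or
#'   `"gap"` to cut at the midpoint of the largest gap in the sorted merge
#'   heights instead.
#' @return A tibble `(probe_id, module)` with the `hclust` tree in
#'   `attr(, "tree")` and the height used in `attr(, "cut_height")`.
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.98) {
  tom <- as.matrix(tom)
  n <- nrow(tom)
  probe_ids <- rownames(tom) %||% sprintf("probe_%d", seq_len(n))
  if (n < min_module_size) {
    warn("fewer probes than `min_module_size`; all probes assigned to grey")
    out <- tibble(probe_id = probe_ids, module = "grey")
    return(structure(out, tree = NULL, cut_height = NA_real_))
  }
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  if (identical(cut_height, "gap")) {
    hs <- sort(tree$height)
    gaps <- diff(hs)
    if (length(gaps) == 0 || max(gaps) <= 0) {
      cut_height <- min(hs) - 1  # no structure: everything stays a singleton
    } else {
      i <- which.max(gaps)
      cut_height <- (hs[i] + hs[i + 1]) / 2
    }
  }
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # Order kept clusters by decreasing size, ties by smallest member probe id.
  first_probe <- vapply(keep, function(g) min(probe_ids[cl == g]), "")
  ord <- keep[order(-as.integer(sizes[keep]), first_probe)]
  colors <- module_color_names(length(ord))
  module <- rep("grey", n)
  for (j in seq_along(ord)) module[cl == ord[j]] <- colors[j]
  out <- tibble(probe_id = probe_ids, module = module)
  structure(out, tree = tree, cut_height = cut_height)
}

#' Module eigengenes
#'
#' First principal component of each module's per-probe standardized (z-score)
#' log2 expression, scaled to unit variance and sign-oriented so that its
#' mean correlation with the module's members is positive. A single-probe
#' module's eigengene is that probe's z-score.
#'
#' @param data The [expr_set] the modules were detected on.
#' @param assignment Tibble `(probe_id, module)` from [detect_modules()].
#' @return Tibble with `sample_id` and one numeric column per non-grey
#'   module.
#' @export
module_eigengenes <- function(data, assignment) {
  m <- expr_matrix(data, log2 = TRUE)
  mods <- setdiff(unique(assignment$module), "grey")
  assert_that(length(mods) > 0, "no non-grey modules to summarise")
  cols <- lapply(mods, function(mod) {
    ids <- assignment$probe_id[assignment$module == mod]
    sub <- m[ids, , drop = FALSE]
    z <- t(scale(t(sub)))  # per-probe z-score across samples
    if (nrow(z) == 1L) {
      eg <- as.numeric(z)
    } else {
      pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
      eg <- pc$x[, 1]
    }
    eg <- as.numeric(scale(eg))
    if (mean(cor(eg, t(z))) < 0) eg <- -eg
    eg
  })
  names(cols) <- mods
  bind_cols(tibble(sample_id = colnames(m)), as_tibble(cols))
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with a binary sample trait,
#' with the two-sided p-value from the t-transform on `n - 2` degrees of
#' freedom. Modules with positive correlation and `p < alpha` are flagged
#' `trait_up`.
#'
#' @param eigengenes Tibble from [module_eigengenes()].
#' @param trait Named 0/1 vector over sample ids, or a tibble
#'   `(sample_id, trait)`.
#' @param alpha Significance threshold for the `trait_up` flag.
#' @return Tibble `(module, cor, p, trait_up)`.
#' @export
module_trait_association <- function(eigengenes, trait, alpha = 0.05) {
  if (is.data.frame(trait)) trait <- setNames(trait$trait, trait$sample_id)
  assert_that(all(eigengenes$sample_id %in% names(trait)),
              "`trait` must cover every sample")
  tr <- as.numeric(trait[eigengenes$sample_id])
  assert_that(sd(tr) > 0, "trait is constant across samples")
  mods <- setdiff(names(eigengenes), "sample_id")
  n <- length(tr)
  purrr::map_dfr(mods, function(mod) {
    r <- cor(eigengenes[[mod]], tr)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
    tibble(module = mod, cor = r, p = p, trait_up = r > 0 & p < alpha)
  })
}
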