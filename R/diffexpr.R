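#' Filter probes by abundance
#'
#' Retains probes expressed above `min_value` (linear scale) in at least
#' `min_samples` samples — the conventional `FPKM > 1` in at least 3 samples
#' abundance filter. Probe order is preserved.
#'
#' @param data An [expr_set].
#' @param min_value Linear-scale expression threshold (strict `>`).
#' @param min_samples Minimum number of samples above threshold.
#' @return A filtered [expr_set] (truth, if any, subset accordingly). An
#'   empty result triggers a warning, not an error.
#' @export
filter_expressed <- function(data, min_value = 1, min_samples = 3) {
  stopifnot(inherits(data, "expr_set"))
  assert_that(min_value > 0, "`min_value` must be positive")
  assert_that(min_samples >= 0, "`min_samples` must be non-negative")
  m <- expr_matrix(data)
  keep <- rowSums(m > min_value) >= min_samples
  if (!any(keep)) warn("no probes pass the abundance filter")
  truth <- data$truth
  if (!is.null(truth) && !is.null(truth$probes)) {
    truth$probes <- truth$probes[truth$probes$probe_id %in%
                                   data$expr$probe_id[keep], , drop = FALSE]
  }
  expr_set(data$expr[keep, , drop = FALSE], data$samples, truth)
}

#' Two-group differential expression
#'
#' Per probe, a two-tailed Welch (unequal-variance) t-test on
#' `log2(value + pseudocount)` between two sample groups, with the log2 fold
#' change defined as `mean(log2 group_a) - mean(log2 group_b)` and the linear
#' fold change as the ratio of linear group means. p-values are BH-adjusted
#' across all tested probes. A probe with zero variance in both groups and
#' zero mean difference is reported with `p = 1` by convention.
#'
#' @param data An [expr_set].
#' @param group_a,group_b Group names to contrast (`a` vs `b`).
#' @param pseudocount Added before the log2 transform (default 1).
#' @return Tibble of class `de_results`: `probe_id`, `log2_fc`, `fc`
#'   (linear-mean ratio), `p`, `q`, `neg_log10_p`.
#' @export
differential_expression <- function(data, group_a, group_b, pseudocount = 1) {
  stopifnot(inherits(data, "expr_set"))
  grp <- sample_groups(data)
  ia <- names(grp)[grp == group_a]
  ib <- names(grp)[grp == group_b]
  assert_that(length(ia) >= 2 && length(ib) >= 2,
              "both groups need at least 2 samples")
  m <- expr_matrix(data)
  la <- log2(m[, ia, drop = FALSE] + pseudocount)
  lb <- log2(m[, ib, drop = FALSE] + pseudocount)
  welch <- welch_t(la, lb)
  fc <- rowMeans(m[, ia, drop = FALSE]) / rowMeans(m[, ib, drop = FALSE])
  out <- tibble(
    probe_id = rownames(m),
    log2_fc = unname(rowMeans(la) - rowMeans(lb)),
    fc = unname(fc),
    p = unname(welch$p),
    q = unname(bh_adjust(welch$p))
  )
  out$neg_log10_p <- -log10(out$p)
  class(out) <- c("de_results", class(out))
  out
}

# Vectorized Welch t-test with Satterthwaite degrees of freedom; rows are
# probes. Degenerate rows (zero variance in both groups): p = 1 when the mean
# difference is 0, p = 0 otherwise.
welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  degen <- se2 == 0
  p[degen] <- ifelse(abs(ma[degen] - mb[degen]) == 0, 1, 0)
  list(t = tstat, df = df, p = p)
}

#' Classify differential-expression calls
#'
#' Applies the discovery thresholds: `up` if `p < p_thresh` and linear fold
#' change `> fc_thresh`; `down` if `p < p_thresh` and fold change
#' `< 1/fc_thresh`; otherwise `ns`. The raw p-value is used for the cutoff
#' (matching the stated `p < 0.05 and fold change > 2` rule); the BH q-value
#' is reported alongside.
#'
#' @param results A `de_results` tibble from [differential_expression()].
#' @param fc_thresh Linear fold-change threshold (default 2).
#' @param p_thresh Raw p-value threshold (default 0.05).
#' @return The input tibble with a `call` column (`up`/`down`/`ns`).
#' @export
classify_de <- function(results, fc_thresh = 2, p_thresh = 0.05) {
  assert_that(fc_thresh > 0 && p_thresh > 0, "thresholds must be positive")
  results$call <- dplyr::case_when(
    results$p < p_thresh & results$fc > fc_thresh ~ "up",
    results$p < p_thresh & results$fc < 1 / fc_thresh ~ "down",
    TRUE ~ "ns"
  )
  results
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl)`;
#' the returned fold change is `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct in the case
#'   condition.
#' @param ct_target_ctrl,ct_ref_ctrl The same in the control condition.
#' @return Positive fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  assert_that(all(is.finite(cts)), "all Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
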