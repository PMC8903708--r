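#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Glance at a log-rank test
#'
#' @param x A `logrank_test` result.
#' @param ... Unused.
#' @return One-row tibble: `chi_square`, `df`, `p.value`, `n`.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble(chi_square = x$chi_square, df = x$df, p.value = x$p,
         n = x$n_a + x$n_b)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit` tibble.
#' @param ... Unused.
#' @return Tibble with one row per distinct time: `time`, `n.risk`,
#'   `n.event`, `n.censor`, `estimate`.
#' @method tidy km_fit
#' @export
tidy.km_fit <- function(x, ...) {
  tibble(time = x$time, n.risk = x$n_risk, n.event = x$n_event,
         n.censor = x$n_censor, estimate = x$survival)
}

#' Glance at an expression-stratified survival comparison
#'
#' @param x A `surv_strat` object.
#' @param ... Unused.
#' @return One-row tibble: subject counts per stratum and the log-rank
#'   statistic and p-value.
#' @method glance surv_strat
#' @export
glance.surv_strat <- function(x, ...) {
  tibble(
    n = nrow(x$table),
    n_high = sum(x$table$expr_group == "high", na.rm = TRUE),
    n_low = sum(x$table$expr_group == "low", na.rm = TRUE),
    chi_square = x$test$chi_square,
    p.value = x$test$p
  )
}

#' Glance at a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  s <- x$summary
  tibble(
    n_probes_filtered = s$n_probes_filtered,
    n_de_up = s$n_de_up, n_de_down = s$n_de_down,
    n_modules = s$n_modules,
    n_trait_up_modules = length(s$trait_up_modules),
    panel_size = s$panel_size, panel_ari = s$panel_ari,
    primary_orf_length_aa = s$primary_orf_length_aa,
    n_sig_as_events = s$n_sig_as_events,
    logrank_p = s$logrank_p
  )
}
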