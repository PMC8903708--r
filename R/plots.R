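#' @importFrom ggplot2 ggplot aes geom_point geom_step geom_col geom_hline
#'   geom_vline labs theme_minimal scale_color_manual autoplot
NULL

#' Volcano plot of differential-expression results
#'
#' @param object A `de_results` tibble (after [classify_de()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot de_results
#' @export
autoplot.de_results <- function(object, ...) {
  df <- as_tibble(object)
  if (!"call" %in% names(df)) df$call <- "ns"
  ggplot(df, aes(x = .data$log2_fc, y = .data$neg_log10_p,
                 color = .data$call)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                  ns = "grey60")) +
    labs(x = "log2 fold change", y = "-log10 p", color = NULL) +
    theme_minimal()
}

#' Soft-threshold scan diagnostics
#'
#' Scale-free fit R^2 against candidate power; the chosen power is marked.
#'
#' @param object A `soft_threshold_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soft_threshold_scan
#' @export
autoplot.soft_threshold_scan <- function(object, ...) {
  chosen <- attr(object, "chosen_power")
  ggplot(as_tibble(object), aes(x = .data$power, y = .data$fit_r2)) +
    geom_point() +
    geom_vline(xintercept = chosen, linetype = "dashed", color = "red") +
    labs(x = "soft-threshold power", y = "scale-free fit R²") +
    theme_minimal()
}

#' Kaplan-Meier step curve
#'
#' @param object A `km_fit` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, survival = 1),
                  as_tibble(object)[, c("time", "survival")])
  ggplot(df, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    labs(x = "time (months)", y = "survival probability") +
    theme_minimal()
}

#' Expression-stratified survival curves
#'
#' Kaplan-Meier curves of the high- and low-expression strata with the
#' log-rank p in the subtitle.
#'
#' @param x A `surv_strat` object from [survival_by_expression()].
#' @return A ggplot.
#' @export
plot_survival_strata <- function(x) {
  stopifnot(inherits(x, "surv_strat"))
  df <- purrr::imap_dfr(x$km, function(km, grp)
    bind_rows(tibble(time = 0, survival = 1),
              as_tibble(km)[, c("time", "survival")]) |>
      mutate(stratum = grp))
  ggplot(df, aes(x = .data$time, y = .data$survival,
                 color = .data$stratum)) +
    geom_step() +
    labs(x = "time (months)", y = "survival probability", color = NULL,
         subtitle = sprintf("log-rank p = %.3g", x$test$p)) +
    theme_minimal()
}

#' Splicing-category bar chart
#'
#' @param summary Category summary from [summarize_categories()].
#' @return A ggplot.
#' @export
plot_as_categories <- function(summary) {
  ggplot(summary, aes(x = stats::reorder(.data$type, -.data$count),
                      y = .data$count)) +
    geom_col(fill = "#34495e") +
    labs(x = "event category", y = "significant events") +
    theme_minimal()
}

#' Module-trait association heat strip
#'
#' @param association Tibble from [module_trait_association()].
#' @return A ggplot.
#' @export
plot_module_trait <- function(association) {
  ggplot(association, aes(x = .data$module, y = "trait",
                          fill = .data$cor)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(aes(label = sprintf("%.2f\np=%.2g", .data$cor,
                                           .data$p)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white",
                                  high = "#c0392b", limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "cor") +
    theme_minimal()
}
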