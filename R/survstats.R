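#' Dichotomize a survival cohort by expression
#'
#' `median` rule: high iff expression strictly above the cohort median (the
#' median itself falls in the low group). `tertile` rule: top third high,
#' bottom third low (`floor(n/3)` each side), middle excluded (`NA`).
#'
#' @param table Survival tibble with columns `subject_id`, `time`, `event`,
#'   `expression`.
#' @param rule `"median"` (default) or `"tertile"`.
#' @return The input tibble with an added `expr_group` column
#'   (`"high"`/`"low"`/`NA`).
#' @export
dichotomize_by_expression <- function(table, rule = c("median", "tertile")) {
  rule <- match.arg(rule)
  table <- as_tibble(table)
  assert_that(nrow(table) >= 2, "need at least 2 subjects")
  x <- table$expression
  assert_that(sd(x) > 0, "expression is identical across subjects")
  if (rule == "median") {
    table$expr_group <- ifelse(x > median(x), "high", "low")
  } else {
    n3 <- floor(nrow(table) / 3)
    ord <- order(x)
    grp <- rep(NA_character_, nrow(table))
    grp[ord[seq_len(n3)]] <- "low"
    grp[ord[seq(nrow(table) - n3 + 1, nrow(table))]] <- "high"
    table$expr_group <- grp
  }
  table
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' the standard tie convention (subjects censored at an event time count as
#' at risk through that time).
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return Tibble of class `km_fit` over distinct observed times: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; the underlying
#'   `survival::survfit` object is in `attr(, "fit")`.
#' @export
km_estimate <- function(times, events) {
  assert_that(all(times > 0), "times must be positive")
  assert_that(all(events %in% c(0, 1)), "events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_fit", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival tables: at each distinct
#' event time the observed events in group A are compared with their
#' hypergeometric expectation; the chi-square statistic is referred to a
#' 1-df chi-square distribution.
#'
#' @param group_a,group_b Tibbles with `time` and `event` columns.
#' @return Tibble of class `logrank_test`: `chi_square`, `df`, `p`,
#'   `n_a`, `n_b`, `events_a`, `events_b`, `expected_a`, `expected_b`.
#' @export
logrank_test <- function(group_a, group_b) {
  assert_that(nrow(group_a) > 0 && nrow(group_b) > 0,
              "both groups must be non-empty")
  d <- bind_rows(
    tibble(time = group_a$time, event = group_a$event, g = "a"),
    tibble(time = group_b$time, event = group_b$event, g = "b")
  )
  assert_that(sum(d$event) > 0, "no events in either group")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  out <- tibble(
    chi_square = unname(sd_fit$chisq), df = 1L,
    p = pchisq(unname(sd_fit$chisq), df = 1, lower.tail = FALSE),
    n_a = unname(sd_fit$n[1]), n_b = unname(sd_fit$n[2]),
    events_a = unname(sd_fit$obs[1]), events_b = unname(sd_fit$obs[2]),
    expected_a = unname(sd_fit$exp[1]), expected_b = unname(sd_fit$exp[2])
  )
  class(out) <- c("logrank_test", class(out))
  out
}

#' Expression-stratified survival comparison
#'
#' Convenience wrapper: dichotomize a cohort by expression, estimate
#' Kaplan-Meier curves per stratum and compare them by log-rank.
#'
#' @param table Survival tibble (`subject_id`, `time`, `event`,
#'   `expression`).
#' @param rule Dichotomization rule, see [dichotomize_by_expression()].
#' @return List of class `surv_strat`: `table` (with `expr_group`), `km`
#'   (named list of [km_estimate()] per stratum), `test`
#'   ([logrank_test()] result).
#' @export
survival_by_expression <- function(table, rule = "median") {
  tab <- dichotomize_by_expression(table, rule)
  tab2 <- tab[!is.na(tab$expr_group), , drop = FALSE]
  km <- lapply(split(tab2, tab2$expr_group),
               function(g) km_estimate(g$time, g$event))
  test <- logrank_test(tab2[tab2$expr_group == "high", ],
                       tab2[tab2$expr_group == "low", ])
  structure(list(table = tab, km = km, test = test), class = "surv_strat")
}

#' @export
print.surv_strat <- function(x, ...) {
  cat(sprintf("<surv_strat> %d subjects (high %d / low %d), log-rank p = %.3g\n",
              nrow(x$table), sum(x$table$expr_group == "high", na.rm = TRUE),
              sum(x$table$expr_group == "low", na.rm = TRUE), x$test$p))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the hit list and the set, given the
#' universe; BH-adjusted across sets.
#'
#' @param hits Character vector of hit identifiers (must lie in the
#'   universe).
#' @param sets A gene-set collection: list with `sets` (named list of member
#'   vectors) and `universe`.
#' @param alpha Significance threshold on `q`.
#' @return Tibble of class `ora_results` sorted by `p`: `set_name`,
#'   `overlap`, `set_size`, `hit_count`, `universe_size`, `p`, `q`,
#'   `significant`.
#' @export
ora_enrichment <- function(hits, sets, alpha = 0.05) {
  universe <- sets$universe
  outside <- setdiff(hits, universe)
  assert_that(length(outside) == 0,
              paste0("hit not in universe: ", outside[1]))
  n_u <- length(universe)
  n_h <- length(hits)
  res <- purrr::imap_dfr(sets$sets, function(members, nm) {
    ov <- length(intersect(hits, members))
    tibble(set_name = nm, overlap = ov, set_size = length(members),
           hit_count = n_h, universe_size = n_u,
           p = phyper(ov - 1, length(members), n_u - length(members), n_h,
                      lower.tail = FALSE))
  })
  res <- res |>
    mutate(q = bh_adjust(.data$p), significant = .data$q < alpha) |>
    arrange(.data$p, .data$set_name)
  class(res) <- c("ora_results", class(res))
  res
}
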