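#' Simulate alternative-splicing junction counts
#'
#' Generates per-event, per-replicate inclusion/skipping junction counts in
#' two conditions. Event types are drawn from `category_probs`; each event
#' has a true PSI per condition; per replicate the total junction count is
#' Poisson with mean `depth` and inclusion reads are binomial with the
#' effective-length-weighted inclusion probability
#' `eff_inc * psi / (eff_inc * psi + eff_skip * (1 - psi))`, so the
#' length-normalized PSI estimator is consistent.
#'
#' Defaults state a realistic differential-splicing world: true baseline PSI
#' uniform on (0.05, 0.95); 15% of events perturbed by +/-0.3 PSI in
#' condition 2 (clamped to (0.02, 0.98)); event-type mix dominated by exon
#' skipping (SE 60%).
#'
#' @param n_events Number of events.
#' @param category_probs Named probabilities per event type (must sum to 1
#'   within 1e-9).
#' @param psi_cond1,psi_cond2 Optional per-event true PSI vectors (length 1
#'   or `n_events`); defaults as above.
#' @param depth Mean junction-read count per event and replicate (> 0).
#' @param n_replicates Replicates per condition.
#' @param eff_len_inc,eff_len_skip Effective lengths used in the read-choice
#'   probability.
#' @param seed Integer seed.
#' @return List of class `as_sim`: `counts` tibble (`event_id`, `gene_id`,
#'   `type`, `sample`, `condition`, `inclusion`, `skipping`) and `truth`
#'   tibble (`event_id`, `type`, `psi_cond1`, `psi_cond2`, `differential`).
#' @export
sim_as_counts <- function(n_events = 1000,
                          category_probs = c(SE = 0.60, A3SS = 0.12,
                                             A5SS = 0.10, RI = 0.10,
                                             MXE = 0.08),
                          psi_cond1 = NULL, psi_cond2 = NULL,
                          depth = 50, n_replicates = 3,
                          eff_len_inc = 2, eff_len_skip = 1, seed = 1) {
  assert_that(abs(sum(category_probs) - 1) <= 1e-9,
              "`category_probs` must sum to 1 (tolerance 1e-9)")
  assert_that(depth > 0, "`depth` must be positive")
  assert_that(n_replicates >= 1, "`n_replicates` must be >= 1")
  with_seed(seed, {
    types <- sample(names(category_probs), n_events, replace = TRUE,
                    prob = category_probs)
    if (is.null(psi_cond1)) psi_cond1 <- runif(n_events, 0.05, 0.95)
    psi_cond1 <- rep_len(psi_cond1, n_events)
    differential <- rep(FALSE, n_events)
    if (is.null(psi_cond2)) {
      psi_cond2 <- psi_cond1
      n_diff <- round(0.15 * n_events)
      if (n_diff > 0) {
        idx <- sample(n_events, n_diff)
        shift <- sample(c(-0.3, 0.3), n_diff, replace = TRUE)
        psi_cond2[idx] <- pmin(pmax(psi_cond1[idx] + shift, 0.02), 0.98)
        differential[idx] <- TRUE
      }
    }
    psi_cond2 <- rep_len(psi_cond2, n_events)
    assert_that(all(psi_cond1 >= 0 & psi_cond1 <= 1) &&
                  all(psi_cond2 >= 0 & psi_cond2 <= 1),
                "true PSI values must lie in [0, 1]")
    event_ids <- sprintf("event_%05d", seq_len(n_events))
    gene_ids <- sprintf("gene_%05d", seq_len(n_events))
    grid <- tidyr::expand_grid(
      idx = seq_len(n_events),
      condition = c("cond1", "cond2"),
      rep = seq_len(n_replicates)
    )
    psi_true <- ifelse(grid$condition == "cond1",
                       psi_cond1[grid$idx], psi_cond2[grid$idx])
    p_inc <- eff_len_inc * psi_true /
      (eff_len_inc * psi_true + eff_len_skip * (1 - psi_true))
    total <- rpois(nrow(grid), depth)
    inc <- rbinom(nrow(grid), total, p_inc)
    counts <- tibble(
      event_id = event_ids[grid$idx],
      gene_id = gene_ids[grid$idx],
      type = types[grid$idx],
      sample = paste0(grid$condition, "_r", grid$rep),
      condition = grid$condition,
      inclusion = inc,
      skipping = total - inc
    )
    truth <- tibble(event_id = event_ids, gene_id = gene_ids, type = types,
                    psi_cond1 = psi_cond1, psi_cond2 = psi_cond2,
                    differential = differential)
    structure(list(counts = counts, truth = truth), class = "as_sim")
  })
}

#' Simulate an expression-linked survival cohort
#'
#' Expression is log-normal (`meanlog = log(5)`, `sdlog = 0.8`); subjects
#' above the cohort median expression have their exponential event hazard
#' multiplied by `hazard_ratio` (baseline mean survival `baseline_scale`
#' time units). Independent uniform censoring `C ~ U(0, u)` is applied with
#' `u` solved numerically so the expected censored fraction matches
#' `censor_fraction`.
#'
#' @param n_subjects Cohort size.
#' @param hazard_ratio Hazard multiplier for high-expression subjects (> 0).
#' @param baseline_scale Mean event time of the low-hazard stratum (months).
#' @param censor_fraction Target censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble: `subject_id`, `time`, `event`, `expression`; the
#'   generating parameters are in `attr(, "truth")`.
#' @export
sim_survival <- function(n_subjects = 200, hazard_ratio = 2,
                         baseline_scale = 60, censor_fraction = 0.2,
                         seed = 1) {
  assert_that(hazard_ratio > 0, "`hazard_ratio` must be positive")
  assert_that(censor_fraction >= 0 && censor_fraction < 1,
              "`censor_fraction` must lie in [0, 1)")
  assert_that(baseline_scale > 0, "`baseline_scale` must be positive")
  with_seed(seed, {
    expr <- rlnorm(n_subjects, meanlog = log(5), sdlog = 0.8)
    high <- expr > median(expr)
    rate <- (1 / baseline_scale) * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(n_subjects, rate)
    if (censor_fraction == 0) {
      time <- t_event
      event <- rep(1L, n_subjects)
    } else {
      # P(C < T) for C ~ U(0, u), T ~ Exp(lambda): (1 - exp(-lambda u)) /
      # (lambda u); average over the two hazard strata and solve for u.
      p_cens <- function(u) {
        sum(vapply(unique(rate), function(l)
          mean(rate == l) * (1 - exp(-l * u)) / (l * u), 1))
      }
      u <- uniroot(function(u) p_cens(u) - censor_fraction,
                   lower = 1e-6, upper = 1e6 * baseline_scale,
                   tol = 1e-8)$root
      cens <- runif(n_subjects, 0, u)
      time <- pmin(t_event, cens)
      event <- as.integer(t_event <= cens)
    }
    time <- pmax(time, .Machine$double.eps)
    out <- tibble(subject_id = sprintf("subj_%04d", seq_len(n_subjects)),
                  time = time, event = event, expression = expr)
    attr(out, "truth") <- list(hazard_ratio = hazard_ratio,
                               baseline_scale = baseline_scale,
                               censor_fraction = censor_fraction,
                               high = high, seed = seed)
    out
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Random member sets over a universe plus one planted set constructed to be
#' over-represented in a designated hit list; ground truth (hit list,
#' planted set name) is recorded.
#'
#' @param universe_size Number of identifiers in the universe.
#' @param n_sets Number of random (non-planted) sets.
#' @param planted List with `set_size` and `hit_fraction` (fraction of the
#'   hit list contained in the planted set); `NULL` for no planted set.
#' @param n_hits Size of the designated hit list.
#' @param set_size_range Size range of the random sets.
#' @param seed Integer seed.
#' @return List of class `geneset_collection`: `sets` (named list),
#'   `universe`, `hits`, `planted_set` (name or `NA`).
#' @export
sim_genesets <- function(universe_size = 2000, n_sets = 50,
                         planted = list(set_size = 50, hit_fraction = 0.8),
                         n_hits = 100,
                         set_size_range = c(10, 100), seed = 1) {
  assert_that(n_hits <= universe_size, "`n_hits` exceeds the universe")
  if (!is.null(planted)) {
    assert_that(planted$set_size <= universe_size,
                "planted set size exceeds the universe")
  }
  assert_that(max(set_size_range) <= universe_size,
              "random set sizes exceed the universe")
  with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(universe_size))
    hits <- sample(universe, n_hits)
    sets <- list()
    if (n_sets > 0) {
      sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                      replace = TRUE)
      sets <- lapply(sizes, function(sz) sample(universe, sz))
      names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    }
    planted_name <- NA_character_
    if (!is.null(planted)) {
      n_in <- round(planted$hit_fraction * min(n_hits, planted$set_size))
      members <- c(sample(hits, n_in),
                   sample(setdiff(universe, hits),
                          planted$set_size - n_in))
      planted_name <- "set_planted"
      sets[[planted_name]] <- members
    }
    structure(list(sets = sets, universe = universe, hits = hits,
                   planted_set = planted_name),
              class = "geneset_collection")
  })
}
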