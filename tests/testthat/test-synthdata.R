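test_that("expression generator emits the discovery cohort design and is seeded", {
  es <- sim_expression(seed = 11)
  expect_s3_class(es, "expr_set")
  grp <- table(sample_groups(es))
  expect_equal(unname(grp[c("NPC", "IgD", "IgG")]), c(3L, 5L, 5L),
               ignore_attr = TRUE)
  expect_equal(ncol(es$expr) - 1L, 13L)
  m <- expr_matrix(es)
  expect_true(all(is.finite(m)) && all(m >= 0))

  # bit-identical rerun with the same seed; different seed differs
  es2 <- sim_expression(seed = 11)
  expect_identical(es$expr, es2$expr)
  es3 <- sim_expression(seed = 12)
  expect_false(identical(es$expr, es3$expr))

  # ground truth records modules, IgD-up status and DE spikes
  tr <- es$truth$probes
  expect_equal(sum(tr$module > 0), sum(c(60, 50, 45, 40, 35, 30, 25)))
  expect_equal(sort(unique(tr$module[tr$igd_up])), c(1L, 5L))
  expect_equal(sum(tr$de_lfc == 2), 100L)
  expect_equal(sum(tr$de_lfc == -2), 100L)
})

test_that("within-module sample correlation tracks the configured value", {
  # one 50-probe module, 50 samples, cor 0.9: mean pairwise member
  # correlation within +/- 0.1 of the target, averaged over replicates
  cors <- vapply(1:20, function(s) {
    es <- sim_expression(n_probes = 50, groups = c(NPC = 17, IgD = 17,
                                                   IgG = 16),
                         n_modules = 1, module_sizes = 50,
                         within_module_cor = 0.9, n_igd_up_modules = 0,
                         de_spec = list(), seed = s)
    cc <- cor(t(expr_matrix(es, log2 = TRUE)))
    mean(cc[upper.tri(cc)])
  }, 1)
  expect_lt(abs(mean(cors) - 0.9), 0.1)
})

test_that("expression generator validates its configuration", {
  expect_error(sim_expression(n_probes = 100, module_sizes = rep(30, 7),
                              seed = 1), "module_sizes")
  expect_error(sim_expression(within_module_cor = 1.2, seed = 1),
               "within_module_cor")
  expect_error(sim_expression(groups = c(3, 5, 5), seed = 1), "named")
})

test_that("circle generator plants recoverable ORFs", {
  # direct construction: 12-nt circle, start 1, 2-aa product
  c1 <- sim_circle(circle_length = 12, start_pos = 1, product_length_aa = 2,
                   ires = NULL, seed = 3)
  expect_equal(nchar(c1$sequence), 12L)
  expect_equal(substr(c1$sequence, 1, 3), "AUG")
  calls <- find_circular_orfs(c1, min_length_aa = 1)
  planted <- calls[calls$start == 1, ]
  expect_equal(planted$length_aa, 2L)
  expect_equal(planted$traversals, 0L)

  # rolling-circle spec: 10-nt circle, 7-aa product, two junction crossings
  c2 <- sim_circle(circle_length = 10, start_pos = 1, product_length_aa = 7,
                   ires = NULL, seed = 5)
  calls2 <- find_circular_orfs(c2, min_length_aa = 1)
  planted2 <- calls2[calls2$start == 1, ]
  expect_equal(planted2$length_aa, 7L)
  expect_equal(planted2$traversals, 2L)

  # seeded determinism
  expect_identical(sim_circle(seed = 4)$sequence, sim_circle(seed = 4)$sequence)

  # frame-repeating circles cannot host a planted stop beyond one lap
  expect_error(sim_circle(circle_length = 12, start_pos = 1,
                          product_length_aa = 10, ires = NULL, seed = 1),
               "infeasible")
})

test_that("planted ORF recovery holds across random specs", {
  specs <- list(c(30, 4, 5), c(46, 10, 20), c(100, 33, 40), c(61, 1, 25),
                c(20, 7, 3))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    circ <- sim_circle(circle_length = sp[1], start_pos = sp[2],
                       product_length_aa = sp[3], ires = NULL, seed = 100 + i)
    calls <- find_circular_orfs(circ, max_traversals = 8, min_length_aa = 1)
    planted <- calls[calls$start == sp[2], ]
    expect_equal(nrow(planted), 1L)
    expect_equal(planted$length_aa, sp[3])
  }
})

test_that("splicing count generator respects its contract", {
  sim <- sim_as_counts(n_events = 200, seed = 2)
  expect_equal(nrow(sim$truth), 200L)
  expect_equal(nrow(sim$counts), 200L * 2L * 3L)
  expect_true(all(sim$counts$inclusion >= 0 & sim$counts$skipping >= 0))
  # determinism
  sim2 <- sim_as_counts(n_events = 200, seed = 2)
  expect_identical(sim$counts, sim2$counts)
  # invalid configs
  expect_error(sim_as_counts(depth = 0, seed = 1), "depth")
  expect_error(sim_as_counts(category_probs = c(SE = 0.5, RI = 0.4),
                             seed = 1), "sum to 1")
  # degenerate category distribution
  se_only <- sim_as_counts(n_events = 50, category_probs = c(SE = 1),
                           seed = 3)
  expect_true(all(se_only$truth$type == "SE"))
})

test_that("estimated PSI converges to true PSI at high depth", {
  sim <- sim_as_counts(n_events = 400, depth = 1e4, n_replicates = 2,
                       seed = 7)
  pooled <- dplyr::summarise(
    dplyr::group_by(sim$counts, .data$event_id, .data$condition),
    psi = compute_psi(sum(.data$inclusion), sum(.data$skipping)),
    .groups = "drop"
  )
  truth_long <- tidyr::pivot_longer(
    sim$truth[, c("event_id", "psi_cond1", "psi_cond2")],
    -"event_id", names_to = "condition", values_to = "true_psi",
    names_prefix = "psi_"
  )
  j <- dplyr::inner_join(pooled, truth_long,
                         by = c("event_id", "condition"))
  expect_lt(mean(abs(j$psi - j$true_psi)), 0.01)
})

test_that("survival generator links hazard to expression and censors as asked", {
  tab <- sim_survival(n_subjects = 400, hazard_ratio = 2,
                      censor_fraction = 0.25, seed = 3)
  expect_true(all(tab$time > 0))
  expect_true(all(tab$event %in% c(0L, 1L)))
  expect_lt(abs(mean(tab$event == 0) - 0.25), 0.08)
  # high-expression subjects die faster on average among events
  high <- attr(tab, "truth")$high
  expect_lt(median(tab$time[high]), median(tab$time[!high]))
  # no censoring
  tab0 <- sim_survival(n_subjects = 50, censor_fraction = 0, seed = 4)
  expect_true(all(tab0$event == 1L))
  expect_identical(sim_survival(seed = 5), sim_survival(seed = 5))
  expect_error(sim_survival(hazard_ratio = 0, seed = 1), "hazard_ratio")
  expect_error(sim_survival(censor_fraction = 1, seed = 1), "censor_fraction")
})

test_that("gene-set generator plants a recoverable enriched set", {
  # 4/5 of a 5-member hit list inside the planted set, universe 20
  gs <- sim_genesets(universe_size = 20, n_sets = 8,
                     planted = list(set_size = 5, hit_fraction = 0.8),
                     n_hits = 5, set_size_range = c(3, 8), seed = 9)
  expect_equal(length(gs$universe), 20L)
  res <- ora_enrichment(gs$hits, gs)
  expect_equal(res$set_name[1], "set_planted")
  # oracle check of the planted set's p-value
  top <- res[1, ]
  expect_equal(top$p, hyper_tail_oracle(top$overlap, top$set_size, 20,
                                        top$hit_count), tolerance = 1e-12)
  # empty collection and determinism
  gs0 <- sim_genesets(n_sets = 0, planted = NULL, seed = 1)
  expect_equal(length(gs0$sets), 0L)
  expect_identical(sim_genesets(seed = 2)$sets, sim_genesets(seed = 2)$sets)
  expect_error(sim_genesets(universe_size = 10, n_hits = 5,
                            planted = list(set_size = 50,
                                           hit_fraction = 0.5), seed = 1),
               "planted")
})
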