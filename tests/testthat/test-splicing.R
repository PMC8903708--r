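exons <- function(coords, strand = "+") {
  tibble::tibble(start = coords[, 1], end = coords[, 2], strand = strand)
}

ten_exon <- function() cbind(seq(100, 1000, by = 100),
                             seq(150, 1050, by = 100))

test_that("event classification types the canonical single-event cases", {
  full <- exons(ten_exon())
  # SKP2-like: same model missing internal exon 5
  skip5 <- exons(ten_exon()[-5, ])
  expect_equal(classify_as_event(full, skip5), "SE", ignore_attr = TRUE)
  expect_equal(attr(classify_as_event(full, skip5), "skipped_in"), "b")
  expect_equal(attr(classify_as_event(skip5, full), "skipped_in"), "a")

  expect_equal(classify_as_event(full, full), "none")

  # alternative donor on + strand: exon end differs
  a <- exons(rbind(c(100, 200), c(300, 400)))
  b <- exons(rbind(c(100, 230), c(300, 400)))
  expect_equal(classify_as_event(a, b), "A5SS", ignore_attr = TRUE)
  # the same change on the - strand is an acceptor-side difference
  am <- exons(rbind(c(100, 200), c(300, 400)), strand = "-")
  bm <- exons(rbind(c(100, 230), c(300, 400)), strand = "-")
  expect_equal(classify_as_event(am, bm), "A3SS", ignore_attr = TRUE)
  # start differing on + strand: acceptor side
  b2 <- exons(rbind(c(100, 200), c(280, 400)))
  expect_equal(classify_as_event(a, b2), "A3SS", ignore_attr = TRUE)

  # retained intron: two adjacent exons merged across the intron
  ri_a <- exons(rbind(c(100, 200), c(300, 400), c(500, 600)))
  ri_b <- exons(rbind(c(100, 400), c(500, 600)))
  expect_equal(classify_as_event(ri_a, ri_b), "RI", ignore_attr = TRUE)
  expect_equal(classify_as_event(ri_b, ri_a), "RI", ignore_attr = TRUE)

  # mutually exclusive internal exons with shared flanks
  mxe_a <- exons(rbind(c(100, 200), c(300, 350), c(700, 800)))
  mxe_b <- exons(rbind(c(100, 200), c(450, 500), c(700, 800)))
  expect_equal(classify_as_event(mxe_a, mxe_b), "MXE", ignore_attr = TRUE)

  # multi-difference pairs are reported as complex, not force-fitted
  cx <- exons(rbind(c(100, 210), c(320, 400), c(500, 600)))
  expect_equal(classify_as_event(ri_a, cx), "complex")

  expect_error(classify_as_event(a, am), "strand")
})

test_that("PSI follows the effective-length-normalized formula", {
  expect_equal(compute_psi(30, 0), 1)
  expect_equal(compute_psi(0, 30), 0)
  expect_equal(compute_psi(30, 30), (30 / 2) / (30 / 2 + 30), tolerance = 1e-12)
  expect_equal(compute_psi(30, 30), 1 / 3, tolerance = 1e-4)
  # scale invariance
  expect_equal(compute_psi(12, 7), compute_psi(12 * 13, 7 * 13),
               tolerance = 1e-12)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 3), "non-negative")
})

test_that("differential splicing matches the exact Fisher oracle", {
  counts <- tibble::tibble(
    event_id = rep(c("e1", "e2"), each = 2),
    sample = rep(c("s1", "s2"), 2),
    inclusion = c(12, 3, 5, 5),
    skipping = c(2, 11, 5, 5)
  )
  cond <- c(s1 = "cond1", s2 = "cond2")
  res <- differential_splicing(counts, cond)
  # e1 pools to the worked 2x2 table [[12,2],[3,11]]
  expect_equal(res$p[res$event_id == "e1"], fisher_oracle(12, 2, 3, 11),
               tolerance = 1e-9)
  expect_equal(res$p[res$event_id == "e1"],
               fisher.test(matrix(c(12, 2, 3, 11), 2))$p.value,
               tolerance = 1e-12)
  # identical tables: odds ratio 1, p = 1
  expect_equal(res$p[res$event_id == "e2"], 1)
  expect_equal(res$delta_psi[res$event_id == "e2"], 0)

  # Fisher equals enumeration for random tables with total <= 40
  set.seed(8)
  for (i in 1:25) {
    tot <- sample(4:40, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    tab <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], tot - cuts[3])
    p_pkg <- fisher.test(matrix(tab, 2))$p.value
    expect_equal(p_pkg, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("condition swap negates delta PSI and keeps the p-value", {
  sim <- sim_as_counts(n_events = 50, seed = 3)
  cond <- setNames(sim$counts$condition, sim$counts$sample)
  cond <- cond[!duplicated(names(cond))]
  res1 <- differential_splicing(sim$counts, cond)
  swapped <- setNames(ifelse(cond == "cond1", "cond2", "cond1"), names(cond))
  # relabel so conds sort the same way but groups swap
  res2 <- differential_splicing(sim$counts, swapped)
  expect_equal(res1$delta_psi, -res2$delta_psi, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("differential splicing is calibrated under the null", {
  fracs <- vapply(1:10, function(s) {
    sim <- sim_as_counts(n_events = 1000, psi_cond1 = NULL, seed = 500 + s)
    # force the null: condition 2 regenerated with condition-1 PSI
    simn <- sim_as_counts(n_events = 1000, psi_cond1 = sim$truth$psi_cond1,
                          psi_cond2 = sim$truth$psi_cond1, seed = 500 + s)
    cond <- setNames(simn$counts$condition, simn$counts$sample)
    cond <- cond[!duplicated(names(cond))]
    res <- differential_splicing(simn$counts, cond)
    mean(res$significant)
  }, 1)
  expect_lte(mean(fracs), 0.05)
})

test_that("zero-count events are excluded with a warning", {
  counts <- tibble::tibble(
    event_id = c("dead", "dead", "live", "live"),
    sample = c("s1", "s2", "s1", "s2"),
    inclusion = c(0, 0, 6, 2), skipping = c(0, 0, 2, 7)
  )
  expect_warning(res <- differential_splicing(
    counts, c(s1 = "cond1", s2 = "cond2")), "zero total")
  expect_equal(res$event_id, "live")
})

test_that("category summaries report count/total percentages", {
  ev <- tibble::tibble(
    event_id = sprintf("e%02d", 1:12),
    type = c(rep("SE", 6), rep("RI", 3), rep("MXE", 3)),
    significant = c(rep(TRUE, 6), rep(TRUE, 3), c(TRUE, FALSE, FALSE))
  )
  sm <- summarize_categories(ev)
  expect_equal(sm$count[sm$type == "SE"], 6L)
  expect_equal(sm$label[sm$type == "SE"], "6/10 (60.00%)")
  expect_equal(sum(sm$count), 10L)
  expect_equal(nrow(summarize_categories(ev[0, ])), 0L)

  # multinomial sampling: SE share near its configured probability
  sim <- sim_as_counts(n_events = 2000, seed = 10)
  se_share <- mean(sim$truth$type == "SE")
  expect_lt(abs(se_share - 0.60), 0.03)
})

test_that("RIP intersection ranks candidate direct targets by |delta PSI|", {
  ev <- tibble::tibble(
    event_id = c("e1", "e2", "e3", "e4"),
    gene_id = c("g1", "g2", "g3", "g4"),
    delta_psi = c(0.1, -0.5, 0.3, 0.8),
    significant = c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(nrow(intersect_rip_targets(ev, c("zz"))), 0L)
  hit <- intersect_rip_targets(ev, c("g2", "g4", "g1"))
  # e4 is not significant; e2 has the largest |delta_psi| among hits
  expect_equal(hit$event_id, c("e2", "e1"))

  # planted strongest event lands first on simulated data
  sim <- sim_as_counts(n_events = 300, depth = 200, seed = 12)
  cond <- setNames(sim$counts$condition, sim$counts$sample)
  cond <- cond[!duplicated(names(cond))]
  res <- differential_splicing(sim$counts, cond)
  res$gene_id <- sim$truth$gene_id[match(res$event_id, sim$truth$event_id)]
  diff_genes <- sim$truth$gene_id[sim$truth$differential]
  ranked <- intersect_rip_targets(res, diff_genes)
  expect_gt(nrow(ranked), 0)
  expect_equal(ranked$event_id,
               ranked$event_id[order(-abs(ranked$delta_psi),
                                     ranked$event_id)])
})
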