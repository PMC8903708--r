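#' Classify the alternative-splicing event between two isoforms
#'
#' Compares the exon chains of two isoforms of the same gene (same strand)
#' and types the single event separating them:
#' * `SE` — one isoform lacks exactly one internal exon of the other, flanks
#'   identical (skipped exon).
#' * `A5SS` / `A3SS` — exactly one shared exon differs at one end; the donor
#'   end (3' end of the exon in transcription direction: `end` on `+`,
#'   `start` on `-`) gives A5SS, the acceptor end A3SS.
#' * `RI` — one isoform merges two adjacent exons of the other across their
#'   intron (retained intron).
#' * `MXE` — each isoform has one internal exon absent from the other, the
#'   two exons do not overlap, flanks identical (mutually exclusive exons).
#' * `none` — identical exon chains.
#' * `complex` — anything else (multi-event differences are reported, not
#'   force-fitted).
#'
#' @param iso_a,iso_b Exon tables: data frames with `start`, `end` (1-based
#'   inclusive) and a common `strand` (`+`/`-`), one row per exon.
#' @return A single event-type string; for `SE` the attribute `skipped_in`
#'   records which isoform (`"a"`/`"b"`) lacks the exon.
#' @export
classify_as_event <- function(iso_a, iso_b) {
  ea <- normalize_exons(iso_a)
  eb <- normalize_exons(iso_b)
  assert_that(attr(ea, "strand") == attr(eb, "strand"),
              "isoforms are on different strands")
  strand <- attr(ea, "strand")
  key <- function(e) paste(e$start, e$end)
  if (identical(key(ea), key(eb))) return("none")

  only_a <- dplyr::anti_join(ea, eb, by = c("start", "end"))
  only_b <- dplyr::anti_join(eb, ea, by = c("start", "end"))

  # SE: the isoform with one exon more has an internal exon absent from the
  # other; remaining chains identical.
  se <- function(long, short, label) {
    if (nrow(long) == nrow(short) + 1) {
      extra <- dplyr::anti_join(long, short, by = c("start", "end"))
      rest <- dplyr::anti_join(long, extra, by = c("start", "end"))
      if (nrow(extra) == 1 && identical(key(rest), key(short)) &&
          extra$start > min(long$start) && extra$end < max(long$end)) {
        return(structure("SE", skipped_in = label))
      }
    }
    NULL
  }
  out <- se(ea, eb, "b") %||% se(eb, ea, "a")
  if (!is.null(out)) return(out)

  # A5SS/A3SS: exactly one differing exon on each side, sharing one boundary.
  if (nrow(only_a) == 1 && nrow(only_b) == 1) {
    same_start <- only_a$start == only_b$start
    same_end <- only_a$end == only_b$end
    if (xor(same_start, same_end)) {
      donor_is_end <- strand == "+"
      differs_at_donor <- if (donor_is_end) !same_end else !same_start
      return(if (differs_at_donor) "A5SS" else "A3SS")
    }
    # MXE: the two differing exons are disjoint internal exons, same flanks.
    disjoint <- only_a$end < only_b$start || only_b$end < only_a$start
    internal <- only_a$start > min(ea$start) && only_a$end < max(ea$end) &&
      only_b$start > min(eb$start) && only_b$end < max(eb$end)
    if (disjoint && internal) return("MXE")
    return("complex")
  }
  # RI: one isoform merges two adjacent exons of the other across the intron
  # (2 exons on one side differ, the single merged exon on the other).
  for (ord in list(list(ea, eb), list(eb, ea))) {
    a2 <- ord[[1]]; b2 <- ord[[2]]
    if (nrow(a2) == nrow(b2) + 1) {
      oa <- dplyr::anti_join(a2, b2, by = c("start", "end"))
      ob <- dplyr::anti_join(b2, a2, by = c("start", "end"))
      if (nrow(oa) == 2 && nrow(ob) == 1 &&
          min(oa$start) == ob$start && max(oa$end) == ob$end) {
        return("RI")
      }
    }
  }
  "complex"
}

normalize_exons <- function(iso) {
  e <- as_tibble(iso)
  assert_that(all(c("start", "end") %in% names(e)),
              "exon table needs `start` and `end` columns")
  strand <- if ("strand" %in% names(e)) unique(as.character(e$strand)) else "+"
  assert_that(length(strand) == 1, "exon table mixes strands")
  assert_that(all(e$start <= e$end), "exon start must be <= end")
  e <- arrange(e[, c("start", "end")], .data$start)
  assert_that(all(e$end[-nrow(e)] < e$start[-1] | nrow(e) == 1),
              "exons overlap")
  structure(e, strand = strand)
}

#' Percent spliced in (PSI) from junction counts
#'
#' `psi = (I / eff_len_inc) / (I / eff_len_inc + S / eff_len_skip)` — the
#' effective-length-normalized inclusion fraction; the default lengths
#' `(2, 1)` reflect the two inclusion junctions versus one skipping junction
#' of an exon-skipping event. Undefined (`NA`) when both counts are zero.
#'
#' @param inclusion_count,skipping_count Non-negative junction read counts
#'   (vectorized).
#' @param eff_len_inc,eff_len_skip Positive effective lengths.
#' @return PSI in `[0, 1]`, `NA` where both counts are zero.
#' @export
compute_psi <- function(inclusion_count, skipping_count,
                        eff_len_inc = 2, eff_len_skip = 1) {
  assert_that(all(inclusion_count >= 0) && all(skipping_count >= 0),
              "junction counts must be non-negative")
  assert_that(eff_len_inc > 0 && eff_len_skip > 0,
              "effective lengths must be positive")
  i <- inclusion_count / eff_len_inc
  s <- skipping_count / eff_len_skip
  out <- i / (i + s)
  out[inclusion_count == 0 & skipping_count == 0] <- NA_real_
  out
}

#' Differential splicing between two conditions
#'
#' Per event, inclusion and skipping junction counts are summed within each
#' condition and compared with a two-sided Fisher exact test on the 2x2
#' table; q-values are BH-adjusted across events and an event is significant
#' at `q < alpha`. `delta_psi` is the difference of mean per-replicate PSI
#' (condition 2 minus condition 1). Events with zero total count are excluded
#' with a warning.
#'
#' @param counts Tibble with columns `event_id`, `sample`, `inclusion`,
#'   `skipping` and optionally `gene_id`, `type` (carried through).
#' @param condition_map Named condition vector over samples, or a tibble
#'   `(sample, condition)`; exactly two conditions.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param eff_len_inc,eff_len_skip Effective lengths for PSI.
#' @return Tibble of class `as_events`: per event `psi_1`, `psi_2`,
#'   `delta_psi`, `p`, `q`, `significant` (plus carried columns), conditions
#'   in `attr(, "conditions")`.
#' @export
differential_splicing <- function(counts, condition_map, alpha = 0.05,
                                  eff_len_inc = 2, eff_len_skip = 1) {
  if (is.data.frame(condition_map)) {
    condition_map <- setNames(as.character(condition_map$condition),
                              condition_map$sample)
  }
  conds <- sort(unique(condition_map))
  assert_that(length(conds) == 2, "exactly two conditions are required")
  counts <- as_tibble(counts)
  assert_that(all(counts$sample %in% names(condition_map)),
              "every sample needs a condition")
  counts$condition <- condition_map[counts$sample]
  totals <- counts |>
    group_by(.data$event_id) |>
    summarise(total = sum(.data$inclusion + .data$skipping), .groups = "drop")
  dead <- totals$event_id[totals$total == 0]
  if (length(dead)) {
    warn(sprintf("excluding %d event(s) with zero total counts", length(dead)))
    counts <- counts[!counts$event_id %in% dead, , drop = FALSE]
  }
  carry_cols <- intersect(c("gene_id", "type"), names(counts))
  per_event <- counts |>
    group_by(.data$event_id) |>
    summarise(
      dplyr::across(dplyr::all_of(carry_cols), dplyr::first),
      i1 = sum(.data$inclusion[.data$condition == conds[1]]),
      s1 = sum(.data$skipping[.data$condition == conds[1]]),
      i2 = sum(.data$inclusion[.data$condition == conds[2]]),
      s2 = sum(.data$skipping[.data$condition == conds[2]]),
      psi_1 = mean(compute_psi(.data$inclusion[.data$condition == conds[1]],
                               .data$skipping[.data$condition == conds[1]],
                               eff_len_inc, eff_len_skip), na.rm = TRUE),
      psi_2 = mean(compute_psi(.data$inclusion[.data$condition == conds[2]],
                               .data$skipping[.data$condition == conds[2]],
                               eff_len_inc, eff_len_skip), na.rm = TRUE),
      .groups = "drop"
    )
  per_event$p <- purrr::pmap_dbl(
    per_event[, c("i1", "s1", "i2", "s2")],
    function(i1, s1, i2, s2)
      fisher.test(matrix(c(i1, s1, i2, s2), 2))$p.value
  )
  per_event <- per_event |>
    mutate(delta_psi = .data$psi_2 - .data$psi_1,
           q = bh_adjust(.data$p),
           significant = .data$q < alpha)
  attr(per_event, "conditions") <- conds
  class(per_event) <- c("as_events", class(per_event))
  per_event
}

#' Summarise significant splicing events by category
#'
#' Counts and percentages of significant events per event type, formatted
#' `"count/total (pct%)"`.
#'
#' @param events An `as_events` tibble (or any tibble with `type` and
#'   `significant` columns).
#' @return Tibble `(type, count, total, pct, label)` sorted by decreasing
#'   count; empty input gives an empty summary.
#' @export
summarize_categories <- function(events) {
  sig <- events[isTRUE_vec(events$significant), , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble(type = character(), count = integer(), total = integer(),
                  pct = numeric(), label = character()))
  }
  total <- nrow(sig)
  sig |>
    count(.data$type, name = "count") |>
    mutate(total = total, pct = 100 * .data$count / total,
           label = sprintf("%d/%d (%.2f%%)", .data$count, total, .data$pct)) |>
    arrange(desc(.data$count), .data$type)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Intersect splicing events with RIP-bound transcripts
#'
#' Significant events whose gene/transcript is in the RIP-seq bound set,
#' ranked by `|delta_psi|` descending (ties by event id) — the candidate
#' direct targets of the RNA-binding protein.
#'
#' @param events An `as_events` tibble with a `gene_id` column.
#' @param rip Character vector of bound transcript/gene ids (or a list with
#'   an `ids` element).
#' @return The filtered, ranked events tibble.
#' @export
intersect_rip_targets <- function(events, rip) {
  ids <- if (is.list(rip) && !is.null(rip$ids)) rip$ids else rip
  assert_that(!anyDuplicated(ids), "RIP target ids must be unique")
  events |>
    filter(isTRUE_vec(.data$significant), .data$gene_id %in% ids) |>
    arrange(desc(abs(.data$delta_psi)), .data$event_id)
}
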