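#' Circular transcript object
#'
#' A covalently closed RNA sequence with junction-anchored coordinates:
#' position 1 is the first nucleotide downstream of the back-splice junction,
#' so the junction lies between positions `L` and 1. `T` is accepted and
#' mapped to `U`; lower case is upper-cased.
#'
#' @param id Transcript identifier.
#' @param sequence RNA (or DNA) sequence string, length >= 3.
#' @param circular Logical flag; the ORF finder requires `TRUE`.
#' @param ires Optional 1-based `(start, end)` of an internal ribosome entry
#'   site, in circular coordinates.
#' @param source_exons Optional label of the originating exons (e.g.
#'   `"E2..E13"`).
#' @return Object of class `circular_transcript`.
#' @export
circular_transcript <- function(id, sequence, circular = TRUE, ires = NULL,
                                source_exons = NULL) {
  seq <- chartr("acgutT", "ACGUUU", sequence)
  assert_that(nchar(seq) >= 3, "sequence must be at least 3 nt")
  assert_that(!grepl("[^ACGU]", seq),
              "sequence contains characters outside {A,C,G,U,T}")
  if (!is.null(ires)) {
    assert_that(length(ires) == 2 && ires[1] >= 1 && ires[1] <= ires[2] &&
                  ires[2] <= nchar(seq),
                "IRES interval out of bounds (coordinates are 1-based)")
    ires <- as.integer(ires)
  }
  structure(list(id = id, sequence = seq, circular = isTRUE(circular),
                 ires = ires, source_exons = source_exons),
            class = "circular_transcript")
}

#' @export
print.circular_transcript <- function(x, ...) {
  cat(sprintf("<circular_transcript> %s: %d nt%s%s\n", x$id,
              nchar(x$sequence), if (x$circular) " (circular)" else "",
              if (!is.null(x$ires))
                sprintf(", IRES %d-%d", x$ires[1], x$ires[2]) else ""))
  invisible(x)
}

STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Translate an RNA sequence with the standard genetic code
#'
#' Trailing partial codons are dropped; stop codons translate to `*`. No
#' N-terminal methionine excision is modelled.
#'
#' @param rna RNA string over `{A,C,G,U}` (T accepted).
#' @return Amino-acid string.
#' @export
translate_rna <- function(rna) {
  rna <- chartr("T", "U", toupper(rna))
  n <- nchar(rna) %/% 3
  if (n == 0) return("")
  codons <- substring(rna, 3 * seq_len(n) - 2, 3 * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  aa <- code[chartr("U", "T", codons)]
  paste(aa, collapse = "")
}

#' Find open reading frames on a circular transcript
#'
#' Scans every `AUG` whose `A` lies at circular positions `1..L` and reads
#' codons on the conceptually repeated sequence, crossing the back-splice
#' junction as needed, until the first stop codon (`UAA`/`UAG`/`UGA`) or
#' until `max_traversals` junction crossings are exhausted (the call is then
#' flagged unterminated with `stop_codon = "none"`). Rolling-circle ORFs —
#' coding spans longer than the circle — are therefore found naturally. The
#' `traversals` field counts junction crossings before the stop codon
#' completes: `floor((start - 1 + length_nt - 1) / L)`.
#'
#' @param circ A [circular_transcript] with `circular = TRUE`.
#' @param max_traversals Cap on junction crossings (default 4); ORFs on
#'   circles with `L` divisible by 3 can never terminate once they survive a
#'   full frame-preserving lap and are reported as unterminated.
#' @param min_length_aa Calls shorter than this are dropped (default 20).
#' @return Tibble of class `orf_calls`, sorted by `length_aa` descending then
#'   `start` ascending: `transcript_id`, `start`, `frame_offset`,
#'   `length_aa`, `length_nt`, `traversals`, `stop_codon`, `unterminated`,
#'   `peptide`. The primary ORF is the first junction-spanning call; see
#'   [primary_orf()].
#' @export
find_circular_orfs <- function(circ, max_traversals = 4, min_length_aa = 20) {
  stopifnot(inherits(circ, "circular_transcript"))
  assert_that(circ$circular,
              "transcript is not circular; use a linear ORF scanner instead")
  s <- circ$sequence
  L <- nchar(s)
  big <- strrep(s, max_traversals + 2L)
  max_end <- (max_traversals + 1L) * L  # codon ends beyond this exceed the cap
  starts <- which(vapply(seq_len(L), function(p)
    substr(big, p, p + 2L) == "AUG", logical(1)))
  calls <- purrr::map_dfr(starts, function(p) {
    n_codons <- (max_end - p + 1L) %/% 3L
    if (n_codons < 1L) return(NULL)
    idx <- p + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(big, idx, idx + 2L)
    stop_at <- which(codons %in% STOP_CODONS)[1]
    if (is.na(stop_at)) {
      length_aa <- n_codons
      length_nt <- 3L * n_codons
      stop_codon <- "none"
      unterminated <- TRUE
      pep <- translate_rna(paste(codons, collapse = ""))
    } else {
      length_aa <- stop_at - 1L
      length_nt <- 3L * stop_at
      stop_codon <- codons[stop_at]
      unterminated <- FALSE
      pep <- translate_rna(paste(codons[seq_len(length_aa)], collapse = ""))
    }
    tibble(
      transcript_id = circ$id, start = p,
      frame_offset = (p - 1L) %% 3L,
      length_aa = length_aa, length_nt = length_nt,
      traversals = (p - 1L + length_nt - 1L) %/% L,
      stop_codon = stop_codon, unterminated = unterminated, peptide = pep
    )
  })
  if (nrow(calls) == 0) {
    calls <- tibble(transcript_id = character(), start = integer(),
                    frame_offset = integer(), length_aa = integer(),
                    length_nt = integer(), traversals = integer(),
                    stop_codon = character(), unterminated = logical(),
                    peptide = character())
  }
  calls <- calls |>
    filter(.data$length_aa >= min_length_aa) |>
    arrange(desc(.data$length_aa), .data$start)
  class(calls) <- c("orf_calls", class(calls))
  calls
}

#' Primary junction-spanning ORF
#'
#' The first junction-spanning call (traversals >= 1) in the sorted call
#' list: the longest ORF whose reading crosses the back-splice junction.
#'
#' @param calls An `orf_calls` tibble from [find_circular_orfs()].
#' @return A one-row tibble, or a zero-row tibble if no call spans the
#'   junction.
#' @export
primary_orf <- function(calls) {
  head(calls[calls$traversals >= 1, , drop = FALSE], 1)
}

#' Flag IRES-proximal ORF starts
#'
#' Marks a call IRES-proximal when its start codon lies within the circular
#' interval from the IRES 5' end to `window` nt downstream of the IRES 3'
#' end (boundaries inclusive).
#'
#' @param calls An `orf_calls` tibble.
#' @param circ The [circular_transcript] carrying the IRES annotation.
#' @param window Downstream proximity window in nt (default 60).
#' @return The calls with an added/updated logical `ires_proximal` column.
#'   If the transcript has no IRES the calls are returned unchanged with a
#'   warning.
#' @export
annotate_ires <- function(calls, circ, window = 60) {
  stopifnot(inherits(circ, "circular_transcript"))
  if (is.null(circ$ires)) {
    warn("transcript has no IRES annotation; calls returned unchanged")
    return(calls)
  }
  L <- nchar(circ$sequence)
  span <- min(circ$ires[2] + window - circ$ires[1], L - 1L)
  offset <- (calls$start - circ$ires[1]) %% L
  calls$ires_proximal <- offset <= span
  calls
}

#' Back-splice junction probe sequence
#'
#' The `2 * flank` nt sequence a junction-specific probe or divergent-primer
#' amplicon must cover: the last `flank` nt of the circle followed by the
#' first `flank` nt.
#'
#' @param circ A [circular_transcript].
#' @param flank Flank length on each side of the junction; at most `L / 2`.
#' @return String of length `2 * flank`.
#' @export
junction_probe_sequence <- function(circ, flank = 25) {
  stopifnot(inherits(circ, "circular_transcript"))
  L <- nchar(circ$sequence)
  assert_that(flank <= L / 2, "`flank` exceeds half the circle length")
  if (flank == 0) return("")
  paste0(substr(circ$sequence, L - flank + 1L, L),
         substr(circ$sequence, 1L, flank))
}
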