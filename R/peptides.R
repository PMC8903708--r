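#' In-silico protease digest
#'
#' Trypsin rule: cleave C-terminal to K or R except when the next residue is
#' P. With `missed_cleavages > 0`, peptides spanning up to that many skipped
#' cleavage sites are also emitted.
#'
#' @param protein Amino-acid string (standard one-letter codes).
#' @param protease Only `"trypsin"` is implemented.
#' @param missed_cleavages Maximum number of missed cleavage sites.
#' @return Character vector of peptides in N- to C-terminal order.
#' @export
digest_protein <- function(protein, protease = "trypsin",
                           missed_cleavages = 0) {
  protease <- match.arg(protease, "trypsin")
  assert_that(nchar(protein) > 0, "protein sequence is empty")
  assert_that(!grepl("[^ACDEFGHIKLMNPQRSTVWY*]", protein),
              "protein contains non-amino-acid characters")
  frags <- strsplit(gsub("(?<=[KR])(?!P)", "\30", protein, perl = TRUE),
                    "\30", fixed = TRUE)[[1]]
  if (missed_cleavages == 0 || length(frags) == 1) return(frags)
  out <- frags
  for (mc in seq_len(missed_cleavages)) {
    if (length(frags) <= mc) break
    joined <- vapply(seq_len(length(frags) - mc), function(i)
      paste(frags[i:(i + mc)], collapse = ""), "")
    out <- c(out, joined)
  }
  out
}

#' Junction-unique peptides of a circRNA-encoded protein
#'
#' Peptides produced by an in-silico digest of the circRNA-encoded protein
#' that cannot arise from the linear host-gene protein — the peptide set a
#' mass-spectrometry experiment can use to prove translation across the
#' back-splice junction. Peptides shorter than `min_length` residues are
#' excluded (MS-detectability convention, default 6).
#'
#' @param circ_protein Amino-acid sequence of the circRNA-encoded isoform.
#' @param linear_protein Amino-acid sequence of the linear isoform.
#' @param protease Passed to [digest_protein()].
#' @param missed_cleavages Passed to [digest_protein()].
#' @param min_length Minimum peptide length reported.
#' @return Sorted character vector of peptides unique to `circ_protein`.
#' @export
junction_peptides <- function(circ_protein, linear_protein,
                              protease = "trypsin", missed_cleavages = 0,
                              min_length = 6) {
  pc <- digest_protein(circ_protein, protease, missed_cleavages)
  pl <- digest_protein(linear_protein, protease, missed_cleavages)
  uniq <- setdiff(pc, pl)
  sort(uniq[nchar(uniq) >= min_length])
}
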