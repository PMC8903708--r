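#' Simulate a circular transcript with a planted ORF
#'
#' Constructs a circular RNA of exactly `circle_length` nt carrying a planted
#' open reading frame: an `AUG` at `start_pos`, `product_length_aa` non-stop
#' codons, then the first in-frame stop codon — reading across the
#' back-splice junction as many times as needed, so products longer than
#' `circle_length / 3` yield rolling-circle ORFs. No other in-frame `AUG`
#' occurs upstream of the planted start within the first traversal, and no
#' in-frame stop intervenes before the planted one. Stop placement is
#' computed on the concatenated sequence and projected back to circular
#' coordinates; because traversals revisit positions in shifted frames, the
#' builder uses a constraint-repair loop and verifies the planted call by
#' re-running the ORF finder.
#'
#' @param circle_length Circle length in nt (default 1733, the circHNRNPU
#'   preset).
#' @param start_pos Circular coordinate of the `A` of the start codon
#'   (default 380, just downstream of the preset IRES).
#' @param product_length_aa Planted product length in amino acids (default
#'   603).
#' @param ires Optional IRES interval `(start, end)` recorded on the
#'   transcript (default `c(201, 374)`).
#' @param id Transcript id.
#' @param seed Integer seed.
#' @return A [circular_transcript]; the planted truth (start, product
#'   length) is attached as `attr(, "truth")`.
#' @export
sim_circle <- function(circle_length = 1733, start_pos = 380,
                       product_length_aa = 603, ires = c(201, 374),
                       id = "circ_sim", seed = 1) {
  L <- as.integer(circle_length)
  aa <- as.integer(product_length_aa)
  start_pos <- as.integer(start_pos)
  assert_that(L >= 6, "`circle_length` must be at least 6 nt")
  assert_that(start_pos >= 1 && start_pos <= L,
              "`start_pos` must lie in 1..circle_length")
  assert_that(aa >= 1, "`product_length_aa` must be >= 1")
  length_nt <- 3L * (aa + 1L)
  if (L %% 3L == 0L && length_nt > L) {
    abort(paste0("infeasible spec: on a circle with length divisible by 3 ",
                 "the reading frame repeats after one traversal, so the ",
                 "planted stop would collide with an earlier body codon"))
  }

  circ_idx <- function(pos) ((pos - 1L) %% L) + 1L
  codon_pos <- function(j) circ_idx(start_pos + 3L * (j - 1L) + 0:2)
  upstream_frame <- setdiff(seq(((start_pos - 1L) %% 3L) + 1L, L, by = 3L),
                            start_pos)
  upstream_frame <- upstream_frame[upstream_frame < start_pos]

  with_seed(seed, {
    for (attempt in seq_len(200)) {
      s <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      s[codon_pos(1L)] <- c("A", "U", "G")
      ok <- FALSE
      for (pass in seq_len(100)) {
        violation <- FALSE
        # Body codons 2..aa must not be stops.
        for (j in 2:(aa + 1L)) {
          idx <- codon_pos(j)
          cod <- paste(s[idx], collapse = "")
          if (j <= aa && cod %in% STOP_CODONS) {
            s[idx[3L]] <- sample(c("C", "G", "U"), 1)
            violation <- TRUE
          } else if (j == aa + 1L && !(cod %in% STOP_CODONS)) {
            s[idx] <- c("U", "A", "A")
            violation <- TRUE
          }
        }
        # No upstream in-frame AUG before the planted start.
        for (q in upstream_frame) {
          if (paste(s[circ_idx(q + 0:2)], collapse = "") == "AUG") {
            s[circ_idx(q + 1L)] <- sample(c("A", "C", "G"), 1)
            violation <- TRUE
          }
        }
        if (!violation) { ok <- TRUE; break }
      }
      if (!ok) next
      circ <- circular_transcript(id, paste(s, collapse = ""), circular = TRUE,
                                  ires = ires)
      needed <- (start_pos - 1L + length_nt - 1L) %/% L
      calls <- find_circular_orfs(circ, max_traversals = max(4L, needed),
                                  min_length_aa = 1)
      planted <- calls[calls$start == start_pos, , drop = FALSE]
      recovered <- nrow(planted) == 1 && planted$length_aa == aa &&
        !planted$unterminated
      primary_ok <- recovered &&
        (planted$traversals < 1L ||
           identical(primary_orf(calls)$start, start_pos))
      if (recovered && primary_ok) {
        attr(circ, "truth") <- list(start = start_pos,
                                    product_length_aa = aa, seed = seed)
        return(circ)
      }
    }
    abort("generation error: could not realise the planted ORF spec")
  })
}

#' The circHNRNPU fixture circle
#'
#' The packaged preset emulating the 1733-nt circle with an IRES at +201 to
#' +374 and a 603-aa rolling-circle product. The planted start (position
#' 380) is IRES-proximal; since the coding span (1812 nt including the stop)
#' exceeds the circle length, the ribosome crosses the back-splice junction
#' and finishes on its second lap around the circle.
#'
#' @param seed Integer seed for the sequence fill.
#' @return A [circular_transcript].
#' @export
circhnrnpu_circle <- function(seed = 1) {
  sim_circle(circle_length = 1733, start_pos = 380, product_length_aa = 603,
             ires = c(201, 374), id = "circHNRNPU_sim", seed = seed)
}
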