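#' Read a probe-by-sample expression matrix with its sample annotation
#'
#' Expression TSV: header row of sample ids, first column probe ids, linear
#' scale values. Annotation TSV: columns `sample_id` and `group`. Malformed
#' input (duplicate ids, missing groups, non-numeric cells) is rejected with
#' the offending location, never coerced.
#'
#' @param path Expression TSV path.
#' @param annotation_path Sample-annotation TSV path.
#' @return An [expr_set]; probe and sample order preserved.
#' @export
read_expression <- function(path, annotation_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, name_repair = "minimal")
  names(raw)[1] <- "probe_id"
  for (j in seq_along(raw)[-1]) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & !is.na(raw[[j]]))
    if (length(bad)) {
      abort(sprintf("non-numeric cell at row %d, column `%s` of %s",
                    bad[1], names(raw)[j], path))
    }
    raw[[j]] <- num
  }
  ann <- readr::read_tsv(annotation_path,
                         col_types = readr::cols(.default =
                                                   readr::col_character()),
                         progress = FALSE)
  assert_that(all(c("sample_id", "group") %in% names(ann)),
              "annotation needs `sample_id` and `group` columns")
  missing <- setdiff(names(raw)[-1], ann$sample_id)
  assert_that(length(missing) == 0,
              paste0("sample without group annotation: ", missing[1]))
  expr_set(raw, ann[, c("sample_id", "group")])
}

#' @rdname read_expression
#' @param data An [expr_set] to write.
#' @export
write_expression <- function(data, path, annotation_path) {
  stopifnot(inherits(data, "expr_set"))
  readr::write_tsv(data$expr, path, progress = FALSE)
  readr::write_tsv(data$samples, annotation_path, progress = FALSE)
  invisible(data)
}

#' Read circular transcripts from FASTA
#'
#' Header tokens after the id may include `circular=true` and
#' `ires=START-END` (1-based circular coordinates). Bodies are upper-cased
#' and `T` mapped to `U`.
#'
#' @param path FASTA path.
#' @return Named list of [circular_transcript] objects.
#' @export
read_circular_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    tokens <- strsplit(header, "\\s+")[[1]]
    id <- tokens[1]
    kv <- tokens[-1][grepl("=", tokens[-1])]
    vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    circular <- isTRUE(tolower(vals["circular"]) == "true")
    ires <- NULL
    if (!is.na(vals["ires"])) {
      parts <- as.integer(strsplit(vals[["ires"]], "-")[[1]])
      assert_that(length(parts) == 2 && !anyNA(parts),
                  paste0("malformed ires token in header: ", header))
      assert_that(parts[1] >= 1,
                  "IRES coordinates are 1-based; got a start < 1")
      ires <- parts
    }
    circular_transcript(id, as.character(seqs[[i]]), circular = circular,
                        ires = ires)
  })
  names(out) <- vapply(out, function(x) x$id, "")
  out
}

#' @rdname read_circular_fasta
#' @param transcripts List of [circular_transcript] objects (or one).
#' @param width Line width for the sequence body.
#' @export
write_circular_fasta <- function(transcripts, path, width = 70) {
  if (inherits(transcripts, "circular_transcript")) {
    transcripts <- list(transcripts)
  }
  lines <- unlist(lapply(transcripts, function(x) {
    header <- paste0(">", x$id,
                     if (x$circular) " circular=true" else "",
                     if (!is.null(x$ires))
                       sprintf(" ires=%d-%d", x$ires[1], x$ires[2]) else "")
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", x$sequence)
    c(header, strsplit(body, "\n")[[1]])
  }))
  writeLines(lines, path)
  invisible(transcripts)
}

#' Read transcript exon models from GTF
#'
#' Keeps `exon` features, groups them by `transcript_id` (an exon without a
#' transcript id is a parse error) and sorts exons by ascending start.
#'
#' @param path GTF path.
#' @return Tibble of class `transcript_models`: `transcript_id`, `seqname`,
#'   `start`, `end`, `strand`, one row per exon.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    abort("GTF exon feature without a transcript_id attribute")
  }
  out <- tibble(
    transcript_id = as.character(tid),
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    arrange(.data$transcript_id, .data$start)
  class(out) <- c("transcript_models", class(out))
  out
}

#' @rdname read_transcript_models
#' @param models A `transcript_models` tibble.
#' @export
write_transcript_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$seqname %||% "chr1",
    ranges = IRanges::IRanges(models$start, models$end),
    strand = models$strand,
    type = "exon",
    transcript_id = models$transcript_id,
    gene_id = models$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(models)
}

#' Read or write a survival table (CSV)
#'
#' Columns: `subject_id`, `time` (positive, months), `event` (0/1),
#' `expression`.
#'
#' @param path CSV path.
#' @return Tibble with the validated columns.
#' @export
read_survival_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer(),
    expression = readr::col_double()
  ), progress = FALSE)
  assert_that(all(tab$time > 0), "survival times must be positive")
  assert_that(all(tab$event %in% c(0L, 1L)), "event must be 0/1")
  tab
}

#' @rdname read_survival_table
#' @param table Survival tibble to write.
#' @export
write_survival_table <- function(table, path) {
  readr::write_csv(table[, c("subject_id", "time", "event", "expression")],
                   path, progress = FALSE)
  invisible(table)
}

#' Read or write gene-set collections (GMT-like)
#'
#' One set per line: `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' The universe defaults to the union of all members.
#'
#' @param path GMT path.
#' @param universe Optional universe (must contain every member).
#' @return A `geneset_collection` list (`sets`, `universe`).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1)
  members <- unique(unlist(sets))
  universe <- universe %||% sort(members)
  bad <- setdiff(members, universe)
  assert_that(length(bad) == 0,
              paste0("set member outside the universe: ", bad[1]))
  structure(list(sets = sets, universe = universe),
            class = "geneset_collection")
}

#' @rdname read_gmt
#' @param sets A `geneset_collection` (or named list of member vectors).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "geneset_collection")) sets <- sets$sets
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}
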