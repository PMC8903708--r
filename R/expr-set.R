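#' Expression dataset container
#'
#' Bundles a probe-by-sample expression tibble (linear, FPKM-like scale) with
#' its sample annotation and, for simulated data, the generating ground truth.
#' This is the substrate of the filtering, differential-expression, network
#' and hub-screening stages.
#'
#' @param expr Tibble or data frame whose first column is `probe_id` and whose
#'   remaining columns are one numeric column per sample.
#' @param samples Tibble with columns `sample_id` and `group`, one row per
#'   sample column of `expr`, in any order.
#' @param truth Optional list of simulation ground truth (module membership,
#'   planted differential expression) attached verbatim.
#'
#' @return An object of class `expr_set`: a list with elements `expr`,
#'   `samples` and `truth`.
#' @export
expr_set <- function(expr, samples, truth = NULL) {
  expr <- as_tibble(expr)
  samples <- as_tibble(samples)
  assert_that(names(expr)[1] == "probe_id",
              "first column of `expr` must be `probe_id`")
  assert_that(all(c("sample_id", "group") %in% names(samples)),
              "`samples` needs columns `sample_id` and `group`")
  sample_ids <- names(expr)[-1]
  assert_that(!anyDuplicated(expr$probe_id),
              paste0("duplicate probe id: ",
                     expr$probe_id[duplicated(expr$probe_id)][1]))
  assert_that(!anyDuplicated(sample_ids), "duplicate sample ids in `expr`")
  assert_that(setequal(sample_ids, samples$sample_id),
              "sample columns of `expr` and `samples$sample_id` must match")
  missing_group <- samples$sample_id[is.na(samples$group)]
  assert_that(length(missing_group) == 0,
              paste0("sample without group: ", missing_group[1]))
  vals <- as.matrix(expr[, -1, drop = FALSE])
  assert_that(is.numeric(vals) || length(vals) == 0,
              "expression values must be numeric")
  assert_that(all(is.finite(vals)), "expression values must be finite")
  assert_that(all(vals >= 0), "expression values must be non-negative")
  samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
  structure(list(expr = expr, samples = samples, truth = truth),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d probes x %d samples\n",
              nrow(x$expr), nrow(x$samples)))
  grp <- table(x$samples$group)
  cat("groups:", paste(names(grp), grp, sep = ":", collapse = " "), "\n")
  if (!is.null(x$truth)) cat("carries simulation truth\n")
  invisible(x)
}

#' Extract the numeric probe-by-sample matrix of an expression set
#'
#' @param x An [expr_set].
#' @param log2 If `TRUE`, return `log2(value + 1)` (the scale used by the
#'   testing and network stages); default is the stored linear scale.
#' @return Numeric matrix with probe ids as rownames, sample ids as colnames.
#' @export
expr_matrix <- function(x, log2 = FALSE) {
  stopifnot(inherits(x, "expr_set"))
  m <- as.matrix(x$expr[, -1, drop = FALSE])
  rownames(m) <- x$expr$probe_id
  if (log2) m <- log2(m + 1)
  m
}

#' Sample-to-group assignment of an expression set
#'
#' @param x An [expr_set].
#' @return Named character vector mapping sample id to group name.
#' @export
sample_groups <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  setNames(as.character(x$samples$group), x$samples$sample_id)
}

#' Tidy an expression set into long format
#'
#' @param x An [expr_set].
#' @param ... Unused.
#' @return A tibble with columns `probe_id`, `sample_id`, `group`, `value`.
#' @method tidy expr_set
#' @export
tidy.expr_set <- function(x, ...) {
  tidyr::pivot_longer(x$expr, -"probe_id",
                      names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::select("probe_id", "sample_id", "group", "value")
}
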