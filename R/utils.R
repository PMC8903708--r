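#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats cor sd median quantile var p.adjust pt phyper pchisq
#'   fisher.test hclust cutree as.dist prcomp rnorm runif rbinom rexp rpois
#'   rlnorm setNames uniroot complete.cases
#' @importFrom utils head
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb global reproducibility.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Benjamini-Hochberg shorthand used across result tibbles.
bh_adjust <- function(p) p.adjust(p, method = "BH")

# WGCNA-style module colour sequence, assigned by decreasing module size.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue"
)

module_color_names <- function(n) {
  if (n <= length(MODULE_COLORS)) {
    MODULE_COLORS[seq_len(n)]
  } else {
    c(MODULE_COLORS, paste0("module", seq_len(n - length(MODULE_COLORS))))
  }
}
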