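# Independent brute-force oracles used across the test suite. These are kept
# deliberately naive (loops, enumeration) and separate from the package
# implementation paths they check.

# Triple-loop topological overlap.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# Naive circular ORF scan: read codons on (max_traversals + 2) concatenated
# copies, starts restricted to the first copy.
orf_oracle <- function(seq, max_traversals = 4, min_length_aa = 1) {
  L <- nchar(seq)
  big <- strrep(seq, max_traversals + 2)
  stops <- c("UAA", "UAG", "UGA")
  max_end <- (max_traversals + 1) * L
  rows <- list()
  for (p in 1:L) {
    if (substr(big, p, p + 2) != "AUG") next
    aa <- 0; q <- p; stop_codon <- "none"
    while (q + 2 <= max_end) {
      cod <- substr(big, q, q + 2)
      if (cod %in% stops) { stop_codon <- cod; break }
      aa <- aa + 1
      q <- q + 3
    }
    length_nt <- if (stop_codon == "none") 3 * aa else 3 * (aa + 1)
    if (aa >= min_length_aa) {
      rows[[length(rows) + 1]] <- data.frame(
        start = p, length_aa = aa,
        traversals = (p - 1 + length_nt - 1) %/% L,
        stop_codon = stop_codon
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out[order(-out$length_aa, out$start), , drop = FALSE]
}

random_circle_seq <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# Exact two-sided Fisher p by full enumeration of the hypergeometric support.
fisher_oracle <- function(i1, s1, i2, s2) {
  r1 <- i1 + s1; r2 <- i2 + s2; c1 <- i1 + i2; n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- sapply(support, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)))
  p_obs <- probs[support == i1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation.
hyper_tail_oracle <- function(overlap, set_size, universe_size, hit_count) {
  ks <- overlap:min(set_size, hit_count)
  sum(sapply(ks, function(k)
    exp(lchoose(set_size, k) + lchoose(universe_size - set_size,
                                       hit_count - k) -
          lchoose(universe_size, hit_count))))
}

# Literal-loop multi-class ReliefF on a samples-by-features matrix.
relieff_oracle <- function(x, labels, k) {
  n <- nrow(x); p <- ncol(x)
  rng_lo <- apply(x, 2, min); rng_hi <- apply(x, 2, max)
  span <- ifelse(rng_hi - rng_lo == 0, 1, rng_hi - rng_lo)
  xs <- x
  for (j in 1:p) xs[, j] <- (x[, j] - rng_lo[j]) / span[j]
  pri <- table(labels) / n
  w <- rep(0, p)
  for (i in 1:n) {
    d <- sapply(1:n, function(j) sqrt(sum((xs[i, ] - xs[j, ])^2)))
    ci <- labels[i]
    hits <- setdiff(which(labels == ci), i)
    hits <- hits[order(d[hits], hits)][1:min(k, length(hits))]
    for (f in 1:p) {
      w[f] <- w[f] - mean(abs(xs[i, f] - xs[hits, f])) / n
    }
    for (cc in setdiff(names(pri), ci)) {
      mis <- which(labels == cc)
      mis <- mis[order(d[mis], mis)][1:min(k, length(mis))]
      coef <- pri[[cc]] / (1 - pri[[ci]])
      for (f in 1:p) {
        w[f] <- w[f] + coef * mean(abs(xs[i, f] - xs[mis, f])) / n
      }
    }
  }
  w
}

# Hand log-rank: O, E, V accumulated over distinct event times.
logrank_oracle <- function(t1, e1, t2, e2) {
  d <- data.frame(time = c(t1, t2), event = c(e1, e2),
                  g = rep(c(1, 2), c(length(t1), length(t2))))
  times <- sort(unique(d$time[d$event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    n1 <- sum(d$time >= tt & d$g == 1); n2 <- sum(d$time >= tt & d$g == 2)
    d1 <- sum(d$time == tt & d$event == 1 & d$g == 1)
    dt <- sum(d$time == tt & d$event == 1)
    nt <- n1 + n2
    O <- O + d1
    E <- E + dt * n1 / nt
    if (nt > 1) V <- V + dt * (n1 / nt) * (n2 / nt) * (nt - dt) / (nt - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
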