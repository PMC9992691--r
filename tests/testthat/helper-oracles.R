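# Independent oracles used to check the implementation: brute-force window
# means, hypergeometric tail sums, set-partition enumeration, containment
# checks. These re-derive expected values from first principles and never
# call the code paths they verify.

# brute-force insulation: raw window mean at each bin, then log2 ratio
oracle_insulation <- function(counts, w) {
  n <- nrow(counts)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    acc <- 0; k <- 0
    for (r in (i - w):(i - 1)) {
      for (cc in (i + 1):(i + w)) {
        acc <- acc + counts[r, cc]; k <- k + 1
      }
    }
    raw[i] <- acc / k
  }
  log2(raw / mean(raw, na.rm = TRUE))
}

# exhaustive hypergeometric upper tail P(X >= a)
oracle_hyper_tail <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  ks <- seq(a, min(n, K))
  if (length(ks) == 0) return(0)
  sum(dhyper(ks, K, N - K, n))
}

# brute-force boundary containment
oracle_crosses <- function(bin1, bin2, boundary_bins) {
  any(boundary_bins > bin1 & boundary_bins < bin2)
}

# all set partitions of 1..n (Bell-number enumeration)
oracle_partitions <- function(n) {
  if (n == 1) return(list(c(1L)))
  smaller <- oracle_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    k <- max(p)
    for (g in seq_len(k + 1)) {
      out[[length(out) + 1L]] <- c(p, g)
    }
  }
  out
}

# exhaustive maximum modularity over all partitions of a small graph
oracle_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  parts <- oracle_partitions(n)
  best <- -Inf
  for (p in parts) {
    m <- igraph::modularity(g, p)
    if (m > best) best <- m
  }
  best
}

# ROSE cutoff oracle: slope-1 tangent on the scaled rank curve, by direct
# slope search on the sorted scaled signals
oracle_rose_cutoff <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  # the tangent point of slope 1 maximizes x - y on a convex curve
  s[which.max(x - y)]
}

# deterministic small contact matrix with two internal blocks
toy_two_block <- function(n = 40, split = 20, within = 10, between = 1) {
  m <- matrix(between, n, n)
  m[1:split, 1:split] <- within
  m[(split + 1):n, (split + 1):n] <- within
  m
}

# small genome + truth pair used across tests (10 Mb keeps HiChIP fast)
small_genome <- function(seed = 1, n_genes = 40) {
  generate_genome(1L, 10e6, n_genes, seed = seed)
}
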