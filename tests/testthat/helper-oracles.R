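# Independent reference implementations used as oracles.  Deliberately
# naive: double loops and exhaustive enumeration, no shared code with the
# package internals they check.

# NODF by direct double-loop over the published definition
naive_nodf <- function(a) {
  pair_sum <- function(m) {
    f <- rowSums(m)
    s <- 0
    n <- nrow(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      hi <- if (f[i] >= f[j]) i else j
      lo <- if (f[i] >= f[j]) j else i
      if (f[hi] > f[lo] && f[lo] > 0)
        s <- s + 100 * sum(m[hi, ] == 1 & m[lo, ] == 1) / f[lo]
    }
    s
  }
  n <- nrow(a); m <- ncol(a)
  (pair_sum(a) + pair_sum(t(a))) / (n * (n - 1) / 2 + m * (m - 1) / 2)
}

# Barber bipartite modularity by direct double loop
naive_modularity <- function(a, gi, gh) {
  F <- sum(a)
  k <- rowSums(a); d <- colSums(a)
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (gi[i] == gh[j]) s <- s + a[i, j] - k[i] * d[j] / F
  unname(s / F)
}

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (g in seq_len(maxid + 1L))
      rec(c(prefix, g), max(maxid, g))
  }
  rec(integer(0), 0L)
  out
}

# exhaustive maximum modularity over every partition of all nodes
exhaustive_best_M <- function(net) {
  a <- net$adjacency
  n <- nrow(a); m <- ncol(a)
  best <- -Inf
  for (g in all_partitions(n + m)) {
    v <- naive_modularity(a, g[seq_len(n)], g[n + seq_len(m)])
    if (v > best) best <- v
  }
  best
}

# quick constructor for unlabelled test matrices
mk_net <- function(...) bipartite_network(rbind(...))

# a random binary matrix guaranteed to have no empty rows/columns
random_filled_matrix <- function(n, m, fill = 0.3) {
  repeat {
    a <- matrix(as.integer(runif(n * m) < fill), n, m)
    if (all(rowSums(a) > 0) && all(colSums(a) > 0)) return(a)
  }
}
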