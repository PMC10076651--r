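# Shared fixtures and independent oracles used across test files.

# Small two-block, eight-node generator used for fast end-to-end checks.
small_generator <- function(seed, n = 600, rho = 0.2, bridge = 0.1) {
  generator_config(
    n_respondents = n,
    blocks = data.frame(label = c("a", "b"), size = c(4L, 4L),
                        rho = c(rho, rho), stringsAsFactors = FALSE),
    bridge_edges = data.frame(i = 1L, j = 5L, rho = bridge),
    item_levels = 4L,
    seed = seed
  )
}

# Weighted modularity computed from first principles (independent of igraph):
# Q = sum_c [ w_in(c)/m - (strength(c)/(2m))^2 ] on the absolute-weight graph.
modularity_manual <- function(w, membership) {
  a <- abs(w); diag(a) <- 0
  m <- sum(a) / 2
  strength <- rowSums(a)
  q <- 0
  for (cm in unique(membership)) {
    nodes <- which(membership == cm)
    w_in <- sum(a[nodes, nodes, drop = FALSE]) / 2
    q <- q + w_in / m - (sum(strength[nodes]) / (2 * m))^2
  }
  q
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_block) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (b in seq_len(next_block)) {
      rec(c(assign, b), next_block + (b == next_block))
    }
  }
  rec(integer(0), 1L)
  out
}

# Exhaustive-search maximum modularity over every partition (n <= 8 only).
brute_force_max_modularity <- function(w) {
  n <- nrow(w)
  stopifnot(n <= 8)
  best <- -Inf
  for (memb in all_partitions(n)) {
    q <- modularity_manual(w, memb)
    if (q > best) best <- q
  }
  best
}

# Symmetric zero-diagonal weight matrix from an edge list (i, j, w).
weights_from_edges <- function(p, edges) {
  w <- matrix(0, p, p)
  for (r in seq_len(nrow(edges))) {
    w[edges$i[r], edges$j[r]] <- edges$w[r]
    w[edges$j[r], edges$i[r]] <- edges$w[r]
  }
  colnames(w) <- rownames(w) <- paste0("V", seq_len(p))
  w
}

# Two 4-cliques joined by one weak edge: the canonical 2-community graph.
two_cliques <- function(strong = 1, weak = 0.1) {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- strong
  w[5:8, 5:8] <- strong
  diag(w) <- 0
  w[4, 5] <- w[5, 4] <- weak
  colnames(w) <- rownames(w) <- paste0("V", 1:8)
  w
}

edge_support <- function(w) {
  w[upper.tri(w)] != 0
}

skewness_sample <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}
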