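# Fixtures and independent oracles shared across the suite.

# Build an undirected network from a compact "a-b,b-c" edge string.
net_from_string <- function(s, directed = FALSE) {
  pairs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  as_network(
    data.frame(
      from = vapply(pairs, `[[`, character(1), 1),
      to = vapply(pairs, `[[`, character(1), 2)
    ),
    directed = directed
  )
}

triangle_net <- function() net_from_string("a-b,b-c,a-c")

# A fixed 12-node graph used for exhaustive-enumeration checks.
twelve_node_net <- function() {
  set.seed(1203)
  nodes <- paste0("n", sprintf("%02d", 1:12))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.3
  as_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
}

# Exhaustive oracle: statistics of the within-count over ALL k-subsets of
# `pool` (brute force; usable when choose(|pool|, k) is small).
exhaustive_within_stats <- function(net, pool, k, observed = NULL) {
  sets <- combn(pool, k)
  counts <- apply(sets, 2, function(g) count_edges_within(net, g))
  list(
    counts = counts,
    mean = mean(counts),
    sd = sd(counts),
    exceed_ge = if (!is.null(observed)) mean(counts >= observed) else NULL,
    exceed_le = if (!is.null(observed)) mean(counts <= observed) else NULL
  )
}

# Brute-force hypergeometric tail by enumerating all n-subsets of the
# background: P(X >= k) for draws from N genes of which K carry the term.
brute_hyper_tail <- function(N, K, n, k, tail = "enriched") {
  bg <- seq_len(N)
  annotated <- seq_len(K)
  draws <- combn(bg, n)
  xs <- apply(draws, 2, function(d) sum(d %in% annotated))
  if (tail == "enriched") mean(xs >= k) else mean(xs <= k)
}

# Small expression fixture: 3 genes x 3 conditions, one missing cell.
small_expr <- function() {
  tibble::tibble(
    gene = c("g1", "g2", "g3"),
    brain = c(2, 5, NA),
    eye = c(3, 0, 10),
    gut = c(5, 0, 5)
  )
}
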