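# Shared fixtures and independent brute-force oracles.  The oracles work
# directly on raw edge lists / p-vectors and never call the package's own
# degree or adjustment code paths.

# The documented toy layer: edges G1-G2, G1-G3, G1-G4, G2-G3, G5-G6
# (6 nodes).  Pathway {G1, G2, G3, G7} has k = 4 and di_P(G1) = 2.
toy_edges <- function() {
  rbind(c("G1", "G2"), c("G1", "G3"), c("G1", "G4"), c("G2", "G3"),
        c("G5", "G6"))
}
toy_layer <- function() network_layer("L1", toy_edges())

# Brute-force degree oracle: scans a raw two-column edge matrix.
oracle_degree <- function(edges, gene) {
  sum(edges[, 1] == gene | edges[, 2] == gene)
}
oracle_pathway_degree <- function(edges, gene, pathway) {
  others <- setdiff(pathway, gene)
  inc <- edges[edges[, 1] == gene | edges[, 2] == gene, , drop = FALSE]
  nbr <- ifelse(inc[, 1] == gene, inc[, 2], inc[, 1])
  sum(unique(nbr) %in% others)
}

# Independent Benjamini-Hochberg step-up oracle, written from the
# definition: sort ascending, multiply by n/i, enforce monotonicity from the
# largest rank down, clip at 1, restore input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Random simple undirected graph as a raw edge matrix over given node names.
random_edge_matrix <- function(nodes, p, seed) {
  set.seed(seed)
  n <- length(nodes)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
}

# A bundle configuration inside the criterion's operable regime
# (pathway sizes below sqrt(m), strong planting) used for end-to-end runs.
operable_config <- function(seed = 7) {
  simulation_config(pathway_size_range = c(8, 14),
                    planted_within_pathway_prob = 0.9,
                    seed = seed)
}
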