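# Independent reference implementations used to validate the package's
# fast paths. Deliberately written as plain, slow enumerations.

# Benjamini-Hochberg step-up, from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher p by explicit enumeration of the hypergeometric support
# with binomial-coefficient ratios (no dhyper).
fisher_oracle <- function(nf, n, Nf, N) {
  if (n == 0 || Nf == 0 || N == 0 || n == N || Nf == N) return(1)
  lo <- max(0, n + Nf - N)
  hi <- min(n, Nf)
  xs <- lo:hi
  pr <- choose(Nf, xs) * choose(N - Nf, n - xs) / choose(N, n)
  obs <- pr[nf - lo + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Brute-force core index: for each k, repeatedly delete nodes of degree < k
# within the surviving subgraph; a node's core index is the largest k it
# survives.
kcore_oracle <- function(nodes, edges) {
  deg_in <- function(alive) {
    keep <- edges$gene1 %in% alive & edges$gene2 %in% alive
    d <- table(factor(c(edges$gene1[keep], edges$gene2[keep]),
                      levels = alive))
    stats::setNames(as.integer(d), alive)
  }
  core <- stats::setNames(integer(length(nodes)), nodes)
  for (k in seq_len(length(nodes))) {
    alive <- nodes
    repeat {
      d <- deg_in(alive)
      drop <- alive[d < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
    }
    if (!length(alive)) break
    core[alive] <- k
  }
  core
}

# Build a coexpression_network directly from an adjacency matrix by
# presenting it as a "correlation" matrix of ones.
network_from_adjacency <- function(adj, condition = "") {
  diag(adj) <- 1
  build_network(adj, threshold = 0.999, condition = condition)
}

random_network <- function(n_nodes, p_edge) {
  adj <- matrix(0, n_nodes, n_nodes,
                dimnames = list(sprintf("n%02d", seq_len(n_nodes)),
                                sprintf("n%02d", seq_len(n_nodes))))
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p_edge]
  adj[on] <- 1
  adj <- adj + t(adj)
  network_from_adjacency(adj)
}
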