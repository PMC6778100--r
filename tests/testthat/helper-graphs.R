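# Graph fixtures built in code.

# Two hubs joined to each other, each with 3 private leaves (8 nodes, 7 edges).
two_hub_graph <- function() {
  adj <- matrix(0L, 8, 8)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7), c(2, 8))
  adj[edges] <- 1L
  adj + t(adj)
}

star_graph <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- 1L
  adj[2:n, 1] <- 1L
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  adj
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- 1L
  adj + t(adj)
}

# Two dense cliques bridged by one edge: high clustering, modular.
two_clique_bridge <- function(k = 10) {
  n <- 2 * k
  adj <- matrix(0L, n, n)
  adj[1:k, 1:k] <- 1L
  adj[(k + 1):n, (k + 1):n] <- 1L
  diag(adj) <- 0L
  adj[k, k + 1] <- 1L
  adj[k + 1, k] <- 1L
  adj
}

# Sparse ER periphery plus a 6-node clique core wired into it by 5 spokes per
# core node: a planted rich club whose core degrees sit at 10, so the
# one-tailed permutation p at its top degrees can clear Bonferroni even with
# a few hundred null networks.
planted_core_graph <- function(seed, n_periphery = 100, p_bg = 0.03,
                               core_size = 6, spokes = 5) {
  set.seed(seed)
  n <- n_periphery + core_size
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj[1:n_periphery, 1:n_periphery])
  bg <- matrix(0L, n_periphery, n_periphery)
  bg[up] <- rbinom(sum(up), 1L, p_bg)
  adj[1:n_periphery, 1:n_periphery] <- bg + t(bg)
  core <- (n_periphery + 1):n
  adj[core, core] <- 1L
  diag(adj) <- 0L
  for (v in core) {
    targets <- sample.int(n_periphery, spokes)
    adj[v, targets] <- 1L
    adj[targets, v] <- 1L
  }
  adj
}

# Size/density-matched ER control for planted_core_graph.
matched_er_graph <- function(seed, n = 106, n_edges = 195) {
  set.seed(seed)
  p <- n_edges / choose(n, 2)
  er_adjacency(n, p)
}
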