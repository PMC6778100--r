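# Independent brute-force oracles. These deliberately share no code with the
# package: triangles are enumerated over node triples, distances come from a
# hand-rolled BFS, assortativity from cor() on the directed edge list, and
# components from reachability growth on the adjacency matrix.

bf_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    t_i <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) t_i <- t_i + 1
      }
    }
    ci[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(ci)
}

bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] != 0)) {
          if (!visited[w]) { visited[w] <- TRUE; d[s, w] <- depth; nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
  }
  d
}

bf_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_shortest_paths(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

bf_assortativity <- function(adj) {
  deg <- rowSums(adj != 0)
  el <- which(adj != 0, arr.ind = TRUE)  # both orientations
  x <- deg[el[, 1]]; y <- deg[el[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Components of an edge list by reachability growth; returns list of sorted
# node vectors plus the max edge count per component.
bf_components <- function(pairs, n) {
  adj <- matrix(0L, n, n)
  adj[pairs] <- 1L
  adj[pairs[, c(2, 1), drop = FALSE]] <- 1L
  involved <- sort(unique(as.vector(pairs)))
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in involved) {
    if (seen[s]) next
    members <- s
    repeat {
      grown <- unique(c(members, which(rowSums(adj[, members, drop = FALSE]) > 0)))
      if (length(grown) == length(members)) break
      members <- grown
    }
    seen[members] <- TRUE
    sub <- adj[members, members, drop = FALSE]
    comps[[length(comps) + 1]] <- list(
      nodes = sort(members),
      extent = sum(sub) / 2
    )
  }
  comps
}

er_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- stats::rbinom(sum(up), 1L, p)
  adj + t(adj)
}

rand_symmetric <- function(n) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Raw data with exactly the requested mean and sd (oracle for the
# from-summary ANOVA).
vector_with_summary <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  x * sd + mean
}
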