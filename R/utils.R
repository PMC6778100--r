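# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. `seed = NULL` leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic derived seed for stream `index` of a master seed; stays inside
# the 32-bit signed integer range so set.seed() accepts it on any platform.
derive_seed <- function(seed, index) {
  s <- abs(as.double(seed)) %% 2147483647
  v <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483646
  as.integer(v) + 1L
}

# Upper-triangle node pairs (i < j) in row-major (i, j) lexicographic order;
# this order is the deterministic tie-break used throughout.
edge_index_pairs <- function(n) {
  stopifnot(n >= 2L)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

n_node_pairs <- function(n) n * (n - 1L) / 2

check_square_symmetric <- function(m, name = "matrix", tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  if (!is.numeric(m) && !is.logical(m)) {
    stop(name, " must be numeric or logical", call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol) {
    stop(name, " must be symmetric (tolerance ", format(tol), ")", call. = FALSE)
  }
  invisible(m)
}

# Symmetric matrix from an upper-triangle value vector in edge_index_pairs order.
matrix_from_upper <- function(values, n, diag_value = 0) {
  pairs <- edge_index_pairs(n)
  m <- matrix(diag_value, n, n)
  m[pairs] <- values
  m[pairs[, c(2L, 1L), drop = FALSE]] <- values
  diag(m) <- diag_value
  m
}

upper_values <- function(m) {
  m[edge_index_pairs(nrow(m))]
}

as_adjacency <- function(g, name = "graph") {
  check_square_symmetric(g, name = name)
  g <- (g != 0) * 1L
  diag(g) <- 0L
  g
}

adjacency_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}
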