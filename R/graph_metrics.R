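# Binary-graph topology: segregation (mean clustering coefficient),
# integration (global efficiency), resilience (degree assortativity),
# degree-preserving randomization, and rich-club curves with normalization
# against the randomized null. Graphs are 0/1 symmetric adjacency matrices
# with zero diagonal; all metrics are invariant under node relabeling.

#' Mean clustering coefficient
#'
#' Per node, C_i = 2 t_i / (k_i (k_i - 1)) where t_i counts triangles through
#' node i; nodes of degree < 2 contribute C_i = 0 (the Brain Connectivity
#' Toolbox convention). Returns the unweighted mean over all nodes.
#'
#' @param g Binary adjacency matrix, N >= 3.
#' @return Mean clustering coefficient in \[0, 1\].
#' @export
mean_clustering <- function(g) {
  adj <- as_adjacency(g)
  if (nrow(adj) < 3L) stop("need at least 3 nodes", call. = FALSE)
  ci <- igraph::transitivity(adjacency_to_igraph(adj), type = "local",
                             isolates = "zero")
  mean(ci)
}

#' Global efficiency
#'
#' E = 1 / (N (N - 1)) * sum over ordered pairs of 1 / d_ij with d_ij the
#' shortest-path length; unreachable pairs contribute 0, so disconnected
#' (e.g. sparsely thresholded) graphs are handled without error.
#'
#' @param g Binary adjacency matrix, N >= 2.
#' @return Global efficiency in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  adj <- as_adjacency(g)
  if (nrow(adj) < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (sum(adj) == 0L) return(0)
  igraph::global_efficiency(adjacency_to_igraph(adj))
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at the two ends of every edge,
#' each undirected edge counted in both orientations. Returns `NA` (an
#' explicit undefined sentinel, never a silent 0) when the endpoint-degree
#' variance is zero, as in any regular graph.
#'
#' @param g Binary adjacency matrix with >= 1 edge.
#' @return Assortativity coefficient in \[-1, 1\], or `NA` if undefined.
#' @export
assortativity <- function(g) {
  adj <- as_adjacency(g)
  if (sum(adj) == 0L) stop("assortativity is undefined on an edgeless graph",
                           call. = FALSE)
  r <- igraph::assortativity_degree(adjacency_to_igraph(adj))
  if (!is.finite(r)) NA_real_ else r
}

#' Degree-preserving randomization (Maslov-Sneppen rewiring)
#'
#' Attempts `swap_factor * E` double-edge swaps, rejecting any swap that
#' would create a self-loop or multi-edge. The degree sequence (hence size
#' and edge count) is preserved exactly while higher-order structure is
#' destroyed; this is the null model for rich-club normalization.
#'
#' @param g Binary adjacency matrix with >= 2 edges.
#' @param swap_factor Attempted swaps per edge, default 10.
#' @param seed Optional seed; output is deterministic given the seed.
#' @return Randomized binary adjacency matrix with the same degree sequence.
#' @export
degree_preserving_randomize <- function(g, swap_factor = 10, seed = NULL) {
  adj <- as_adjacency(g)
  e <- sum(adj) / 2L
  if (e < 2L) stop("need at least 2 edges to rewire", call. = FALSE)
  ig <- adjacency_to_igraph(adj)
  rg <- with_seed(seed, igraph::rewire(
    ig, igraph::keeping_degseq(loops = FALSE, niter = ceiling(swap_factor * e))
  ))
  out <- as.matrix(igraph::as_adjacency_matrix(rg, type = "both", sparse = FALSE))
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  if (identical(out, adj)) {
    warning("no rewiring occurred (graph may admit no valid swap)",
            call. = FALSE)
  }
  out
}

#' Rich-club coefficient curve
#'
#' For each degree level k, the subgraph induced by nodes of degree
#' strictly greater than k has N_k nodes and E_k edges;
#' Phi(k) = 2 E_k / (N_k (N_k - 1)) is the edge density among those nodes.
#' Phi(k) is undefined (`NA`) when fewer than 2 nodes exceed k. The curve is
#' evaluated on k = 1 .. max degree - 1.
#'
#' @param g Binary adjacency matrix, N >= 3.
#' @return `data.frame` (class `rich_club_curve`) with columns `k`,
#'   `n_nodes`, `n_edges`, `phi`.
#' @export
rich_club_curve <- function(g) {
  adj <- as_adjacency(g)
  n <- nrow(adj)
  if (n < 3L) stop("need at least 3 nodes", call. = FALSE)
  deg <- rowSums(adj)
  kmax <- max(deg)
  if (kmax < 2L) {
    ks <- integer(0L)
  } else {
    ks <- seq_len(kmax - 1L)
  }
  pairs <- edge_index_pairs(n)
  on_edge <- adj[pairs] != 0
  min_deg <- pmin(deg[pairs[, 1L]], deg[pairs[, 2L]])[on_edge]
  res <- data.frame(k = ks,
                    n_nodes = vapply(ks, function(k) sum(deg > k), 0),
                    n_edges = vapply(ks, function(k) sum(min_deg > k), 0))
  res$phi <- ifelse(res$n_nodes >= 2L,
                    2 * res$n_edges / (res$n_nodes * (res$n_nodes - 1)),
                    NA_real_)
  class(res) <- c("rich_club_curve", "data.frame")
  res
}

#' Normalized rich-club curve with regime detection
#'
#' Computes Phi(k), divides by the mean Phi over `R` degree-preserving
#' randomizations to obtain Phi_norm(k), and assigns each k a one-tailed
#' permutation p-value p(k) = (1 + #\{Phi_rand(k) >= Phi(k)\}) / (1 + R).
#' The rich-club regime is the maximal contiguous k range where
#' Phi_norm(k) > 1 and p(k) is below `alpha` after Bonferroni correction
#' over the evaluated k levels.
#'
#' @param g Binary adjacency matrix.
#' @param R Number of random networks, default 1000 (values below 100 give
#'   an unstable null and trigger a warning).
#' @param alpha Significance level before Bonferroni correction.
#' @param swap_factor Rewiring effort per random network.
#' @param seed Optional master seed for the randomization stream.
#' @return Object of class `rich_club_norm`: a list with `curve` (data.frame
#'   with k, phi, phi_rand_mean, phi_norm, p, significant, regime), `R`,
#'   `alpha`, `n_evaluated`.
#' @export
normalized_rich_club <- function(g, R = 1000L, alpha = 0.05, swap_factor = 10,
                                 seed = NULL) {
  if (R < 100L) {
    warning("R < 100 random networks gives an unstable null", call. = FALSE)
  }
  adj <- as_adjacency(g)
  obs <- rich_club_curve(adj)
  kk <- nrow(obs)
  phi_rand <- matrix(NA_real_, R, kk)
  for (r in seq_len(R)) {
    rs <- if (is.null(seed)) NULL else derive_seed(seed, r)
    rnd <- degree_preserving_randomize(adj, swap_factor = swap_factor,
                                       seed = rs)
    phi_rand[r, ] <- rich_club_curve(rnd)$phi
  }
  defined <- !is.na(obs$phi)
  phi_rand_mean <- colMeans(phi_rand)
  phi_norm <- obs$phi / phi_rand_mean
  p <- rep(NA_real_, kk)
  for (j in which(defined)) {
    p[j] <- (1 + sum(phi_rand[, j] >= obs$phi[j])) / (1 + R)
  }
  m <- sum(defined)
  significant <- defined & !is.na(phi_norm) & phi_norm > 1 & p < alpha / max(m, 1L)
  regime <- rep(FALSE, kk)
  if (any(significant)) {
    runs <- rle(significant)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sig_runs <- which(runs$values)
    best <- sig_runs[which.max(runs$lengths[sig_runs])]
    regime[starts[best]:ends[best]] <- TRUE
  }
  curve <- data.frame(k = obs$k, n_nodes = obs$n_nodes, phi = obs$phi,
                      phi_rand_mean = phi_rand_mean, phi_norm = phi_norm,
                      p = p, significant = significant, regime = regime)
  structure(list(curve = curve, R = R, alpha = alpha, n_evaluated = m),
            class = "rich_club_norm")
}

#' @export
print.rich_club_norm <- function(x, ...) {
  cat("Normalized rich-club curve (", x$R, " degree-preserving nulls)\n",
      sep = "")
  cat("Evaluated k levels:", x$n_evaluated,
      "| Bonferroni alpha:", signif(x$alpha / max(x$n_evaluated, 1L), 3L), "\n")
  if (any(x$curve$regime)) {
    ks <- range(x$curve$k[x$curve$regime])
    cat("Rich-club regime: k =", ks[1L], "..", ks[2L], "\n")
  } else {
    cat("Rich-club regime: none detected\n")
  }
  invisible(x)
}
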