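# Network-based statistic: edge-wise two-sample t statistics with covariate
# residualization, suprathreshold component extraction, and max-component
# permutation family-wise error control. The component statistic is extent
# (edge count). Internally subjects' matrices are flattened to a
# subjects x edges value matrix on the analyzable (masked) edge set so the
# permutation loop is vectorized over edges.

# Flatten a cohort of matrices to a subjects x edges matrix on the masked
# upper-triangle edge set; attribute "pairs" carries the (i, j) node pairs.
edge_value_matrix <- function(matrices, mask = NULL) {
  n <- nrow(matrices[[1L]])
  pairs <- edge_index_pairs(n)
  if (!is.null(mask)) {
    keep <- mask[pairs]
    pairs <- pairs[keep, , drop = FALSE]
  }
  v <- t(vapply(matrices, function(m) m[pairs], numeric(nrow(pairs))))
  attr(v, "pairs") <- pairs
  attr(v, "n_nodes") <- n
  v
}

# Column-wise pooled-variance two-sample t over a subjects x edges matrix.
# Constant (zero-variance) columns with zero mean difference give t = 0;
# zero variance with a nonzero difference gives signed Inf.
col_tstats <- function(v, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- v[idx1, , drop = FALSE]; x2 <- v[idx2, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1 * x1) - n1 * m1 * m1
  ss2 <- colSums(x2 * x2) - n2 * m2 * m2
  sp2 <- pmax(ss1 + ss2, 0) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- d / se
  zero <- se == 0
  if (any(zero)) t[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  t
}

# Directional exceedance of the primary threshold.
edges_passing <- function(t, threshold, direction) {
  switch(direction,
         greater = t > threshold,
         less = t < -threshold,
         two.sided = abs(t) > threshold,
         stop("direction must be 'greater', 'less' or 'two.sided'",
              call. = FALSE))
}

# Union-find over an edge list; returns max component extent (edge count).
max_component_extent <- function(pairs) {
  ne <- nrow(pairs)
  if (ne <= 1L) return(ne)
  nodes <- unique(as.vector(pairs))
  parent <- seq_along(nodes)
  idx <- match(as.vector(pairs), nodes)
  a <- idx[seq_len(ne)]; b <- idx[ne + seq_len(ne)]
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(ne)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  max(tabulate(roots[a], nbins = length(nodes)) +
        tabulate(roots[b], nbins = length(nodes))) / 2
}

#' Edge-wise two-sample t statistics
#'
#' Residualizes every masked edge on the covariates across subjects, then
#' computes the pooled-variance two-sample t per edge, signed as group 1
#' minus group 2. Zero-variance edges are recorded as t = 0 and counted in
#' attribute `n_zero_variance`.
#'
#' @param matrices Named list of connectivity matrices (negative-edge masking
#'   via the reference mask is expected upstream).
#' @param labels Character/factor vector of group labels per subject.
#' @param group1,group2 The two labels to contrast.
#' @param covariates Optional numeric covariate matrix (rows aligned to
#'   `matrices`).
#' @param mask Optional analyzable-edge mask.
#' @return Symmetric N x N matrix of t values (class `edge_stats`), zero
#'   outside the mask.
#' @export
edgewise_tstats <- function(matrices, labels, group1, group2,
                            covariates = NULL, mask = NULL) {
  stopifnot(length(labels) == length(matrices))
  sel <- labels %in% c(group1, group2)
  matrices <- matrices[sel]
  labels <- labels[sel]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[sel, , drop = FALSE]
  }
  idx1 <- which(labels == group1); idx2 <- which(labels == group2)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  v <- edge_value_matrix(matrices, mask)
  pairs <- attr(v, "pairs")
  n <- attr(v, "n_nodes")
  if (!is.null(covariates)) v <- apply(v, 2L, residualize, covariates)
  t <- col_tstats(v, idx1, idx2)
  out <- matrix(0, n, n)
  out[pairs] <- t
  out[pairs[, c(2L, 1L), drop = FALSE]] <- t
  col_var <- colMeans(v^2) - colMeans(v)^2
  attr(out, "n_zero_variance") <- sum(col_var <= 1e-300)
  class(out) <- c("edge_stats", class(out))
  out
}

#' Suprathreshold components of an edge-statistic matrix
#'
#' Keeps the edges whose statistic exceeds the threshold in the requested
#' direction and extracts the connected components of the edge-induced
#' graph. Components are ordered by decreasing extent (edge count), ties by
#' smallest node id.
#'
#' @param stats Symmetric edge-statistic matrix (e.g. [edgewise_tstats()]).
#' @param threshold Primary component-forming threshold on the statistic.
#' @param direction "greater" (t > thr), "less" (t < -thr) or "two.sided"
#'   (|t| > thr).
#' @return List of components, each a list with `nodes`, `edges` (two-column
#'   matrix) and `extent`; empty list when no edge passes.
#' @export
suprathreshold_components <- function(stats, threshold,
                                      direction = "two.sided") {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  m <- unclass(stats)
  check_square_symmetric(m, "edge-statistic matrix")
  n <- nrow(m)
  pairs <- edge_index_pairs(n)
  pass <- edges_passing(m[pairs], threshold, direction)
  pairs <- pairs[pass, , drop = FALSE]
  if (nrow(pairs) == 0L) return(list())
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  comp <- igraph::components(g)
  comps <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    in_comp <- comp$membership[pairs[, 1L]] == cid
    edges <- pairs[in_comp, , drop = FALSE]
    if (nrow(edges) == 0L) next  # isolated vertices from graph_from_edgelist
    comps[[length(comps) + 1L]] <- list(
      nodes = sort(unique(as.vector(edges))),
      edges = edges,
      extent = nrow(edges)
    )
  }
  ord <- order(-vapply(comps, `[[`, 0L, "extent"),
               vapply(comps, function(cm) min(cm$nodes), 0L))
  comps[ord]
}

#' Network-based statistic group test
#'
#' The three NBS steps with permutation FWER control: (1) edge-wise
#' two-sample t statistics on covariate-residualized, reference-masked
#' connectivity values; (2) primary component-forming threshold, the t
#' quantile at `p_primary` for the contrast's degrees of freedom
#' (n - 2 - #covariates); (3) connected components of the suprathreshold
#' edges. Steps 1-3 are repeated for `n_perm` random permutations of the
#' group labels (covariates residualized once, before permuting), recording
#' the maximum component extent to form the null distribution of largest
#' component size. Each observed component gets
#' FWER p = (1 + #\{max_perm >= extent\}) / (1 + n_perm).
#'
#' @param matrices Named list of connectivity matrices.
#' @param labels Group label per subject.
#' @param group1,group2 Labels to contrast (t signed group1 - group2).
#' @param covariates Optional numeric covariate matrix.
#' @param mask Optional analyzable-edge mask (reference positive mask and/or
#'   distance mask).
#' @param p_primary Primary threshold as a one-sided tail probability,
#'   in (0, 0.5); default 0.005.
#' @param n_perm Number of permutations, >= 100; default 10000.
#' @param direction "less" tests for decreased connectivity in group 1
#'   (default), "greater" the opposite, "two.sided" both.
#' @param seed Optional seed governing the whole permutation stream.
#' @return Object of class `nbs_result`: components (with per-component
#'   `fwer_p`), `t_threshold`, `df`, `null_max_extent`, `n_perm`,
#'   `direction`.
#' @export
nbs_test <- function(matrices, labels, group1, group2, covariates = NULL,
                     mask = NULL, p_primary = 0.005, n_perm = 10000L,
                     direction = "less", seed = NULL) {
  if (p_primary <= 0 || p_primary >= 0.5) {
    stop("p_primary must lie in (0, 0.5)", call. = FALSE)
  }
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  stopifnot(length(labels) == length(matrices))
  sel <- labels %in% c(group1, group2)
  matrices <- matrices[sel]
  labels <- labels[sel]
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[sel, , drop = FALSE]
  }
  idx1 <- which(labels == group1); idx2 <- which(labels == group2)
  n1 <- length(idx1); n2 <- length(idx2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  v <- edge_value_matrix(matrices, mask)
  pairs <- attr(v, "pairs")
  n_nodes <- attr(v, "n_nodes")
  if (!is.null(covariates)) v <- apply(v, 2L, residualize, covariates)
  q_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  df <- n1 + n2 - 2L - q_cov
  t_threshold <- stats::qt(1 - p_primary, df)
  t_obs <- col_tstats(v, idx1, idx2)
  obs_pass <- edges_passing(t_obs, t_threshold, direction)
  comps <- if (any(obs_pass)) {
    tm <- matrix(0, n_nodes, n_nodes)
    tm[pairs] <- t_obs
    tm[pairs[, c(2L, 1L), drop = FALSE]] <- t_obs
    suprathreshold_components(tm, t_threshold, direction)
  } else {
    list()
  }
  n <- n1 + n2
  null_max <- with_seed(seed, {
    out <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      p1 <- sample.int(n, n1)
      tb <- col_tstats(v, p1, setdiff(seq_len(n), p1))
      pass <- edges_passing(tb, t_threshold, direction)
      out[b] <- if (!any(pass)) 0L else
        max_component_extent(pairs[pass, , drop = FALSE])
    }
    out
  })
  for (ci in seq_along(comps)) {
    comps[[ci]]$fwer_p <-
      (1 + sum(null_max >= comps[[ci]]$extent)) / (1 + n_perm)
  }
  structure(list(
    components = comps, t_threshold = t_threshold, df = df,
    p_primary = p_primary, null_max_extent = null_max, n_perm = n_perm,
    direction = direction, groups = c(group1, group2),
    n_subjects = c(n1, n2)
  ), class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistic:", x$groups[1L], "vs", x$groups[2L],
      sprintf("(n = %d/%d, direction = %s)\n", x$n_subjects[1L],
              x$n_subjects[2L], x$direction))
  cat(sprintf("Primary threshold: |t| > %.3f (p = %g, df = %d), %d permutations\n",
              x$t_threshold, x$p_primary, x$df, x$n_perm))
  if (length(x$components) == 0L) {
    cat("No suprathreshold components.\n")
  } else {
    for (i in seq_along(x$components)) {
      cm <- x$components[[i]]
      cat(sprintf("Component %d: %d nodes, %d edges, FWER p = %.4g\n",
                  i, length(cm$nodes), cm$extent, cm$fwer_p))
    }
  }
  invisible(x)
}

#' @export
summary.nbs_result <- function(object, ...) {
  data.frame(
    component = seq_along(object$components),
    n_nodes = vapply(object$components, function(cm) length(cm$nodes), 0L),
    extent = vapply(object$components, `[[`, 0L, "extent"),
    fwer_p = vapply(object$components, `[[`, 0, "fwer_p")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
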