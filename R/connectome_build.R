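# Connectome construction: correlation -> optional Fisher z -> covariate
# residualization -> reference positive masking -> distance exclusion ->
# proportional density thresholding. All matrices are symmetric with a zero
# diagonal; node order is the atlas row order throughout.

#' Pairwise correlation matrix of a regional time series
#'
#' Pearson correlations between all region pairs, diagonal zeroed. With
#' `fisher_z = TRUE` the entries are variance-stabilized as atanh(r), with r
#' clipped to +/-(1 - 1e-12) so perfectly collinear pairs stay finite.
#'
#' @param ts Numeric T x N matrix (T >= 10), no constant columns.
#' @param fisher_z Apply the Fisher z-transform entrywise.
#' @return Symmetric N x N matrix, zero diagonal, with attribute
#'   `scale` = "pearson" or "fisher_z".
#' @export
correlation_matrix <- function(ts, fisher_z = FALSE) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 10L) {
    stop("need at least 10 time points for correlations", call. = FALSE)
  }
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(ts)
    bad <- which(sds == 0)
    stop("constant time series in ROI column ",
         if (is.null(nm)) bad[1L] else nm[bad[1L]], call. = FALSE)
  }
  r <- stats::cor(ts)
  if (fisher_z) {
    r <- atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
  }
  diag(r) <- 0
  r <- (r + t(r)) / 2
  attr(r, "scale") <- if (fisher_z) "fisher_z" else "pearson"
  r
}

#' Short-distance edge exclusion mask
#'
#' Marks as analyzable only the node pairs whose Euclidean distance is at
#' least `threshold_mm`; pairs strictly closer are excluded to avoid shared
#' signal between nearby regions. A pair at exactly the threshold is kept.
#'
#' @param atlas Atlas `data.frame` with x, y, z in mm.
#' @param threshold_mm Exclusion distance, default 20 mm.
#' @return Logical N x N symmetric mask, diagonal FALSE.
#' @export
distance_mask <- function(atlas, threshold_mm = 20) {
  d <- as.matrix(stats::dist(as.matrix(atlas[, c("x", "y", "z")])))
  mask <- d >= threshold_mm
  diag(mask) <- FALSE
  dimnames(mask) <- NULL
  mask
}

#' Healthy-reference positive-edge mask
#'
#' Averages the control-group connectivity matrices, zeroes negative entries,
#' and retains the strongest edges down to the requested density (fraction of
#' all N(N-1)/2 node pairs, rounded). Ties on equal weight are broken by
#' (i, j) node-index order. Only strictly positive average edges are ever
#' retained; if fewer exist than requested, all of them are kept with a
#' warning and the achieved density is recorded in attribute
#' `density_achieved`.
#'
#' @param hc_matrices List of >= 2 connectivity matrices on the same node set.
#' @param density Target edge fraction in (0, 1], default 0.45.
#' @return Logical N x N symmetric mask of retained edges.
#' @export
reference_positive_mask <- function(hc_matrices, density = 0.45) {
  if (!is.list(hc_matrices) || length(hc_matrices) < 2L) {
    stop("need at least 2 reference (control) matrices", call. = FALSE)
  }
  if (density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(hc_matrices[[1L]])
  for (m in hc_matrices) {
    check_square_symmetric(m, "reference matrix")
    if (nrow(m) != n) stop("reference matrices differ in size", call. = FALSE)
  }
  avg <- Reduce(`+`, hc_matrices) / length(hc_matrices)
  avg[avg < 0] <- 0
  pairs <- edge_index_pairs(n)
  w <- avg[pairs]
  n_target <- round(density * n_node_pairs(n))
  pos <- which(w > 0)
  if (length(pos) < n_target) {
    warning("only ", length(pos), " positive reference edges available for ",
            n_target, " requested; keeping all positive edges", call. = FALSE)
    keep <- pos
  } else {
    ord <- pos[order(-w[pos], pairs[pos, 1L], pairs[pos, 2L])]
    keep <- ord[seq_len(n_target)]
  }
  mask <- matrix(FALSE, n, n)
  mask[pairs[keep, , drop = FALSE]] <- TRUE
  mask <- mask | t(mask)
  attr(mask, "density_achieved") <- length(keep) / n_node_pairs(n)
  mask
}

#' Regress covariates out of connectivity matrices
#'
#' Per edge, ordinary least squares of the edge value on an intercept plus
#' the (column-centered) covariates across subjects; the output is residual
#' plus fitted intercept, which preserves the grand mean of every edge. With
#' no covariates this is the identity. Covariates exactly orthogonal to an
#' edge leave that edge unchanged.
#'
#' @param matrices List of connectivity matrices, one per subject.
#' @param covariates Numeric matrix/data.frame (subjects x covariates), or
#'   `NULL`/zero columns for the identity. Categorical covariates must be
#'   encoded numerically (e.g. via [stats::model.matrix()]) beforehand.
#' @return List of adjusted matrices, same shape and names as the input.
#' @export
regress_covariates <- function(matrices, covariates = NULL) {
  s <- length(matrices)
  if (s < 2L) stop("need at least 2 subjects", call. = FALSE)
  n <- nrow(matrices[[1L]])
  for (m in matrices) check_square_symmetric(m, "connectivity matrix")
  if (is.null(covariates) || NCOL(covariates) == 0L) return(matrices)
  x <- as.matrix(covariates)
  if (!is.numeric(x)) {
    stop("covariates must be numeric; encode factors with model.matrix()",
         call. = FALSE)
  }
  if (nrow(x) != s) {
    stop("covariate rows (", nrow(x), ") != number of subjects (", s, ")",
         call. = FALSE)
  }
  if (s < ncol(x) + 3L) {
    stop("need at least 2 more subjects than model parameters", call. = FALSE)
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  design <- cbind(intercept = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("covariate design is rank deficient (collinear: ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  pairs <- edge_index_pairs(n)
  y <- t(vapply(matrices, function(m) m[pairs], numeric(nrow(pairs))))
  beta <- qr.coef(qrd, y)
  fitted_int <- beta[1L, ]  # intercept = grand mean (centered design)
  resid <- y - design %*% beta
  out <- lapply(seq_len(s), function(i) {
    matrix_from_upper(resid[i, ] + fitted_int, n)
  })
  names(out) <- names(matrices)
  out
}

#' Proportional density threshold to a binary graph
#'
#' Retains the floor(density * N(N-1)/2) strongest candidate edges and
#' binarizes. Candidates are the strictly positive entries inside `mask`
#' (only positive correlations are analyzed); equal weights are broken by
#' (i, j) node-index order for bit-reproducibility. If fewer candidates than
#' requested exist, all are kept with a warning and the achieved density is
#' recorded.
#'
#' @param matrix Symmetric connectivity matrix, zero diagonal.
#' @param density Target edge fraction in (0, 1].
#' @param mask Optional logical N x N mask of analyzable edges (e.g. the
#'   intersection of [distance_mask()] and [reference_positive_mask()]).
#' @return Binary 0/1 adjacency matrix with attribute `density_achieved`.
#' @export
proportional_threshold <- function(matrix, density, mask = NULL) {
  check_square_symmetric(matrix, "connectivity matrix")
  if (density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(matrix)
  pairs <- edge_index_pairs(n)
  w <- matrix[pairs]
  ok <- w > 0
  if (!is.null(mask)) {
    check_square_symmetric(mask * 1, "mask")
    ok <- ok & mask[pairs]
  }
  n_target <- floor(density * n_node_pairs(n))
  cand <- which(ok)
  if (length(cand) < n_target) {
    warning("only ", length(cand), " positive masked edges available for ",
            n_target, " requested; achieved density ",
            signif(length(cand) / n_node_pairs(n), 3L), call. = FALSE)
    keep <- cand
  } else {
    ord <- cand[order(-w[cand], pairs[cand, 1L], pairs[cand, 2L])]
    keep <- ord[seq_len(n_target)]
  }
  adj <- matrix(0L, n, n)
  adj[pairs[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  attr(adj, "density_achieved") <- length(keep) / n_node_pairs(n)
  adj
}

#' Group-average binary graph at a target density
#'
#' Averages a group's connectivity matrices, zeroes negative entries, and
#' applies [proportional_threshold()] -- the construction used for
#' group-level rich-club analysis (default density 7% of the strongest
#' positive connections).
#'
#' @param matrices List of the group's connectivity matrices.
#' @param density Target edge fraction, default 0.07.
#' @param mask Optional analyzable-edge mask.
#' @return Binary adjacency matrix.
#' @export
group_average_graph <- function(matrices, density = 0.07, mask = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  avg <- Reduce(`+`, matrices) / length(matrices)
  avg[avg < 0] <- 0
  proportional_threshold(avg, density, mask)
}
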