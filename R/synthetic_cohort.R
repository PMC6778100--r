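# Synthetic cohort generation: atlases, block-structured group covariances
# with planted edge effects, and per-subject regional time series. This module
# emulates the statistical structure the downstream analyses assume (community
# structure in the population covariance, group differences confined to known
# edge sets) without any hemodynamic forward modelling.

#' Cohort configuration for the synthetic generator
#'
#' Bundles and validates every knob of the synthetic-cohort generator: the
#' node count, the block (community) structure of the population correlation
#' matrix, the groups with their sizes, and an optional planted effect -- an
#' additive correlation offset `delta` applied to `planted_edges` in
#' `effect_group` only.
#'
#' @param n_rois Number of regions (nodes), at least 3.
#' @param n_modules Number of equally sized covariance communities the nodes
#'   are split into (contiguous blocks).
#' @param within_r Target Pearson correlation between nodes in the same
#'   community.
#' @param between_r Target Pearson correlation between nodes in different
#'   communities.
#' @param groups Named integer vector of subjects per group, e.g.
#'   `c(hc = 20, sa = 16)`.
#' @param planted_edges Two-column integer matrix of node pairs (1-based)
#'   receiving the planted effect, or `NULL` for none.
#' @param delta Additive correlation offset applied to `planted_edges` in
#'   `effect_group`.
#' @param effect_group Name of the group carrying the planted effect; must be
#'   one of `names(groups)` when `delta != 0`.
#' @param n_timepoints Time points per subject (T). Values below 10 are
#'   rejected at sampling time; T > n_rois is recommended for stable
#'   correlation estimates.
#' @param noise_sd Standard deviation of independent Gaussian observation
#'   noise added on top of the multivariate-normal signal.
#' @param seed Master seed; every random draw in the generator is derived
#'   from it deterministically.
#'
#' @return A list of class `cohort_config`.
#' @seealso [sample_cohort()], [build_group_covariance()]
#' @export
cohort_config <- function(n_rois, n_modules = 1L, within_r = 0.3,
                          between_r = 0.1, groups = c(g1 = 10L, g2 = 10L),
                          planted_edges = NULL, delta = 0,
                          effect_group = NULL, n_timepoints = 200L,
                          noise_sd = 0, seed = 1L) {
  stopifnot(n_rois >= 3L, n_modules >= 1L, n_modules <= n_rois,
            noise_sd >= 0, length(groups) >= 1L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector of subject counts", call. = FALSE)
  }
  if (abs(within_r) >= 1 || abs(between_r) >= 1) {
    stop("within_r and between_r must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2L ||
        any(planted_edges < 1L) || any(planted_edges > n_rois) ||
        any(planted_edges[, 1L] == planted_edges[, 2L])) {
      stop("planted_edges must be a two-column matrix of distinct node ",
           "indices in 1..n_rois", call. = FALSE)
    }
    # canonical (i < j) orientation
    planted_edges <- t(apply(planted_edges, 1L, sort))
  }
  if (delta != 0) {
    if (is.null(effect_group) || !effect_group %in% names(groups)) {
      stop("effect_group must name one of the groups when delta != 0",
           call. = FALSE)
    }
    if (abs(within_r + delta) >= 1 || abs(between_r + delta) >= 1) {
      stop("delta pushes a planted correlation outside (-1, 1)", call. = FALSE)
    }
  }
  structure(list(
    n_rois = as.integer(n_rois), n_modules = as.integer(n_modules),
    within_r = within_r, between_r = between_r,
    groups = stats::setNames(as.integer(groups), names(groups)),
    planted_edges = planted_edges, delta = delta,
    effect_group = effect_group,
    n_timepoints = as.integer(n_timepoints), noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic ROI atlas
#'
#' Places `n_rois` points inside a brain-sized ellipsoid (semi-axes 70, 85,
#' 60 mm) by rejection sampling with a minimum pairwise separation of 8 mm,
#' mimicking the geometry of a volumetric parcellation so that the
#' short-distance edge exclusion has something to exclude.
#'
#' @param n_rois Number of regions, at least 3.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @param min_separation_mm Minimum pairwise distance between region centres.
#'
#' @return A `data.frame` with columns `roi_id`, `x`, `y`, `z` (mm) and
#'   `label`; row order defines the node index.
#' @export
#' @examples
#' atlas <- generate_atlas(10, seed = 1)
#' min(dist(atlas[, c("x", "y", "z")])) >= 8
generate_atlas <- function(n_rois, seed = 1L, min_separation_mm = 8) {
  stopifnot(n_rois >= 3L)
  semi <- c(70, 85, 60)
  with_seed(seed, {
    coords <- matrix(NA_real_, n_rois, 3L)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 20000L * n_rois
    while (placed < n_rois) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n_rois, " regions at ", min_separation_mm,
             " mm separation; try fewer ROIs", call. = FALSE)
      }
      p <- stats::runif(3L, -1, 1) * semi
      if (sum((p / semi)^2) > 1) next
      if (placed > 0L) {
        d2 <- colSums((t(coords[seq_len(placed), , drop = FALSE]) - p)^2)
        if (min(d2) < min_separation_mm^2) next
      }
      placed <- placed + 1L
      coords[placed, ] <- p
    }
    data.frame(
      roi_id = seq_len(n_rois),
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
      label = sprintf("ROI_%03d", seq_len(n_rois)),
      stringsAsFactors = FALSE
    )
  })
}

# Contiguous, nearly equal community assignment of nodes to modules.
module_assignment <- function(n_rois, n_modules) {
  sort(rep_len(seq_len(n_modules), n_rois))
}

#' Population correlation matrix for one group
#'
#' Constructs the block-structured population correlation matrix implied by a
#' [cohort_config()]: `within_r` inside communities, `between_r` elsewhere,
#' plus `delta` on the planted edges when `group` is the effect group. The
#' result is repaired to positive definiteness by flooring eigenvalues at
#' 1e-6 and rescaling to unit diagonal; realized correlations can therefore
#' deviate slightly from the nominal block values when the repair binds.
#'
#' @param config A [cohort_config()].
#' @param group Group name the matrix is for.
#' @return Symmetric positive-definite correlation matrix (unit diagonal).
#' @export
build_group_covariance <- function(config, group) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$groups)) {
    stop("unknown group: ", group, call. = FALSE)
  }
  n <- config$n_rois
  mod <- module_assignment(n, config$n_modules)
  sigma <- matrix(config$between_r, n, n)
  same <- outer(mod, mod, "==")
  sigma[same] <- config$within_r
  if (!is.null(config$planted_edges) && config$delta != 0 &&
      identical(group, config$effect_group)) {
    pe <- config$planted_edges
    sigma[pe] <- sigma[pe] + config$delta
    sigma[pe[, c(2L, 1L), drop = FALSE]] <- sigma[pe]
  }
  diag(sigma) <- 1
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    sigma <- stats::cov2cor(sigma)
    sigma <- (sigma + t(sigma)) / 2
  }
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("group covariance is not repairable to positive definiteness",
         call. = FALSE)
  }
  sigma
}

#' Sample a synthetic cohort of regional time series
#'
#' Draws each subject's T x N time-series matrix from a zero-mean
#' multivariate normal with the subject's group covariance, plus independent
#' N(0, `noise_sd`^2) observation noise. Per-subject seeds are derived
#' deterministically from `config$seed` and the subject index, so extending a
#' cohort with more subjects never reshuffles existing ones. Covariates are
#' sampled from fixed, documented distributions: age ~ Uniform(20, 55),
#' gender ~ Bernoulli(0.5) coded 0/1, site assigned round-robin over two
#' sites.
#'
#' @param config A [cohort_config()].
#' @return A list with `timeseries` (named list of T x N matrices) and
#'   `subjects` (data.frame: subject_id, group, age, gender, site).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_timepoints < 10L) {
    stop("n_timepoints must be at least 10; correlations are meaningless ",
         "below that", call. = FALSE)
  }
  sigmas <- lapply(names(config$groups), function(g) {
    build_group_covariance(config, g)
  })
  names(sigmas) <- names(config$groups)
  n_total <- sum(config$groups)
  group_of <- rep(names(config$groups), config$groups)
  ts <- vector("list", n_total)
  ids <- sprintf("sub-%03d", seq_len(n_total))
  age <- numeric(n_total)
  gender <- integer(n_total)
  for (i in seq_len(n_total)) {
    ts[[i]] <- with_seed(derive_seed(config$seed, i), {
      x <- MASS::mvrnorm(config$n_timepoints, mu = rep(0, config$n_rois),
                         Sigma = sigmas[[group_of[i]]])
      if (config$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                        nrow(x), ncol(x))
      }
      age[i] <- stats::runif(1L, 20, 55)
      gender[i] <- stats::rbinom(1L, 1L, 0.5)
      colnames(x) <- sprintf("roi_%d", seq_len(config$n_rois))
      x
    })
  }
  names(ts) <- ids
  subjects <- data.frame(
    subject_id = ids, group = group_of, age = age, gender = gender,
    site = rep_len(c("site1", "site2"), n_total),
    stringsAsFactors = FALSE
  )
  list(timeseries = ts, subjects = subjects)
}

#' Planted connected edge set
#'
#' Builds a connected set of `n_edges` edges on the given nodes: a spanning
#' path first (guaranteeing connectedness), then additional distinct pairs in
#' deterministic order. Used to plant coherent subnetwork effects for the
#' network-based statistic.
#'
#' @param nodes Integer vector of node indices (length >= 2).
#' @param n_edges Number of edges, between `length(nodes) - 1` and
#'   `choose(length(nodes), 2)`.
#' @return Two-column integer matrix of node pairs, i < j.
#' @export
planted_component_edges <- function(nodes, n_edges) {
  nodes <- as.integer(nodes)
  k <- length(nodes)
  stopifnot(k >= 2L, n_edges >= k - 1L, n_edges <= n_node_pairs(k))
  path <- cbind(nodes[-k], nodes[-1L])
  path <- t(apply(path, 1L, sort))
  all_pairs <- edge_index_pairs(k)
  all_pairs <- cbind(nodes[all_pairs[, 1L]], nodes[all_pairs[, 2L]])
  all_pairs <- t(apply(all_pairs, 1L, sort))
  key <- function(m) paste(m[, 1L], m[, 2L])
  extra <- all_pairs[!key(all_pairs) %in% key(path), , drop = FALSE]
  out <- rbind(path, extra[seq_len(n_edges - nrow(path)), , drop = FALSE])
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes one time-series TSV per subject (time x ROI, header = roi ids), the
#' atlas TSV, the subject table TSV, and a ground-truth JSON recording the
#' planted edges, delta, effect group and master seed.
#'
#' @param cohort Output of [sample_cohort()].
#' @param atlas Atlas `data.frame` as from [generate_atlas()].
#' @param config The [cohort_config()] used.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, atlas, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$timeseries)) {
    write_timeseries(cohort$timeseries[[id]],
                     file.path(dir, "timeseries", paste0(id, ".tsv")))
  }
  truth <- list(
    seed = config$seed, delta = config$delta,
    effect_group = config$effect_group,
    planted_edges = if (is.null(config$planted_edges)) list() else
      apply(config$planted_edges, 1L, function(r) as.list(r), simplify = FALSE)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
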