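# Group-comparison statistics: the metric density sweep, permutation
# two-sample t-tests with covariate residualization, Benjamini-Hochberg FDR,
# rich-club group-difference permutation tests, metric-score correlations,
# and summary-statistic tests (one-way ANOVA F and Pearson chi-square
# reconstructed from printed group summaries).

# Residualize a numeric vector on centered covariates, adding back the
# intercept (scale-preserving). NULL/empty covariates -> identity.
residualize <- function(values, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(values)
  x <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
  design <- cbind(1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("covariate design is rank deficient", call. = FALSE)
  }
  beta <- qr.coef(qrd, values)
  as.numeric(values - design %*% beta + beta[1L])
}

# Pooled-variance two-sample t statistic; 0 when both the between-group
# difference and the pooled variance vanish, signed Inf when only the
# variance does.
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  d <- mean(x) - mean(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / se
  }
}

#' Permutation two-sample t-test with covariate control
#'
#' Residualizes the pooled values on the covariates first (residual plus
#' intercept), computes the pooled-variance two-sample t on the residualized
#' values, then permutes group labels. When the total number of label
#' arrangements choose(n, n1) is at most `n_perm`, the null is enumerated
#' exhaustively and p = #\{|t*| >= |t|\} / #arrangements (the observed split
#' is one arrangement); otherwise `n_perm` Monte-Carlo permutations are drawn
#' and p = (1 + #\{|t*| >= |t|\}) / (1 + n_perm). Two-tailed.
#'
#' @param values_g1,values_g2 Numeric vectors, >= 2 each.
#' @param covariates Optional numeric covariate matrix for all subjects
#'   (group 1 rows first, then group 2).
#' @param n_perm Permutation budget, >= 100.
#' @param seed Optional seed for the Monte-Carlo stream.
#' @return List: `t`, `p`, `n_perm_used`, `exhaustive`.
#' @export
#' @examples
#' permutation_ttest(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2/20 = 0.1
permutation_ttest <- function(values_g1, values_g2, covariates = NULL,
                              n_perm = 10000L, seed = NULL) {
  n1 <- length(values_g1); n2 <- length(values_g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 values per group", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  v <- residualize(c(values_g1, values_g2), covariates)
  n <- n1 + n2
  if (stats::var(v[seq_len(n1)]) == 0 && stats::var(v[-seq_len(n1)]) == 0 &&
      mean(v[seq_len(n1)]) == mean(v[-seq_len(n1)])) {
    warning("zero variance in both groups; p = 1", call. = FALSE)
    return(list(t = 0, p = 1, n_perm_used = 0L, exhaustive = TRUE))
  }
  t_obs <- pooled_t(v[seq_len(n1)], v[-seq_len(n1)])
  n_arr <- choose(n, n1)
  tol <- 1e-12
  if (n_arr <= n_perm) {
    combs <- utils::combn(n, n1)
    t_all <- apply(combs, 2L, function(idx) pooled_t(v[idx], v[-idx]))
    p <- mean(abs(t_all) >= abs(t_obs) - tol)
    list(t = t_obs, p = p, n_perm_used = ncol(combs), exhaustive = TRUE)
  } else {
    exceed <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n, n1)
        if (abs(pooled_t(v[idx], v[-idx])) >= abs(t_obs) - tol) cnt <- cnt + 1L
      }
      cnt
    })
    list(t = t_obs, p = (1 + exceed) / (1 + n_perm), n_perm_used = n_perm,
         exhaustive = FALSE)
  }
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q`: reject the hypotheses with the i* smallest
#' p-values where i* = max\{i : p_(i) <= (i/m) q\}. `NA` p-values are never
#' rejected.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param q FDR level, default 0.05.
#' @return Logical rejection mask, same length as `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0L) return(logical(0L))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Topology metrics for every subject across a density sweep
#'
#' Thresholds each subject's connectivity matrix at every density in the grid
#' (candidates restricted to positive entries inside `mask`) and computes
#' assortativity, mean clustering and global efficiency on the resulting
#' binary graph. Undefined assortativity (regular graph) is recorded as `NA`,
#' never a silent zero.
#'
#' @param matrices Named list of connectivity matrices, one per subject.
#' @param mask Optional analyzable-edge mask.
#' @param grid Density grid; default 10% to 34% in steps of 1% (25 values).
#' @param subjects Optional subject table merged onto the output by
#'   `subject_id`.
#' @return Long-format `data.frame`: subject_id, density, assortativity,
#'   clustering, efficiency (plus subject columns when given).
#' @export
density_sweep <- function(matrices, mask = NULL,
                          grid = seq(0.10, 0.34, by = 0.01),
                          subjects = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- names(matrices)
  if (is.null(ids)) ids <- sprintf("sub-%03d", seq_along(matrices))
  rows <- vector("list", length(matrices) * length(grid))
  idx <- 0L
  for (s in seq_along(matrices)) {
    for (d in grid) {
      g <- suppressWarnings(proportional_threshold(matrices[[s]], d, mask))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        subject_id = ids[s], density = d,
        assortativity = if (sum(g) == 0L) NA_real_ else assortativity(g),
        clustering = mean_clustering(g),
        efficiency = global_efficiency(g),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(subjects)) out <- merge(out, subjects, by = "subject_id",
                                       sort = FALSE)
  out
}

#' Compare one metric between two groups across the density sweep
#'
#' Runs [permutation_ttest()] per density and applies [bh_fdr()] across the
#' grid. Subjects with an undefined (NA) metric value at a density are
#' dropped from that density's test, with the dropped count recorded.
#'
#' @param metric_table Output of [density_sweep()] including a `group` column.
#' @param metric One of "assortativity", "clustering", "efficiency".
#' @param group1,group2 Group labels to compare (t is group1 minus group2).
#' @param covariates Optional data.frame of per-subject covariates aligned to
#'   the subject table inside `metric_table` (columns used as numeric
#'   design via model.matrix, no intercept).
#' @param n_perm,q,seed Permutation budget, FDR level, seed.
#' @return `data.frame` (class `sweep_comparison`): density, t, p,
#'   significant_fdr, significant_uncorrected, n_dropped.
#' @export
sweep_group_comparison <- function(metric_table, metric, group1, group2,
                                   covariates = NULL, n_perm = 10000L,
                                   q = 0.05, seed = NULL) {
  stopifnot(metric %in% c("assortativity", "clustering", "efficiency"),
            "group" %in% names(metric_table))
  grid <- sort(unique(metric_table$density))
  res <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    d <- grid[gi]
    sub <- metric_table[metric_table$density == d &
                          metric_table$group %in% c(group1, group2), ]
    val <- sub[[metric]]
    keep <- !is.na(val)
    n_dropped <- sum(!keep)
    sub <- sub[keep, ]
    g1 <- sub[[metric]][sub$group == group1]
    g2 <- sub[[metric]][sub$group == group2]
    covs <- NULL
    if (!is.null(covariates)) {
      cv <- covariates[match(c(sub$subject_id[sub$group == group1],
                               sub$subject_id[sub$group == group2]),
                             rownames(covariates)), , drop = FALSE]
      covs <- cv
    }
    tt <- permutation_ttest(g1, g2, covariates = covs, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL else
                              derive_seed(seed, gi))
    res[[gi]] <- data.frame(density = d, t = tt$t, p = tt$p,
                            n_dropped = n_dropped)
  }
  out <- do.call(rbind, res)
  out$significant_uncorrected <- out$p < 0.05
  out$significant_fdr <- bh_fdr(out$p, q)
  attr(out, "metric") <- metric
  attr(out, "groups") <- c(group1, group2)
  class(out) <- c("sweep_comparison", "data.frame")
  out
}

#' Rich-club group-difference permutation test
#'
#' For two group graphs (typically group-average networks at the top 7% of
#' strongest positive connections), the observed difference
#' Delta(k) = Phi_g1(k) - Phi_g2(k) is compared to a null of `R` differences
#' between paired degree-preserving randomizations of each graph. Two-tailed
#' p(k) = (1 + #\{|Delta_null| >= |Delta|\}) / (1 + R), BH-FDR corrected
#' across the k levels where both curves are defined.
#'
#' @param g1,g2 Binary adjacency matrices.
#' @param R Number of paired randomizations, default 1000.
#' @param q FDR level.
#' @param swap_factor Rewiring effort.
#' @param seed Optional master seed.
#' @return Object of class `rich_club_diff`: data.frame with k, phi1, phi2,
#'   delta, p, significant (BH-FDR), plus attributes `R` and `q`.
#' @export
richclub_group_difference <- function(g1, g2, R = 1000L, q = 0.05,
                                      swap_factor = 10, seed = NULL) {
  a1 <- as_adjacency(g1); a2 <- as_adjacency(g2)
  c1 <- rich_club_curve(a1); c2 <- rich_club_curve(a2)
  kmax <- min(max(c1$k), max(c2$k))
  ks <- seq_len(kmax)
  phi1 <- c1$phi[match(ks, c1$k)]
  phi2 <- c2$phi[match(ks, c2$k)]
  defined <- !is.na(phi1) & !is.na(phi2)
  delta <- phi1 - phi2
  null_delta <- matrix(NA_real_, R, length(ks))
  for (r in seq_len(R)) {
    s1 <- if (is.null(seed)) NULL else derive_seed(seed, 2L * r - 1L)
    s2 <- if (is.null(seed)) NULL else derive_seed(seed, 2L * r)
    r1 <- rich_club_curve(degree_preserving_randomize(a1, swap_factor, s1))
    r2 <- rich_club_curve(degree_preserving_randomize(a2, swap_factor, s2))
    null_delta[r, ] <- r1$phi[match(ks, r1$k)] - r2$phi[match(ks, r2$k)]
  }
  p <- rep(NA_real_, length(ks))
  for (j in which(defined)) {
    p[j] <- (1 + sum(abs(null_delta[, j]) >= abs(delta[j]))) / (1 + R)
  }
  significant <- rep(FALSE, length(ks))
  significant[defined] <- bh_fdr(p[defined], q)
  out <- data.frame(k = ks, phi1 = phi1, phi2 = phi2, delta = delta,
                    p = p, significant = significant)
  attr(out, "R") <- R
  attr(out, "q") <- q
  class(out) <- c("rich_club_diff", "data.frame")
  out
}

#' Correlate topology metrics with a per-subject score
#'
#' Pearson correlation of each metric with the score at every density, with
#' BH-FDR across the density grid within each metric (how associations with
#' symptom-severity scores such as HDRS/BDI are screened). A constant score
#' yields `NA` correlations, flagged, never an error.
#'
#' @param metric_table Output of [density_sweep()].
#' @param scores Named numeric vector (names = subject_id) or data.frame with
#'   `subject_id` and `score` columns.
#' @param q FDR level.
#' @return `data.frame`: metric, density, n, r, p, significant_fdr.
#' @export
metric_score_correlation <- function(metric_table, scores, q = 0.05) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$subject_id)
  }
  metrics <- intersect(c("assortativity", "clustering", "efficiency"),
                       names(metric_table))
  grid <- sort(unique(metric_table$density))
  rows <- list()
  for (m in metrics) {
    mrows <- vector("list", length(grid))
    for (gi in seq_along(grid)) {
      sub <- metric_table[metric_table$density == grid[gi], ]
      sc <- scores[sub$subject_id]
      val <- sub[[m]]
      keep <- !is.na(sc) & !is.na(val)
      n_eff <- sum(keep)
      if (n_eff < 4L || stats::sd(sc[keep]) == 0 || stats::sd(val[keep]) == 0) {
        mrows[[gi]] <- data.frame(metric = m, density = grid[gi], n = n_eff,
                                  r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(val[keep], sc[keep], method = "pearson")
        mrows[[gi]] <- data.frame(metric = m, density = grid[gi], n = n_eff,
                                  r = unname(ct$estimate), p = ct$p.value)
      }
    }
    mdf <- do.call(rbind, mrows)
    mdf$significant_fdr <- bh_fdr(mdf$p, q)
    rows[[m]] <- mdf
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA F from group summary statistics
#'
#' Reconstructs the one-way ANOVA F from printed per-group (n, mean, sd):
#' SSB = sum n_i (mean_i - grand mean)^2, SSW = sum (n_i - 1) sd_i^2,
#' F = (SSB / (G - 1)) / (SSW / (N - G)). Equals a direct ANOVA on any raw
#' data having exactly these summaries.
#'
#' @param n,means,sds Numeric vectors of group sizes (each >= 2), means and
#'   standard deviations (>= 0).
#' @return List: `statistic` (F), `df` (c(G-1, N-G)), `p.value`.
#' @export
#' @examples
#' anova_from_summary(c(38, 20, 16), c(33.1, 40.7, 37.8), c(8.2, 10.3, 10.5))
anova_from_summary <- function(n, means, sds) {
  stopifnot(length(n) == length(means), length(n) == length(sds),
            length(n) >= 2L, all(n >= 2L), all(sds >= 0))
  g <- length(n)
  nn <- sum(n)
  grand <- sum(n * means) / nn
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- g - 1L
  df2 <- nn - g
  if (ssw == 0) {
    if (ssb > 0) {
      warning("zero within-group variance with nonzero between-group ",
              "variance: F is infinite", call. = FALSE)
      return(list(statistic = Inf, df = c(df1, df2), p.value = 0))
    }
    return(list(statistic = NaN, df = c(df1, df2), p.value = NA_real_))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2),
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square from a contingency table
#'
#' Classic Pearson chi-square with expected counts from the row/column
#' margins; no continuity correction (matching how categorical group
#' characteristics such as gender counts are compared).
#'
#' @param counts Matrix of non-negative counts; no all-zero row or column.
#' @return List: `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chisq_from_counts(rbind(c(18, 6, 3), c(20, 14, 13)))
chisq_from_counts <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}
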