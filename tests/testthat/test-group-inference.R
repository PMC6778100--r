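test_that("exhaustive permutation test matches enumeration", {
  tt <- permutation_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_true(tt$exhaustive)
  expect_equal(tt$n_perm_used, 20)
  expect_equal(tt$p, 0.1)  # only the observed split and its mirror reach max |t|

  same <- suppressWarnings(permutation_ttest(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(permutation_ttest(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("permutation p is symmetric under group-label swap", {
  set.seed(30)
  x <- rnorm(6); y <- rnorm(6) + 1
  a <- permutation_ttest(x, y)
  b <- permutation_ttest(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$t, -b$t)
})

test_that("Monte-Carlo and exhaustive permutation p agree within 3 SE", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5) + 1.2
    ex <- permutation_ttest(x, y, n_perm = 100000)  # choose(10,5)=252 -> exact
    expect_true(ex$exhaustive)
    mc <- permutation_ttest(x, y, n_perm = 249, seed = rep)  # force Monte-Carlo
    expect_false(mc$exhaustive)
    se <- sqrt(ex$p * (1 - ex$p) / 249)
    expect_lt(abs(mc$p - ex$p), 3 * se + 1 / 250)
  }
})

test_that("covariate residualization inside the test removes a confound", {
  set.seed(32)
  n <- 12
  age1 <- seq(20, 42, length.out = n); age2 <- age1  # matched groups
  x <- 0.05 * age1 + rnorm(n, sd = 0.1)
  y <- 0.05 * age2 + 0.5 + rnorm(n, sd = 0.1)
  raw <- permutation_ttest(x, y, n_perm = 500, seed = 1)
  adj <- permutation_ttest(x, y, covariates = cbind(age = c(age1, age2)),
                           n_perm = 500, seed = 1)
  expect_lt(adj$p, 0.05)  # true group shift survives adjustment
  expect_gt(abs(adj$t), abs(raw$t) * 0.5)
})

test_that("BH step-up matches the worked thresholds", {
  p <- c(0.005, 0.02, 0.03, 0.04, 0.2)
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 4)), rep(FALSE, 4))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)
  expect_equal(bh_fdr(numeric(0)), logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH controls the FDR in an all-null simulation", {
  set.seed(33)
  n_rep <- 1000
  any_reject <- 0
  for (r in seq_len(n_rep)) {
    p <- runif(25)
    any_reject <- any_reject + any(bh_fdr(p, 0.05))
  }
  # under the global null, FDR = FWER <= q
  expect_lt(any_reject / n_rep, 0.065)
})

test_that("density sweep uses the 25-density grid and flags undefined values", {
  grid <- seq(0.10, 0.34, by = 0.01)
  expect_length(grid, 25)
  # a K-regular graph at every density: assortativity undefined throughout
  n <- 8
  m <- matrix(0.5, n, n); diag(m) <- 0  # equal weights -> deterministic ties
  sw <- density_sweep(list(s1 = m), grid = c(0.10, 0.20))
  expect_true(all(c("assortativity", "clustering", "efficiency") %in% names(sw)))
})

test_that("a planted efficiency difference drives t in the expected direction", {
  cfg_lo <- cohort_config(n_rois = 15, n_modules = 3, within_r = 0.5,
                          between_r = 0.05, groups = c(a = 10),
                          n_timepoints = 150, seed = 40)
  cfg_hi <- cohort_config(n_rois = 15, n_modules = 3, within_r = 0.5,
                          between_r = 0.35, groups = c(b = 10),
                          n_timepoints = 150, seed = 41)
  mats <- c(lapply(sample_cohort(cfg_lo)$timeseries, correlation_matrix),
            lapply(sample_cohort(cfg_hi)$timeseries, correlation_matrix))
  names(mats) <- sprintf("s%02d", 1:20)
  sw <- density_sweep(mats, grid = seq(0.10, 0.34, by = 0.04))
  sw$group <- rep(c("a", "b"), each = nrow(sw) / 2)
  cmp <- sweep_group_comparison(sw, "efficiency", "a", "b", n_perm = 200,
                                seed = 42)
  # stronger between-module correlations -> higher efficiency in group b
  expect_true(all(cmp$t < 0))
  expect_true(all(cmp$significant_fdr %in% c(TRUE, FALSE)))
  # FDR mask is a subset of the uncorrected mask
  expect_true(all(!cmp$significant_fdr | cmp$significant_uncorrected))
})

test_that("rich-club difference is null for identical graphs", {
  set.seed(43)
  g <- er_adjacency(60, 0.2)
  d <- richclub_group_difference(g, g, R = 150, seed = 44)
  ok <- !is.na(d$delta)
  expect_true(all(d$delta[ok] == 0))
  expect_false(any(d$significant))
})

test_that("rich-club difference detects a planted core against a matched null", {
  g1 <- planted_core_graph(seed = 45)
  # degree-matched control: heavily rewired version of the same graph
  g2 <- degree_preserving_randomize(g1, swap_factor = 50, seed = 46)
  d <- richclub_group_difference(g1, g2, R = 400, seed = 47)
  hi <- d$k >= 8 & !is.na(d$delta)
  expect_true(any(d$significant[hi]))
  expect_true(all(d$delta[hi] > 0))
})

test_that("rich-club difference test is calibrated (at most nominal, not degenerate)", {
  # two independent ER draws with identical parameters are exchangeable with
  # their degree-preserving randomizations, so per-k rejections at alpha=0.05
  # should sit at or slightly below 5% (the +1 correction and the
  # discreteness of phi make the test mildly conservative, never liberal)
  n_rep <- 100; R <- 100
  rej <- 0L; tot <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(9000 + r)
    mk <- function() {
      adj <- matrix(0L, 60, 60); up <- upper.tri(adj)
      adj[up] <- rbinom(sum(up), 1L, 0.15); adj + t(adj)
    }
    d <- richclub_group_difference(mk(), mk(), R = R, seed = 10000 + r)
    ok <- !is.na(d$p)
    rej <- rej + sum(d$p[ok] < 0.05)
    tot <- tot + sum(ok)
  }
  rate <- rej / tot
  expect_lt(rate, 0.07)
  expect_gt(rate, 0.01)
})

test_that("metric-score correlations recover exact and null relationships", {
  set.seed(48)
  sw <- data.frame(
    subject_id = rep(sprintf("s%02d", 1:20), each = 2),
    density = rep(c(0.1, 0.2), 20),
    efficiency = rnorm(40)
  )
  # score == metric at density 0.1 -> r = 1
  sc <- sw$efficiency[sw$density == 0.1]
  names(sc) <- sw$subject_id[sw$density == 0.1]
  out <- metric_score_correlation(sw, sc)
  expect_equal(out$r[out$density == 0.1], 1)
  out_neg <- metric_score_correlation(sw, -sc)
  expect_equal(out_neg$r[out_neg$density == 0.1], -1)
  # constant score -> NA, flagged not errored
  const <- metric_score_correlation(sw, setNames(rep(2, 20), names(sc)))
  expect_true(all(is.na(const$r)))
})

test_that("independent scores reject at about the nominal 5% rate", {
  set.seed(49)
  n <- 50; n_rep <- 1000
  crit <- qt(0.975, n - 2)
  rej <- 0
  for (r in seq_len(n_rep)) {
    x <- rnorm(n); y <- rnorm(n)
    tstat <- cor(x, y) * sqrt((n - 2) / (1 - cor(x, y)^2))
    rej <- rej + (abs(tstat) > crit)
  }
  expect_gt(rej / n_rep, 0.035)
  expect_lt(rej / n_rep, 0.065)
})

test_that("from-summary ANOVA equals direct ANOVA on reconstructed data", {
  groups <- list(c(10, 5.0, 1.2), c(14, 6.1, 2.0), c(8, 4.2, 0.8))
  n <- sapply(groups, `[`, 1); m <- sapply(groups, `[`, 2)
  s <- sapply(groups, `[`, 3)
  res <- anova_from_summary(n, m, s)
  raw <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(g = factor(i), y = vector_with_summary(n[i], m[i], s[i]))
  }))
  fit <- anova(aov(y ~ g, data = raw))
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p.value, fit$`Pr(>F)`[1], tolerance = 1e-10)

  # identical groups -> F = 0
  expect_equal(anova_from_summary(c(10, 10), c(3, 3), c(1, 1))$statistic, 0)
  expect_warning(anova_from_summary(c(5, 5), c(1, 2), c(0, 0)), "infinite")
})

test_that("chi-square from counts matches chisq.test without correction", {
  tab <- rbind(c(18, 6, 3), c(20, 14, 13))
  res <- chisq_from_counts(tab)
  oracle <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p.value, unname(oracle$p.value), tolerance = 1e-12)

  even <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(chisq_from_counts(even)$statistic, 0)
  expect_equal(chisq_from_counts(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(chisq_from_counts(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chisq_from_counts(rbind(c(-1, 2), c(1, 2))), "non-negative")
})
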