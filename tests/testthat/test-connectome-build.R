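test_that("correlation_matrix handles exact dependence and independence", {
  set.seed(1)
  base <- rnorm(200)
  ts <- cbind(a = base, b = 2 * base, c = -base, d = rnorm(200))
  r <- correlation_matrix(ts)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(unname(diag(r)), rep(0, 4))
  expect_true(isSymmetric(unclass(r)))

  set.seed(2)
  big <- cbind(rnorm(10000), rnorm(10000))
  r2 <- correlation_matrix(big)
  expect_lt(abs(r2[1, 2]), 0.05)

  ts_const <- cbind(roi_1 = rnorm(50), roi_2 = rep(1, 50))
  expect_error(correlation_matrix(ts_const), "roi_2")
  expect_error(correlation_matrix(matrix(rnorm(8 * 3), 8, 3)), "10 time points")
})

test_that("fisher z transform is atanh on clipped correlations", {
  set.seed(3)
  base <- rnorm(100)
  ts <- cbind(base, 0.5 * base + rnorm(100), 2 * base)
  r <- correlation_matrix(ts, fisher_z = FALSE)
  z <- correlation_matrix(ts, fisher_z = TRUE)
  expect_equal(z[1, 2], atanh(r[1, 2]))
  expect_true(is.finite(z[1, 3]))  # r = 1 clipped, not Inf
  expect_identical(attr(z, "scale"), "fisher_z")
})

test_that("distance mask excludes strictly-below-threshold pairs only", {
  atlas <- data.frame(roi_id = 1:4,
                      x = c(0, 0, 0, 0), y = c(0, 0, 0, 0),
                      z = c(0, 19, 40, 60), label = letters[1:4])
  mask <- distance_mask(atlas, threshold_mm = 20)
  expect_false(mask[1, 2])  # 19 mm: excluded
  expect_true(mask[1, 3])   # 40 mm
  expect_true(mask[2, 3])   # 21 mm
  expect_true(mask[3, 4])   # exactly 20 mm: retained
  expect_false(any(diag(mask)))
  expect_true(isSymmetric(mask))
})

test_that("reference positive mask retains the top fraction of positive average edges", {
  n <- 6
  m <- matrix(0, n, n)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  w <- seq(0.9, by = -0.05, length.out = nrow(pairs))
  m[pairs] <- w
  m <- m + t(m)
  mask <- reference_positive_mask(list(m, m), density = 0.5)
  kept <- sum(mask[upper.tri(mask)])
  expect_equal(kept, round(0.5 * choose(n, 2)))
  # the retained edges are exactly the strongest ones
  expect_true(all(m[mask & upper.tri(m)] >= sort(w, decreasing = TRUE)[kept]))

  full <- reference_positive_mask(list(m, m), density = 1)
  expect_equal(sum(full[upper.tri(full)]), choose(n, 2))
  expect_error(reference_positive_mask(list(m, m), density = 0), "density")
  expect_error(reference_positive_mask(list(m), density = 0.5), "at least 2")
})

test_that("reference mask at 45% of a 262-node matrix keeps 15386 edges", {
  set.seed(8)
  m <- abs(rand_symmetric(262)) + 0.01
  diag(m) <- 0
  mask <- reference_positive_mask(list(m, m), density = 0.45)
  expect_equal(sum(mask[upper.tri(mask)]), round(0.45 * 262 * 261 / 2))
  expect_equal(sum(mask[upper.tri(mask)]), 15386)
})

test_that("covariate regression is scale-preserving and removes linear effects", {
  set.seed(5)
  s <- 20
  mats <- replicate(s, rand_symmetric(5), simplify = FALSE)
  # no covariates: identity
  expect_identical(regress_covariates(mats, NULL), mats)

  # an edge exactly linear in age becomes constant at the grand mean
  age <- seq(20, 58, length.out = s)
  mats2 <- mats
  for (i in seq_len(s)) mats2[[i]][1, 2] <- mats2[[i]][2, 1] <- 0.5 + 0.01 * age[i]
  out <- regress_covariates(mats2, cbind(age = age))
  vals <- vapply(out, function(m) m[1, 2], 0)
  expect_equal(vals, rep(mean(0.5 + 0.01 * age), s), tolerance = 1e-10)

  # covariate orthogonal to an edge leaves it unchanged
  edge_vals <- vapply(mats, function(m) m[3, 4], 0)
  cov_orth <- residuals(lm(rnorm(s) ~ edge_vals))
  out2 <- regress_covariates(mats, cbind(v = cov_orth))
  expect_equal(vapply(out2, function(m) m[3, 4], 0), edge_vals,
               tolerance = 1e-10)

  expect_error(regress_covariates(mats, cbind(a = age, b = 2 * age)),
               "rank deficient")
})

test_that("age adjustment preserves group differences in age-matched groups", {
  set.seed(6)
  s <- 40
  grp <- rep(c(0, 1), each = s / 2)
  age <- rep(seq(25, 45, length.out = s / 2), 2)  # identical age profiles
  mats <- replicate(s, rand_symmetric(4), simplify = FALSE)
  for (i in seq_len(s)) {
    mats[[i]][1, 2] <- mats[[i]][2, 1] <-
      0.2 + 0.4 * grp[i] + 0.01 * age[i] + rnorm(1, sd = 0.01)
  }
  out <- regress_covariates(mats, cbind(age = age))
  raw_diff <- function(ms) {
    v <- vapply(ms, function(m) m[1, 2], 0)
    mean(v[grp == 1]) - mean(v[grp == 0])
  }
  expect_equal(raw_diff(out), raw_diff(mats), tolerance = 1e-10)
})

test_that("proportional threshold keeps the strongest edges at the target count", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.9; m[1, 3] <- 0.8; m[1, 4] <- 0.7
  m[2, 3] <- 0.3; m[2, 4] <- 0.2; m[3, 4] <- 0.1
  m <- m + t(m)
  g <- proportional_threshold(m, 0.5)
  expect_equal(sum(g) / 2, 3)
  expect_equal(g[1, 2] + g[1, 3] + g[1, 4], 3L)
  expect_equal(g[2, 3] + g[2, 4] + g[3, 4], 0L)

  full <- proportional_threshold(abs(rand_symmetric(5)) + 0.1, 1)
  expect_equal(sum(full) / 2, choose(5, 2))

  expect_error(proportional_threshold(m, 1.2), "density")

  # binding mask: fewer candidates than requested -> warn, keep all, record
  mask <- matrix(FALSE, 4, 4)
  mask[1, 2] <- mask[2, 1] <- mask[1, 3] <- mask[3, 1] <- TRUE
  expect_warning(g2 <- proportional_threshold(m, 0.9, mask), "available")
  expect_equal(sum(g2) / 2, 2)
  expect_equal(attr(g2, "density_achieved"), 2 / 6)
})

test_that("threshold edge sets are nested across the density sweep", {
  set.seed(7)
  m <- rand_symmetric(40)
  grid <- seq(0.10, 0.34, by = 0.01)
  expect_length(grid, 25)
  prev <- NULL
  for (d in grid) {
    g <- proportional_threshold(m, d)
    expect_equal(sum(g) / 2, floor(d * choose(40, 2)))
    if (!is.null(prev)) expect_true(all(g[prev == 1L] == 1L))
    prev <- g
  }
})

test_that("thresholding commutes with node relabeling", {
  set.seed(9)
  m <- rand_symmetric(12)
  perm <- sample(12)
  g <- proportional_threshold(m, 0.3)
  g_perm <- proportional_threshold(m[perm, perm], 0.3)
  expect_equal(g_perm, g[perm, perm], ignore_attr = TRUE)
})

test_that("group_average_graph thresholds the positive group mean", {
  set.seed(10)
  mats <- replicate(4, rand_symmetric(20), simplify = FALSE)
  g <- group_average_graph(mats, density = 0.07)
  expect_equal(sum(g) / 2, floor(0.07 * choose(20, 2)))
  avg <- Reduce(`+`, mats) / 4
  expect_true(all(avg[g == 1L] > 0))
})
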