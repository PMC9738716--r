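test_that("single-column CCA reduces to the Pearson correlation", {
  set.seed(51)
  a <- matrix(rnorm(30), ncol = 1)
  b <- matrix(0.6 * a + 0.8 * rnorm(30), ncol = 1)
  fit <- fit_cca(a, b, ridge = 0)
  expect_equal(fit$d_cca, 1L)
  expect_equal(fit$canonical_correlations, abs(pearson(a[, 1], b[, 1])),
               tolerance = 1e-10)

  # perfectly linearly related single columns
  fit2 <- fit_cca(a, 2 * a + 3, ridge = 0)
  expect_equal(fit2$canonical_correlations, 1, tolerance = 1e-10)
  expect_equal(fit2$p_values, 0)
})

test_that("fit_cca agrees with stats::cancor and a 1-degree grid search", {
  set.seed(52)
  for (i in 1:10) {
    n <- 50
    da <- sample(1:5, 1); db <- sample(1:5, 1)
    A <- matrix(rnorm(n * da), n, da)
    B <- matrix(rnorm(n * db), n, db)
    fit <- fit_cca(A, B, ridge = 0)
    ref <- stats::cancor(A, B)
    expect_equal(fit$canonical_correlations, ref$cor, tolerance = 1e-6)
    # canonical variates agree after standardization and sign alignment
    xa <- scale(A, scale = FALSE) %*% ref$xcoef[, seq_len(fit$d_cca), drop = FALSE]
    for (k in seq_len(fit$d_cca)) {
      mine <- fit$canonical_features_a[, k]
      theirs <- xa[, k] / stats::sd(xa[, k])
      expect_equal(abs(stats::cor(mine, theirs)), 1, tolerance = 1e-6)
    }
  }

  set.seed(53)
  for (i in 1:4) {
    A <- matrix(rnorm(30 * 2), 30, 2)
    B <- matrix(rnorm(30 * 3), 30, 3)
    fit <- fit_cca(A, B, ridge = 0)
    grid <- grid_max_cancor(A, B, step_deg = 1)
    expect_gte(fit$canonical_correlations[1], grid - 1e-9)  # optimum dominates any direction
    expect_lt(fit$canonical_correlations[1] - grid, 1e-3)   # grid is dense enough
  }
})

test_that("canonical correlations are invariant to affine maps and block order", {
  set.seed(54)
  A <- matrix(rnorm(40 * 3), 40, 3)
  B <- matrix(rnorm(40 * 4), 40, 4)
  fit <- fit_cca(A, B, ridge = 0)

  Ta <- matrix(rnorm(9), 3, 3); while (abs(det(Ta)) < 0.1) Ta <- matrix(rnorm(9), 3, 3)
  Tb <- matrix(rnorm(16), 4, 4); while (abs(det(Tb)) < 0.1) Tb <- matrix(rnorm(16), 4, 4)
  fit_t <- fit_cca(A %*% Ta + 5, sweep(B %*% Tb, 2, c(1, -2, 3, 0.5), `+`), ridge = 0)
  expect_equal(fit_t$canonical_correlations, fit$canonical_correlations,
               tolerance = 1e-8)

  swapped <- fit_cca(B, A, ridge = 0)
  expect_equal(swapped$canonical_correlations, fit$canonical_correlations,
               tolerance = 1e-8)
  for (k in seq_len(fit$d_cca)) {
    expect_equal(abs(swapped$projection_a[, k]), abs(fit$projection_b[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(abs(swapped$projection_b[, k]), abs(fit$projection_a[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("canonical features satisfy the defining constraints", {
  set.seed(55)
  A <- matrix(rnorm(60 * 4), 60, 4)
  B <- matrix(rnorm(60 * 3), 60, 3)
  fit <- fit_cca(A, B)
  lam <- fit$canonical_correlations
  expect_true(all(diff(lam) <= 1e-10))
  expect_true(all(lam >= 0 & lam <= 1))
  for (k in seq_len(fit$d_cca)) {
    expect_equal(stats::var(fit$canonical_features_a[, k]), 1, tolerance = 1e-6)
    expect_equal(stats::var(fit$canonical_features_b[, k]), 1, tolerance = 1e-6)
    expect_equal(stats::cor(fit$canonical_features_a[, k], fit$canonical_features_b[, k]),
                 lam[k], tolerance = 1e-6)
    w <- fit$projection_a[, k]
    expect_gt(w[which.max(abs(w))], 0)  # sign convention
  }
  ca <- stats::cor(fit$canonical_features_a)
  cb <- stats::cor(fit$canonical_features_b)
  expect_lt(max(abs(ca - diag(fit$d_cca))), 1e-6)
  expect_lt(max(abs(cb - diag(fit$d_cca))), 1e-6)

  # first canonical correlation dominates every single-pair correlation
  best_pair <- max(abs(stats::cor(A, B)))
  expect_gte(lam[1] + 1e-10, best_pair)

  expect_error(fit_cca(A[1:30, ], B), "same number of rows")
  expect_error(fit_cca(matrix(2, 30, 2), B[1:30, ]), "rank-0")
})

test_that("the ridge stabilizes collinear blocks", {
  set.seed(56)
  base <- matrix(rnorm(40 * 2), 40, 2)
  A <- cbind(base, base[, 1] + base[, 2])           # exactly collinear
  B <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_cca(A, B)                              # default ridge
  expect_equal(fit$d_cca, 2L)                       # rank, not column count
  expect_true(all(is.finite(fit$canonical_correlations)))
  expect_true(all(fit$canonical_correlations <= 1))
})

test_that("Bartlett significance matches the closed formula and conventions", {
  fake <- structure(list(canonical_correlations = 0.5, n = 20, d_a = 1, d_b = 1),
                    class = "taste_cca")
  # -(20 - 1 - 3/2) * log(1 - 0.25) = 5.034436 on 1 df
  expect_equal(canonical_significance(fake), 0.02484817, tolerance = 1e-6)

  fake2 <- structure(list(canonical_correlations = c(0.8, 0.3), n = 40, d_a = 2, d_b = 3),
                     class = "taste_cca")
  p <- canonical_significance(fake2)
  c_factor <- -(40 - 1 - (2 + 3 + 1) / 2)
  expect_equal(p[1], pchisq(c_factor * log((1 - 0.64) * (1 - 0.09)), 6, lower.tail = FALSE))
  expect_equal(p[2], pchisq(c_factor * log(1 - 0.09), 2, lower.tail = FALSE))
  expect_true(p[1] < p[2])
})

test_that("permutation significance is seeded, minimal on identical blocks, calibrated on noise", {
  set.seed(57)
  a <- matrix(rnorm(30), ncol = 1)
  p_same <- permutation_significance(a, a, n_perm = 99, seed = 3)
  expect_equal(p_same$p_value, 1 / 100)

  b <- matrix(rnorm(30), ncol = 1)
  expect_equal(permutation_significance(a, b, n_perm = 99, seed = 7)$p_value,
               permutation_significance(a, b, n_perm = 99, seed = 7)$p_value)

  # null calibration: p roughly uniform over independent replicates
  set.seed(58)
  ps <- replicate(20, {
    x <- matrix(rnorm(25), ncol = 1); y <- matrix(rnorm(25), ncol = 1)
    permutation_significance(x, y, n_perm = 99, seed = 11)$p_value
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_error(permutation_significance(a, b, n_perm = 50), "at least 99")
})

test_that("cross-loadings reduce to Pearson in 1-d and reject bad input", {
  set.seed(59)
  a <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(0.5 * a + rnorm(30), ncol = 1)
  fit <- fit_cca(a, b, ridge = 0)
  cl <- cross_loadings(fit, a, side = "a", dimension = 1)
  expect_equal(cl$variable, "x")
  expect_equal(cl$loading, pearson(a[, 1], fit$canonical_features_b[, 1]),
               tolerance = 1e-12)
  expect_error(cross_loadings(fit, a, side = "a", dimension = 2), "1..D_cca")
  expect_error(cross_loadings(fit, matrix(1, 30, 1), side = "a"), "constant")
})
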