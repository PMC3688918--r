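test_that("explained variance matches a dense eigendecomposition oracle", {
  set.seed(7)
  x <- matrix(rnorm(10 * 15), 10, 15)
  model <- fit_pca(x, ncomp = 4)
  xs <- autoscale(x)$values
  eig <- eigen(crossprod(xs) / (nrow(x) - 1), symmetric = TRUE)$values
  expect_equal(model$eigenvalues, eig[1:4], tolerance = 1e-10)
  expect_equal(model$explained_variance, eig[1:4] / sum(eig[eig > 1e-12]),
               tolerance = 1e-10)
  # all min(n-1, p) PCs together explain everything
  expect_equal(sum(model$eigenvalues_all) / sum(eig[eig > 1e-12]), 1,
               tolerance = 1e-10)
  # scores are uncorrelated
  cv <- crossprod(model$scores) / (nrow(x) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
})

test_that("rank-1 data put all variance on PC1 without scaling", {
  v <- c(1, 2, 3, 4)
  x <- outer(c(1, 2, 3, -1, 0.5), v)
  model <- fit_pca(x, ncomp = 1, autoscale = FALSE)
  expect_equal(model$explained_variance, 1, tolerance = 1e-12)
})

test_that("Q statistic is the squared residual distance to the model plane", {
  set.seed(21)
  x <- matrix(rnorm(8 * 6), 8, 6)
  model <- fit_pca(x, ncomp = 2)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  recon <- xs %*% model$loadings %*% t(model$loadings)
  expect_equal(q_statistic(model, x), rowSums((xs - recon)^2),
               tolerance = 1e-10)
  # full-rank model reconstructs every training row
  full <- fit_pca(x, ncomp = min(nrow(x) - 1, ncol(x)))
  expect_lt(max(q_statistic(full, x)), 1e-18)
  # row lying in the subspace has Q = 0
  inplane <- (model$scores[1, ] %*% t(model$loadings)) * model$scale +
    model$center
  expect_lt(q_statistic(model, as.numeric(inplane)), 1e-18)
  # feature-order permutation invariance
  perm <- sample(ncol(x))
  model_p <- fit_pca(x[, perm], ncomp = 2)
  expect_equal(q_statistic(model_p, x[, perm]), q_statistic(model, x),
               tolerance = 1e-8)
})

test_that("T2 is the sum of normalized squared scores", {
  set.seed(22)
  x <- matrix(rnorm(12 * 5), 12, 5)
  model <- fit_pca(x, ncomp = 3)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  t_sc <- xs %*% model$loadings
  oracle <- rowSums(sweep(t_sc^2, 2, model$eigenvalues, "/"))
  expect_equal(t2_statistic(model, x), oracle, tolerance = 1e-10)
  # centroid row scores at zero
  expect_equal(t2_statistic(model, model$center), 0, tolerance = 1e-18)
  # quadratic form: doubling a centered row quadruples T2
  row2 <- model$center + 2 * (x[3, ] - model$center)
  expect_equal(t2_statistic(model, row2), 4 * t2_statistic(model, x[3, ]),
               tolerance = 1e-8)
  # training mean equals A(n-1)/n under the n-1 score-variance convention
  expect_equal(mean(t2_statistic(model, x)),
               model$ncomp * (nrow(x) - 1) / nrow(x), tolerance = 1e-8)
})

test_that("95% limits use the F form and approximately cover normal data", {
  # direct formula instantiation at A=1, n=10
  set.seed(30)
  x10 <- matrix(rnorm(10 * 6), 10, 6)
  m1 <- fit_pca(x10, ncomp = 1)
  lim <- pca_limits(m1, n = 10)
  expect_equal(lim$t2_limit, (1 * 9 * 11) / (10 * 9) * qf(0.95, 1, 9))
  expect_gt(lim$q_limit, 0)  # residual variance remains
  # Monte-Carlo coverage on multivariate-normal data
  set.seed(31)
  n <- 60; p <- 6
  sigma <- diag(c(4, 2.5, 1.5, 0.6, 0.3, 0.1))
  train <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  model <- fit_pca(train, ncomp = 2, autoscale = FALSE)
  fresh <- matrix(rnorm(2000 * p), 2000, p) %*% chol(sigma)
  cov_t2 <- mean(t2_statistic(model, fresh) <= model$t2_limit_95)
  cov_q <- mean(q_statistic(model, fresh) <= model$q_limit_95)
  expect_gt(cov_t2, 0.90); expect_lt(cov_t2, 0.99)
  expect_gt(cov_q, 0.90); expect_lt(cov_q, 0.99)
})

test_that("loo-cv component selection picks a low-dimensional structure", {
  set.seed(40)
  # strong 2-factor structure plus small noise
  z <- matrix(rnorm(20 * 2), 20, 2)
  load <- matrix(rnorm(2 * 10, sd = 2), 2, 10)
  x <- z %*% load + matrix(rnorm(200, sd = 0.05), 20, 10)
  model <- fit_pca(x, ncomp = "loo-cv", ncomp_max = 6)
  expect_lte(model$ncomp, 3L)
  expect_gte(model$ncomp, 1L)
  expect_gt(sum(model$explained_variance), 0.9)
})

test_that("Ward clustering matches the Lance-Williams oracle", {
  set.seed(50)
  x <- matrix(rnorm(9 * 4), 9, 4)
  hc <- ward_hca(x)
  expect_equal(hc$height, oracle_ward_heights(x), tolerance = 1e-8)
  expect_true(all(diff(hc$height) >= -1e-12))  # Ward monotonicity
  # two points merge at their Euclidean distance
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(ward_hca(two)$height, 5)
  # two well-separated blobs split at the top
  blobs <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2),
                 matrix(rnorm(10, sd = 0.1) + 10, 5, 2))
  expect_setequal(cutree(ward_hca(blobs), 2), c(1, 2))
  expect_equal(unname(cutree(ward_hca(blobs), 2)),
               rep(c(1, 2), each = 5))
})
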