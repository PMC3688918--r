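test_that("double cross-validation yields one out-of-fold prediction per sample", {
  sep <- make_separated()
  res <- double_cv(sep$x, sep$y)
  expect_equal(nrow(res$folds), 10L)
  expect_true(all(res$folds$n_lv %in% 1:3))
  expect_equal(dim(res$b_folds), c(10L, ncol(sep$x)))
  expect_equal(res$b_mean, colMeans(res$b_folds))
  expect_equal(res$nmc, 0L)  # strong planted direction separates cleanly
  expect_gt(res$dq2, 0.5)
  expect_error(double_cv(sep$x[c(1, 2, 6), ], c(0, 0, 1)), "at least 4")
  expect_error(double_cv(sep$x, c(0, rep(1, 9))), "at least 2")
})

test_that("balanced permutation enumeration matches the brute-force oracle", {
  y55 <- rep(c(0, 1), each = 5)
  perms <- enumerate_balanced_permutations(y55)
  expect_length(perms, 125L)
  expect_equal(length(perms), oracle_n_permutations(y55))
  y33 <- rep(c(0, 1), each = 3)
  expect_length(enumerate_balanced_permutations(y33), 9L)
  expect_equal(length(enumerate_balanced_permutations(y33)),
               oracle_n_permutations(y33))
  # unbalanced classes: no complements to collapse
  y46 <- rep(c(0, 1), c(4, 6))
  expect_length(enumerate_balanced_permutations(y46),
                choose(10, 6) - 1L)
  # the true labeling (and, balanced, its complement) never appears
  for (p in perms) {
    expect_false(all(as.numeric(p) == y55))
    expect_false(all(as.numeric(p) == 1 - y55))
  }
  # class sizes preserved and enumeration deterministic
  expect_true(all(vapply(perms, function(p) sum(as.numeric(p)), 1) == 5))
  expect_identical(perms, enumerate_balanced_permutations(y55))
})

test_that("permutation p-values and selection behave at the extremes", {
  sep <- make_separated(n_per_class = 3, p = 6, delta = 10, seed = 2)
  pt <- permutation_test(sep$x, sep$y, lv_max = 1)
  expect_equal(pt$n_permutations, 9L)
  expect_true(all(c(pt$p_dq2, pt$p_nmc, pt$per_feature_p) >= 0))
  expect_true(all(c(pt$p_dq2, pt$p_nmc, pt$per_feature_p) <= 1))
  # the planted column dominates every null draw
  expect_equal(pt$per_feature_p[1], 0)
  expect_true("1" %in% pt$selected_features)
  # a feature at the null median is not selected
  expect_true(any(pt$per_feature_p[-1] > 0.2))
})

test_that("feature selection is equivariant under column permutation", {
  sep <- make_separated(n_per_class = 3, p = 5, delta = 6, seed = 4)
  pt <- permutation_test(sep$x, sep$y, lv_max = 2)
  ord <- c(3, 1, 5, 2, 4)
  pt2 <- permutation_test(sep$x[, ord], sep$y, lv_max = 2)
  expect_equal(pt2$per_feature_p, pt$per_feature_p[ord], tolerance = 1e-12)
})

test_that("label-exchangeable data give null-level figures of merit", {
  set.seed(60)
  vals <- replicate(50, {
    x <- matrix(rlnorm(10 * 15), 10, 15)
    double_cv(x, rep(c(0, 1), each = 5))$dq2
  })
  expect_lte(mean(vals), 0.1)
  # and the no-effect generator behaves the same through preprocessing
  null_dq2 <- vapply(1:10, function(s) {
    sim <- generate_dataset(small_null_config(), seed = s)
    double_cv(preprocess(sim$table)$x3)$dq2
  }, numeric(1))
  expect_lte(mean(null_dq2), 0.1)
})

test_that("real-label dQ2 dominates its permutation null on separated data", {
  sim <- generate_dataset(small_null_config(n_discriminant = 8L), seed = 8)
  pp <- preprocess(sim$table)
  pt <- permutation_test(pp$x3)
  expect_gt(pt$real$dq2, max(pt$null_dq2))
  expect_equal(pt$p_dq2, 0)
  # planted markers carry systematically smaller selection p-values
  planted <- pp$x3$features$feature_id %in%
    sim$truth$discriminant$feature_id
  expect_lt(mean(pt$per_feature_p[planted]),
            mean(pt$per_feature_p[!planted]))
  expect_true(all(pt$selected_features %in% pp$x3$features$feature_id))
})
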