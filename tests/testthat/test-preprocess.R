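test_that("replicate collapse takes per-sample medians with zeros included", {
  m <- rbind(c(1, 2, 10, 4, 4, 4),
             c(0, 0, 9, 1, 1, 1))
  tab <- tiny_table(m, c("H1", "H1", "H1", "N1", "N1", "N1"))
  x1 <- collapse_replicates(tab)
  expect_equal(x1$provenance, "X1")
  expect_equal(unname(x1$values["H1", ]), c(2, 0))  # odd-count median; 0 counts
  expect_equal(unname(x1$values["N1", ]), c(4, 1))
  # permutation invariance over replicate order
  perm <- sample(ncol(m))
  tab2 <- tiny_table(m[, perm], c("H1", "H1", "H1", "N1", "N1", "N1")[perm])
  expect_equal(unname(collapse_replicates(tab2)$values[x1$sample_ids, ]),
               unname(x1$values))
})

test_that("blank-feature removal follows the detection rule", {
  # f1 nonzero in 1 blank -> removed at min=1; f2 zero in all blanks -> kept
  m <- rbind(c(5, 5, 5, 2, 0, 0),
             c(3, 3, 3, 0, 0, 0))
  tab <- tiny_table(m, c("H1", "H1", "H1", NA, NA, NA))
  x1 <- collapse_replicates(tab)
  st <- remove_blank_features(x1, tab)
  expect_equal(st$removed_ids, tab$features$feature_id[1])
  expect_equal(ncol(st$matrix$values), 1L)
  expect_equal(st$matrix$provenance, "X2")
  # min_blank_detections = 2 keeps the singly detected feature
  st2 <- remove_blank_features(x1, tab, min_blank_detections = 2L)
  expect_equal(length(st2$removed_ids), 0L)
  # no blanks at all is a configuration error
  tab_nb <- tiny_table(m[, 1:3, drop = FALSE], c("H1", "H1", "H1"))
  expect_error(remove_blank_features(collapse_replicates(tab_nb), tab_nb),
               "blank")
})

test_that("frequency filter removes features seen in fewer than min_samples", {
  vals <- rbind(c(1, 0, 5), c(2, 3, 5), c(0, 0, 5), c(4, 0, 5))
  fm <- feature_matrix(paste0("S", 1:4), rep(c("hypoxia", "normoxia"), 2),
                       data.frame(feature_id = c("a", "b", "c"),
                                  rt = 1:3, mz = c(100, 200, 300)),
                       vals)
  st <- frequency_filter(fm, min_samples = 3L)
  expect_equal(st$removed_ids, "b")          # present in 2 of 4 -> removed
  expect_equal(colnames(st$matrix$values), c("a", "c"))  # 3 of 4 retained
  expect_equal(st$matrix$provenance, "X3")
})

test_that("default synthetic dataset reproduces the reference reductions", {
  sim <- study_shape_fixture(seed = 11)
  pp <- preprocess(sim$table)
  expect_equal(dim(pp$x1$values), c(10L, 365L))
  expect_equal(pp$report$n_removed_blank, 136L)
  expect_equal(dim(pp$x2$values), c(10L, 229L))
  expect_equal(pp$report$n_removed_lowfreq, 117L)
  expect_equal(dim(pp$x3$values), c(10L, 112L))
  expect_equal(ncol(pp$x3$values) / nrow(pp$x3$values), 11.2)
  expect_equal(pp$report$n_features_out,
               pp$report$n_features_in - pp$report$n_removed_blank -
                 pp$report$n_removed_lowfreq)
  # missingness falls from roughly a third to roughly a seventh
  expect_gt(pp$report$missing_fraction_before,
            pp$report$missing_fraction_after)
  expect_lt(abs(pp$report$missing_fraction_before - 0.33), 0.05)
  expect_lt(abs(pp$report$missing_fraction_after - 0.14), 0.05)
})

test_that("autoscaling centers, scales, and is reproducible on held-out rows", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  sc <- autoscale(x)
  expect_equal(unname(colMeans(sc$values)), c(0, 0))
  expect_equal(unname(apply(sc$values, 2, sd)), c(1, 1))
  # stored transform reproduces the scaled columns
  re <- sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
  expect_equal(unname(re), unname(sc$values))
  # column sums vanish
  big <- matrix(rlnorm(200), 10)
  expect_lt(max(abs(colSums(autoscale(big)$values))), 1e-10)
  # zero-variance column errors naming the feature
  expect_error(autoscale(cbind(ok = 1:3, flat = c(2, 2, 2))), "flat")
})

test_that("QC metrics follow their definitions", {
  m <- rbind(c(100, 100, 100), c(50, 60, 70))
  isch <- data.frame(injection_id = paste0("inj", 1:3),
                     area = c(100, 100, 100),
                     mz_measured = rep(609.28729, 3))
  tab <- tiny_table(m, c("H1", "H1", "H1"), is_channel = isch)
  qc <- qc_metrics(tab)
  expect_equal(qc$is_area_rsd, 0)
  expect_equal(qc$is_ppm_errors, rep(10.0, 3), tolerance = 1e-3)
  # identical replicate vectors give r = 1
  m2 <- cbind(c(1, 5, 9), c(1, 5, 9), c(2, 4, 1))
  tab2 <- tiny_table(m2, c("H1", "H1", "N1"))
  qc2 <- qc_metrics(tab2)
  expect_equal(qc2$replicate_correlations$r, 1)
  # no IS channel -> metrics unavailable, not zero
  expect_true(is.na(qc2$is_area_rsd))
})

test_that("synthetic batch QC matches the emulated instrument stability", {
  sim <- study_shape_fixture(seed = 5)
  qc <- qc_metrics(sim$table)
  expect_lt(abs(qc$is_area_rsd - 14), 6)
  expect_true(all(abs(qc$is_ppm_errors) <= 10))
  expect_gt(median(qc$replicate_correlations$r), 0.95)
})
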