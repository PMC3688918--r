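test_that("calibration fitting recovers exact and degenerate lines", {
  conc <- c(19.5, 78, 312.5, 1250, 5000, 10000)
  cal <- fit_calibration(conc, 2 * conc, analyte = "CDP-choline")
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$linear_range, c(19.5, 10000))
  # flat response carries no calibration information
  expect_equal(fit_calibration(conc, rep(7, 6))$r_squared, 0)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  # closed-form least-squares oracle on noisy data
  set.seed(5)
  area <- 3.2 * conc + 40 + rnorm(6, sd = 15)
  cal2 <- fit_calibration(conc, area)
  sxx <- sum((conc - mean(conc))^2)
  slope_hat <- sum((conc - mean(conc)) * (area - mean(area))) / sxx
  expect_equal(cal2$slope, slope_hat, tolerance = 1e-10)
  expect_equal(cal2$intercept, mean(area) - slope_hat * mean(conc),
               tolerance = 1e-10)
})

test_that("quantitation inverts the calibration line and flags range", {
  conc <- c(19.5, 156, 1250, 10000)
  cal <- fit_calibration(conc, 5 * conc + 100)
  at_lo <- quantify(cal, 5 * 19.5 + 100)
  expect_equal(at_lo$concentration_nM, 19.5, tolerance = 1e-9)
  expect_true(at_lo$in_range)  # boundary of the linear range counts
  expect_false(quantify(cal, 5 * 10 + 100)$in_range)
  # round trip through the line
  for (c0 in c(19.5, 500, 10000)) {
    expect_equal(quantify(cal, cal$intercept + cal$slope * c0)$concentration_nM,
                 c0, tolerance = 1e-9)
  }
  expect_equal(quantify(cal, 5 * 50 + 100, dilution = 2)$concentration_nM,
               100, tolerance = 1e-9)
})

test_that("identity confirmation applies the three MRM criteria", {
  ok <- confirm_identity(rt_quant = 2.53, rt_confirm = 2.54,
                         area_quant = 1000, area_confirm = 600,
                         snr_quant = 50, snr_confirm = 20,
                         standard_ratio = 0.5)
  expect_true(ok$ratio_within_25pct)  # 0.6 vs 0.5 is a factor 1.2
  expect_true(ok$confirmed)
  # SNR exactly 9 fails the strictly-greater criterion
  snr9 <- confirm_identity(2.53, 2.54, 1000, 600, 9, 20, 0.5)
  expect_false(snr9$snr_above_9)
  expect_false(snr9$confirmed)
  expect_match(snr9$reason, "SNR")
  # transitions far apart in time fail co-occurrence
  apart <- confirm_identity(2.53, 2.70, 1000, 600, 50, 20, 0.5)
  expect_false(apart$co_occurrence)
  expect_false(apart$confirmed)
  # missing standard ratio leaves criterion ii indeterminate
  nostd <- confirm_identity(2.53, 2.54, 1000, 600, 50, 20, NA)
  expect_true(is.na(nostd$ratio_within_25pct))
  expect_false(nostd$confirmed)
  expect_match(nostd$reason, "standard")
})

test_that("confirmation is monotone: improving a criterion never unconfirms", {
  base <- list(rt_quant = 2.5, rt_confirm = 2.56, area_quant = 1000,
               area_confirm = 700, snr_quant = 9.5, snr_confirm = 9.2,
               standard_ratio = 0.5)
  before <- do.call(confirm_identity, base)
  improved <- base
  improved$rt_confirm <- 2.5       # perfect co-occurrence
  improved$snr_quant <- 100        # better signal
  improved$area_confirm <- 500     # ratio exactly at standard
  after <- do.call(confirm_identity, improved)
  expect_false(before$confirmed && !after$confirmed)
  expect_true(after$confirmed)
})

test_that("tissue concentration conversion is definitional and linear", {
  expect_equal(tissue_concentration(33.3), 1.0)
  expect_equal(tissue_concentration(0), 0)
  expect_equal(tissue_concentration(20), 2 * tissue_concentration(10))
  expect_equal(tissue_concentration(33300, units = "nM"), 1.0)
  expect_error(tissue_concentration(1, tissue_density_mg_ml = 0),
               "positive")
})
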