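test_that("z-scores interpolate the reference mean and SD in age", {
  ref <- gen_growth_reference()
  hc <- growth_reference("head_circumference_cm",
                         ref[ref$measure == "head_circumference_cm", ])
  row <- hc[hc$sex == "M", ][3, ]
  expect_equal(growth_zscore(row$mean, "M", row$age_months, hc), 0)
  expect_equal(growth_zscore(row$mean + 1.5 * row$sd, "M", row$age_months, hc),
               1.5)
  # midway between two tabulated ages, value = average of the two means
  two <- hc[hc$sex == "F", ][4:5, ]
  mid_age <- mean(two$age_months)
  expect_equal(growth_zscore(mean(two$mean), "F", mid_age, hc), 0)
  # hand-interpolated z at the midpoint
  v <- mean(two$mean) + 0.8 * mean(two$sd)
  expect_equal(growth_zscore(v, "F", mid_age, hc), 0.8, tolerance = 1e-10)
})

test_that("z-scores clamp mild age overshoot and reject the rest", {
  tab <- flat_reference("height_cm", 100, 5)
  expect_equal(growth_zscore(105, "M", 206, tab), 1)  # clamped to 204
  expect_error(growth_zscore(105, "M", 215, tab), "clamp")
  expect_error(growth_zscore(105, "X", 60, tab), "absent")
  expect_error(growth_zscore(-1, "M", 60, tab), "positive")
})

test_that("percentile transform is the normal CDF, symmetric and invertible", {
  expect_equal(percentile_from_z(0), 50)
  # erf-based oracle for the 1.5 SD cutoff percentile
  erf_cdf <- function(z) 0.5 * (1 + pracma::erf(z / sqrt(2)))
  expect_equal(percentile_from_z(1.5), 100 * erf_cdf(1.5), tolerance = 1e-4)
  z <- seq(-4.5, 4.5, by = 0.37)
  expect_equal(percentile_from_z(z) + percentile_from_z(-z), rep(100, length(z)))
  expect_true(all(diff(percentile_from_z(seq(-5, 5, by = 0.01))) > 0))
  expect_equal(z_from_percentile(percentile_from_z(z)), z, tolerance = 1e-6)
})

test_that("head-size calls apply the three printed subtype rules", {
  hc <- flat_reference("head_circumference_cm", 50, 2)
  ht <- flat_reference("height_cm", 100, 5)
  mk <- function(hc_z, ht_z) data.frame(
    proband_id = "p", sex = "M", age_months = 60,
    head_circumference_cm = 50 + hc_z * 2, height_cm = 100 + ht_z * 5)
  # hc pct 95.5 / ht pct 95.3: somatic overgrowth
  so <- call_head_size(mk(1.7, z_from_percentile(92)), hc, ht)
  expect_true(so$macrocephaly)
  expect_identical(so$subtype, "SO")
  # hc pct 94 / ht pct 50: ratio 0.532, disproportionate
  dm <- call_head_size(mk(z_from_percentile(94), 0), hc, ht)
  expect_identical(dm$subtype, "DMac")
  expect_equal(dm$ratio, 50 / 94, tolerance = 1e-6)
  # boundary: z exactly 1.5 is not macrocephalic (strict inequality)
  at <- call_head_size(mk(1.5, 0), hc, ht)
  expect_false(at$macrocephaly)
  expect_identical(at$subtype, "none")
  # ratio above the 0.7 cutoff is relative macrocephaly, and the documented
  # boundary assignment (ratio == 0.7 -> RM) is stamped into the output rules
  rm_ <- call_head_size(mk(z_from_percentile(95),
                           z_from_percentile(0.75 * 95)), hc, ht)
  expect_identical(rm_$subtype, "RM")
  expect_identical(attr(rm_, "rules")$ratio_boundary_class, "RM")
  # missing measurement: NA fields plus warning
  miss <- mk(1.7, 0); miss$height_cm <- NA
  expect_warning(res <- call_head_size(miss, hc, ht), "missing")
  expect_true(is.na(res$subtype))
  expect_identical(attr(res, "warnings"), "p")
})

test_that("classifier matches brute-force rule re-application and partitions", {
  hc <- flat_reference("head_circumference_cm", 50, 2)
  ht <- flat_reference("height_cm", 100, 5)
  set.seed(42)
  n <- 2000
  hc_z <- runif(n, -3, 4); ht_z <- runif(n, -3, 4)
  anthro <- data.frame(proband_id = sprintf("p%04d", 1:n), sex = "F",
                       age_months = 120,
                       head_circumference_cm = 50 + hc_z * 2,
                       height_cm = 100 + ht_z * 5)
  calls <- call_head_size(anthro, hc, ht)
  expected <- mapply(oracle_subtype, calls$hc_z, calls$hc_percentile,
                     calls$height_percentile)
  expect_identical(calls$subtype, unname(expected))
  expect_true(all((calls$subtype != "none") == calls$macrocephaly))
})

test_that("megalencephaly is a strict 1.5 SD exceedance of the CV/height ratio", {
  rt <- flat_reference("cv_height_ratio", 12, 0.8)
  mk <- function(ratio_z) data.frame(
    proband_id = "p", sex = "F", age_months = 100, height_cm = 100,
    cerebral_volume_cm3 = (12 + ratio_z * 0.8) * 100)
  expect_false(as.logical(call_megalencephaly(mk(0), rt)))
  expect_true(as.logical(call_megalencephaly(mk(2), rt)))
  # cohort drawn from the reference distribution: tail fraction ~ P(Z > 1.5)
  set.seed(7)
  z <- rnorm(10000)
  coh <- data.frame(proband_id = sprintf("p%05d", seq_along(z)), sex = "M",
                    age_months = 100, height_cm = 100,
                    cerebral_volume_cm3 = (12 + z * 0.8) * 100)
  frac <- mean(as.logical(call_megalencephaly(coh, rt)))
  expect_lt(abs(frac - pnorm(1.5, lower.tail = FALSE)), 0.01)
})

test_that("expression outliers exceed the population mean by > 3 SD", {
  set.seed(1)
  popn <- rnorm(30, 100, 10)
  expect_false(as.logical(zscore_outlier(mean(popn), popn)))
  expect_true(as.logical(zscore_outlier(mean(popn) + 3.1 * sd(popn), popn)))
  vals <- rnorm(100, 100, 10)
  direct <- (vals - mean(popn)) / sd(popn) > 3
  got <- vapply(vals, zscore_outlier, logical(1), population = popn)
  expect_identical(unname(got), direct)
  expect_error(zscore_outlier(1, rep(5, 10)), "variance")
  expect_error(zscore_outlier(1, c(1, 2)), ">= 3")
})
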