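test_that("Pearson correlation and interpretation bands", {
  a <- c(1.2, 2.1, 2.9, 3.8, 5.0)
  expect_equal(pearson_with_band(a, a)$r, 1)
  expect_equal(pearson_with_band(a, a)$band, "very strong")
  neg <- pearson_with_band(a, -a)
  expect_equal(neg$r, -1)
  expect_equal(neg$band, "very strong") # band applied to |r|
  expect_equal(pearson_with_band(c(1, 2, 3), c(2, 3, 5))$r, 0.9820,
               tolerance = 1e-4)
  expect_equal(correlation_band(c(0.95, 0.8, 0.6, 0.4, 0.1)),
               c("very strong", "strong", "moderate", "weak", "very weak"))
})

test_that("Bland-Altman bias, LoA and equivariance", {
  a <- c(1, 2, 3)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  b <- c(1, 2, 3)
  ba <- bland_altman(b + c(0.1, 0.2, 0.3), b)
  expect_equal(ba$bias, 0.2)
  expect_equal(ba$sd_diff, 0.1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0.004, 0.396))
  # LoA identity and translation equivariance
  set.seed(12)
  x <- rnorm(40, 10); y <- rnorm(40, 10)
  r1 <- bland_altman(x, y)
  expect_equal(r1$loa_lower, r1$bias - 1.96 * r1$sd_diff, tolerance = 1e-9)
  expect_equal(r1$loa_upper, r1$bias + 1.96 * r1$sd_diff, tolerance = 1e-9)
  r2 <- bland_altman(x + 5, y)
  expect_equal(r2$bias, r1$bias + 5, tolerance = 1e-9)
  expect_equal(r2$loa_upper, r1$loa_upper + 5, tolerance = 1e-9)
  expect_error(bland_altman(1:2, 2:3), class = "lp_insufficient_data")
})

test_that("paired t-test: hand value, degenerate case, scale invariance", {
  b <- c(5, 6, 7)
  tt <- paired_t(b + c(0.1, 0.2, 0.3), b)
  expect_equal(tt$t_stat, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$df, 2)
  ident <- paired_t(b, b)
  expect_equal(c(ident$t_stat, ident$p_value), c(0, 1))
  set.seed(23)
  x <- rnorm(20, 3); y <- rnorm(20, 3)
  expect_equal(paired_t(10 * x, 10 * y)$t_stat, paired_t(x, y)$t_stat,
               tolerance = 1e-9)
})

test_that("paired Cohen's d: hand value, bands, degenerate zero variance", {
  b <- c(5, 6, 7)
  cd <- cohens_d(b + c(0.1, 0.2, 0.3), b)
  expect_equal(cd$d, 2)
  expect_equal(cd$band, "large")
  expect_warning(deg <- cohens_d(b + 1, b), class = "lp_degenerate_data")
  expect_true(is.na(deg$d))
  expect_equal(effect_size_band(c(0.1, 0.3, 0.6, 0.85, -0.85)),
               c("negligible", "small", "medium", "large", "large"))
  # affine unit change: d is invariant under common positive rescaling
  set.seed(34)
  x <- rnorm(15, 2, 0.4); y <- rnorm(15, 2, 0.4)
  expect_equal(cohens_d(3 * x, 3 * y)$d, cohens_d(x, y)$d, tolerance = 1e-9)
})

test_that("cross-table effect sizes reproduce published values from bias and LoA", {
  tab <- cohens_d_from_loa(vbt_agreement_summaries())
  # the pooled mean-power row is fully determined by its printed summary
  all_mp <- tab[tab$load == "all" & tab$indicator == "mean_power", ]
  expect_equal(round(all_mp$d_from_loa, 2), -0.14)
  expect_equal(round(all_mp$d_from_loa, 2), all_mp$cohens_d)
})

test_that("Deming regression: exact line, swap symmetry, OLS attenuation direction", {
  x <- c(0, 1, 2, 3, 4)
  fit <- deming(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  set.seed(45)
  a <- rnorm(30, 5); b <- 1.3 * a + rnorm(30, 0, 0.3)
  s_ab <- deming(a, b)$slope
  s_ba <- deming(b, a)$slope
  expect_equal(s_ab, 1 / s_ba, tolerance = 1e-9) # lambda = 1 symmetry
  # when x is noisy, OLS attenuates; Deming corrects upward
  xn <- a + rnorm(30, 0, 0.5)
  yn <- 1.3 * a
  ols <- unname(coef(lm(yn ~ xn))[2])
  expect_gte(deming(xn, yn)$slope, ols)
  expect_error(deming(c(1, 1, 1), c(1, 2, 3)), class = "lp_degenerate_data")
})

test_that("Deming at lambda = 1 equals the numeric perpendicular-residual minimiser", {
  set.seed(56)
  for (i in 1:100) {
    x <- rnorm(20, 5, 2)
    y <- 0.8 * x + rnorm(20, 0, 1)
    expect_equal(deming(x, y)$slope, oracle_tls_slope(x, y), tolerance = 1e-6)
  }
})

test_that("jackknife CIs cover a known slope at roughly the nominal rate", {
  set.seed(67)
  covered <- purrr::map_lgl(1:200, function(i) {
    t_true <- rnorm(50, 5, 1.5)
    x <- t_true + rnorm(50, 0, 0.4)
    y <- 1.1 * t_true + rnorm(50, 0, 0.4)
    fit <- deming(x, y)
    fit$slope_lo <= 1.1 && 1.1 <= fit$slope_hi
  })
  expect_gte(mean(covered), 0.90)
})

test_that("agreement report: identical methods are fully concordant with no flags", {
  d <- tibble::tibble(a = c(1.5, 2.5, 3.1, 4.7, 5.2), b = c(1.5, 2.5, 3.1, 4.7, 5.2))
  rep <- suppressWarnings(agreement_report(d, a, b))
  expect_equal(rep$pearson$r, 1)
  expect_equal(rep$bland_altman$bias, 0)
  expect_equal(rep$deming$slope, 1, tolerance = 1e-12)
  expect_false(rep$fixed_bias)
  expect_false(rep$proportional_bias)
  g <- glance(rep)
  expect_equal(g$loa_lower, g$bias - 1.96 * g$sd_diff, tolerance = 1e-9)
  td <- tidy(rep)
  expect_setequal(
    td$term,
    c("pearson_r", "bias", "loa_lower", "loa_upper", "t_stat", "p_value",
      "cohens_d", "deming_slope", "deming_intercept"))
})

test_that("radius-bias pairs raise the proportional-bias flag with slope near 2.20/2.05", {
  pm <- simulate_paired_methods(n_trials = 500, seed = 78)
  rep <- agreement_report(pm, method_a, method_b)
  expect_true(rep$proportional_bias)
  expect_equal(rep$deming$slope, 2.20 / 2.05, tolerance = 0.05)
  # CI covers the generator truth here
  expect_true(rep$deming$slope_lo <= 2.20 / 2.05 &&
                2.20 / 2.05 <= rep$deming$slope_hi)
})

test_that("grouped agreement summaries return one row per group", {
  pm1 <- simulate_paired_methods(n_trials = 60, seed = 89)
  pm2 <- simulate_paired_methods(n_trials = 60, noise_a = 0.05,
                                 noise_b = 0.05, seed = 90)
  both <- dplyr::bind_rows(
    dplyr::mutate(pm1, load = "20kg"),
    dplyr::mutate(pm2, load = "35kg"))
  out <- agreement_by(both, method_a, method_b, load)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$load, c("20kg", "35kg"))
  expect_true(all(out$deming_slope > 1))
})
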