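test_that("median-effect fitting is exact on noise-free curves", {
  dr <- simulate_dose_response(m = 1, dm = 1, doses = c(0.25, 0.5, 1, 2, 4))
  fit <- fit_median_effect(dr)
  expect_equal(fit$m, 1, tolerance = 1e-10)
  expect_equal(fit$dm, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # fa predicted at Dm is 0.5 by definition
  lg <- fit$m * (log10(fit$dm) - log10(fit$dm))
  expect_equal(10^lg / (1 + 10^lg), 0.5)

  dr2 <- simulate_dose_response(m = 2.5, dm = 0.3, doses = c(0.1, 0.3, 0.9))
  fit2 <- fit_median_effect(dr2)
  expect_equal(fit2$m, 2.5, tolerance = 1e-10)
  expect_equal(fit2$dm, 0.3, tolerance = 1e-10)
})

test_that("three-point fits match the closed-form least squares solution", {
  doses <- c(0.5, 1, 4); fa <- c(0.3, 0.55, 0.8)
  x <- log10(doses); y <- log10(fa / (1 - fa))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  fit <- fit_median_effect(list(doses = doses, fa = fa))
  expect_equal(fit$m, slope, tolerance = 1e-12)
  expect_equal(fit$dm, 10^(-intercept / slope), tolerance = 1e-12)
})

test_that("degenerate fractions are excluded before fitting", {
  expect_error(fit_median_effect(list(doses = c(1, 2), fa = c(0, 1))),
               "insufficient")
  fit <- fit_median_effect(list(doses = c(0.5, 1, 2, 4), fa = c(0, 0.4, 0.6, 0.9)))
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$n_used, 3)
})

test_that("effective doses follow Dx = Dm (fa/(1-fa))^(1/m)", {
  fit <- fit_median_effect(simulate_dose_response(1, 2, c(0.5, 2, 8)))
  expect_equal(effective_dose(fit, 0.5), 2, tolerance = 1e-10)
  expect_equal(effective_dose(fit, 0.75), 6, tolerance = 1e-10)
  # round trip: fa at the effective dose returns fa
  for (fa in c(0.1, 0.37, 0.9)) {
    dx <- effective_dose(fit, fa)
    lg <- fit$m * (log10(dx) - log10(fit$dm))
    expect_equal(10^lg / (1 + 10^lg), fa, tolerance = 1e-12)
  }
  expect_error(effective_dose(fit, 1), "inside")
})

test_that("combination index reproduces the additive and synergy identities", {
  fit1 <- fit_median_effect(simulate_dose_response(1, 1, c(0.25, 1, 4)))
  fit2 <- fit_median_effect(simulate_dose_response(2, 3, c(1, 3, 9)))
  # complementary fractional effective doses are exactly additive
  for (alpha in c(0, 0.25, 0.5, 0.8, 1)) {
    fa <- 0.6
    res <- combination_index(fit1, fit2,
                             d1 = alpha * effective_dose(fit1, fa),
                             d2 = (1 - alpha) * effective_dose(fit2, fa),
                             fa_combo = fa)
    expect_equal(res$ci, 1, tolerance = 1e-9)
    expect_equal(res$call, "additive")
  }
  # single-drug consistency
  res1 <- combination_index(fit1, fit2, d1 = effective_dose(fit1, 0.4),
                            d2 = 0, fa_combo = 0.4)
  expect_equal(res1$ci, 1, tolerance = 1e-9)
  # hand-computed synergy: both drugs m=1, Dm=1, quarter doses at fa=0.5
  fitA <- fit_median_effect(simulate_dose_response(1, 1, c(0.5, 1, 2)))
  resS <- combination_index(fitA, fitA, 0.25, 0.25, 0.5)
  expect_equal(resS$ci, 0.5, tolerance = 1e-9)
  expect_equal(resS$call, "synergism")
  expect_error(combination_index(fit1, fit2, 0, 0, 0.5), "zero")
})

test_that("combination index is invariant to rescaling the dose axes", {
  c_ <- 7.3
  fit1 <- fit_median_effect(simulate_dose_response(1.4, 2, c(0.5, 2, 8)))
  fit1s <- fit_median_effect(simulate_dose_response(1.4, 2 * c_, c_ * c(0.5, 2, 8)))
  fit2 <- fit_median_effect(simulate_dose_response(0.8, 5, c(1, 5, 25)))
  fit2s <- fit_median_effect(simulate_dose_response(0.8, 5 * c_, c_ * c(1, 5, 25)))
  a <- combination_index(fit1, fit2, 1.1, 2.3, 0.45)
  b <- combination_index(fit1s, fit2s, c_ * 1.1, c_ * 2.3, 0.45)
  expect_equal(a$ci, b$ci, tolerance = 1e-9)
})

test_that("t-test power has the right size, monotonicity and limits", {
  expect_equal(power_two_sample_t(10, 0, 1, 0.05), 0.05, tolerance = 1e-10)
  pw <- vapply(c(4, 8, 16, 32, 64), function(n)
    power_two_sample_t(n, 0.5, 1, 0.05), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(power_two_sample_t(2000, 0.2, 1, 0.05), 0.999)
  # agreement with the stats reference (which drops the far-tail term)
  expect_equal(power_two_sample_t(15, 0.4, 0.9, 0.05),
               power.t.test(n = 15, delta = 0.4, sd = 0.9,
                            sig.level = 0.05)$power,
               tolerance = 1e-2)
})

test_that("population doubling time counts doublings of exponential growth", {
  expect_equal(population_doubling_time(1e5, 2e5, 36), 36)
  expect_equal(population_doubling_time(1e5, 4e5, 36), 18)
  expect_equal(population_doubling_time(4e5, 1.6e6, 48), 24)
  expect_error(population_doubling_time(1e5, 9e4, 24), "no net growth")
})

test_that("tumour volume is the ellipsoid formula with argument correction", {
  d <- 4
  expect_equal(tumour_volume(d, d), pi / 6 * d^3)
  expect_equal(tumour_volume(10, 5), pi / 6 * 250)
  expect_warning(v <- tumour_volume(5, 10), "swapped")
  expect_equal(v, pi / 6 * 250)
  expect_equal(tumour_volume(10, 6) / tumour_volume(10, 3), 4)
})
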