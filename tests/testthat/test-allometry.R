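test_that("a noiseless power-law cohort is recovered to machine precision", {
  L <- seq(4, 14, length.out = 25)
  d <- tibble::tibble(total_length = L, body_weight = 0.0046 * L^3.03)
  fit <- fit_lwr(d)
  expect_equal(fit$a, 0.0046, tolerance = 1e-10)
  expect_equal(fit$b, 3.03, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("power-law fitting validates its input", {
  expect_error(fit_lwr(tibble::tibble(total_length = c(4, 8), body_weight = c(1, 2))),
               "at least 3")
  expect_error(fit_lwr(tibble::tibble(total_length = c(4, 4, 4), body_weight = c(1, 2, 3))),
               "zero variance")
  expect_error(fit_lwr(tibble::tibble(total_length = c(4, -8, 9), body_weight = c(1, 2, 3))),
               "strictly positive")
})

test_that("the exponent is scale covariant: L -> cL, W -> c^b W leaves b unchanged", {
  coh <- simulate_cohort(cohort_config(n_fish = 60), seed = 17)
  base <- fit_lwr(coh)
  for (c_fac in c(0.1, 2.5, 10)) {
    scaled <- dplyr::mutate(coh,
      total_length = total_length * c_fac,
      body_weight = body_weight * c_fac^base$b
    )
    expect_equal(fit_lwr(scaled)$b, base$b, tolerance = 1e-10)
  }
})

test_that("the fitted exponent is unbiased over replicate cohorts", {
  bs <- vapply(1:150, function(i) fit_lwr(simulate_cohort(seed = 100 + i))$b,
               numeric(1))
  mcse <- sd(bs) / sqrt(length(bs))
  expect_lt(abs(mean(bs) - 3.03), 3 * mcse)
})

test_that("the isometry test matches t-distribution arithmetic", {
  fit <- structure(list(b = 3.2, se_b = 0.1, n = 102), class = "lwr_fit")
  res <- test_isometry(fit)
  expect_equal(res$t_statistic, 2.0, tolerance = 1e-12)
  expect_equal(res$df, 100)
  expect_equal(res$p_value, 2 * pt(2, 100, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.048)

  # exactly at the reference the P-value is exactly 1
  fit$b <- 3
  expect_equal(test_isometry(fit)$p_value, 1)

  # P decreases strictly as the exponent moves away from the reference
  ps <- vapply(seq(3, 3.5, by = 0.05), function(b) {
    fit$b <- b
    test_isometry(fit)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  fit$se_b <- 0
  expect_error(test_isometry(fit), "degenerate")
})

test_that("a zero-noise isometric cohort recovers the isometric exponent", {
  coh <- simulate_cohort(zero_noise_config(lwr_b = 3), seed = 19)
  fit <- fit_lwr(coh)
  # the fitted exponent is 3 to floating tolerance; the t-ratio itself is a
  # 0/0-scale quantity on noiseless data, so the estimate is what is checked
  expect_equal(fit$b, 3, tolerance = 1e-8)
  expect_lt(fit$se_b, 1e-8)
})

test_that("sex-covariate tests are exact zeros for duplicated groups and
           roughly calibrated under the null", {
  coh <- simulate_cohort(cohort_config(n_fish = 40), seed = 23)
  adults <- dplyr::filter(coh, sex_class != "juvenile")
  females <- dplyr::mutate(adults, sex_class = factor("female", levels = levels(adults$sex_class)))
  males <- dplyr::mutate(adults, sex_class = factor("male", levels = levels(adults$sex_class)))
  res <- test_sex_effect(dplyr::bind_rows(females, males))
  expect_equal(res$estimate, c(0, 0), tolerance = 1e-12)

  # type-I calibration at alpha = 0.05 over null replicates
  hits <- vapply(1:150, function(i) {
    coh <- simulate_cohort(cohort_config(n_fish = 80), seed = 3000 + i)
    any(test_sex_effect(coh)$p_value[1] < 0.05)
  }, logical(1))
  expect_lt(mean(hits), 0.11)

  # power: a genuine exponent difference of 0.5 is detected
  power_hits <- vapply(1:60, function(i) {
    f <- simulate_cohort(cohort_config(n_fish = 30, lwr_b = 3.0, maturity_age = 0,
                                       sex_ratio = 1, weight_lognoise_sd = 0.05),
                         seed = 4000 + i)
    m <- simulate_cohort(cohort_config(n_fish = 30, lwr_b = 3.5, maturity_age = 0,
                                       sex_ratio = 0, weight_lognoise_sd = 0.05),
                         seed = 5000 + i)
    both <- dplyr::bind_rows(f, m)
    both$fish_id <- paste0(both$fish_id, rep(c("f", "m"), each = 30))
    test_sex_effect(both)$p_value[1] < 0.05
  }, logical(1))
  expect_gt(mean(power_hits), 0.9)

  expect_error(test_sex_effect(dplyr::filter(coh, sex_class != "male")), ">= 3 fish per sex")
})

test_that("trend fits equal the closed-form normal-equation solution", {
  for (i in 1:10) {
    set.seed(800 + i)
    d <- tibble::tibble(total_length = runif(20, 4, 14),
                        lipid = rnorm(20, 100, 30))
    fit <- fit_trend(d, "lipid")
    ref <- normal_equation_line(d$total_length, d$lipid)
    expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  }
})

test_that("exact lines and constants produce the expected degenerate trends", {
  L <- seq(4, 14, length.out = 30)
  exact <- tibble::tibble(total_length = L, lipid = 20 + 11.3 * L)
  fit <- fit_trend(exact, "lipid")
  expect_equal(fit$slope, 11.3, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- tibble::tibble(total_length = L, ash = rep(120, 30))
  flat_fit <- fit_trend(flat, "ash")
  expect_equal(flat_fit$slope, 0, tolerance = 1e-12)
  expect_equal(flat_fit$r_squared, 0)
})

test_that("slope comparisons match hand arithmetic and stay calibrated", {
  L <- seq(4, 14, length.out = 30)
  set.seed(42)
  f1 <- fit_trend(tibble::tibble(total_length = L, lipid = 20 + 11.3 * L + rnorm(30, 0, 20)), "lipid")
  f2 <- fit_trend(tibble::tibble(total_length = L, ash = 120 + rnorm(30, 0, 20)), "ash")
  res <- compare_trend_slopes(f1, f2)
  expect_equal(res$df, 56)
  expect_equal(res$t_statistic,
               (f2$slope - f1$slope) / sqrt(f1$se_slope^2 + f2$se_slope^2),
               tolerance = 1e-12)

  # identical fits: t exactly 0, P exactly 1
  same <- compare_trend_slopes(f1, f1)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # hand-arithmetic check: slopes 11.3 vs 0 with unit SEs, n = 30 each
  mk <- function(slope, se) structure(list(slope = slope, se_slope = se, n = 30),
                                      class = "linear_fit")
  hand <- compare_trend_slopes(mk(11.3, 1), mk(0, 1))
  expect_equal(hand$t_statistic, -11.3 / sqrt(2), tolerance = 1e-12)
  expect_lt(hand$p_value, 1e-9)

  # two samples from one generating line: nonsignificant at about nominal rate
  hits <- vapply(1:150, function(i) {
    set.seed(6000 + i)
    d1 <- tibble::tibble(total_length = runif(25, 4, 14))
    d2 <- tibble::tibble(total_length = runif(25, 4, 14))
    d1$lipid <- 20 + 5 * d1$total_length + rnorm(25, 0, 15)
    d2$lipid <- 20 + 5 * d2$total_length + rnorm(25, 0, 15)
    compare_trend_slopes(fit_trend(d1, "lipid"), fit_trend(d2, "lipid"))$p_value < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.11)
})

test_that("the paired slope comparison detects same-individual slope differences", {
  L <- seq(4, 14, length.out = 30)
  set.seed(7)
  d <- tibble::tibble(
    total_length = L,
    lipid = 20 + 11.3 * L + rnorm(30, 0, 5),
    ash = 120 - 0.5 * L + rnorm(30, 0, 5)
  )
  res <- compare_trend_slopes_paired(d, "lipid", "ash")
  expect_equal(res$df, 28)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$method, "paired (difference-series) slope t")
})
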