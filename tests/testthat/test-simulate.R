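test_that("zero-noise cohorts lie exactly on the generating curves", {
  coh <- simulate_cohort(zero_noise_config(n_fish = 40), seed = 1)
  expect_equal(coh$total_length,
               vbgf_predict(coh$age, 23.4, 0.060, 0.12), tolerance = 1e-12)
  expect_equal(coh$body_weight, 0.0046 * coh$total_length^3.03, tolerance = 1e-12)
})

test_that("generators are pure functions of (config, seed)", {
  a <- simulate_cohort(cohort_config(), seed = 99)
  b <- simulate_cohort(cohort_config(), seed = 99)
  expect_identical(a, b)
  expect_false(identical(a$total_length,
                         simulate_cohort(cohort_config(), seed = 100)$total_length))

  ra <- simulate_readings(a, seed = 5)
  rb <- simulate_readings(b, seed = 5)
  expect_identical(ra, rb)

  ca <- simulate_composition(a, seed = 6)
  expect_identical(ca, simulate_composition(a, seed = 6))

  ta <- simulate_tree(12, seed = 7)
  expect_identical(ape::write.tree(ta), ape::write.tree(simulate_tree(12, seed = 7)))

  sa <- simulate_species_set(species_sim_config(), seed = 8)
  expect_identical(sa, simulate_species_set(species_sim_config(), seed = 8))
})

test_that("cohort structure follows the config: sex classes, ranges, redraws", {
  cfg <- cohort_config(n_fish = 300, maturity_age = 4.8, sex_ratio = 0.5)
  coh <- simulate_cohort(cfg, seed = 11)
  expect_true(all(coh$age >= 3.3 & coh$age <= 15.8))
  expect_true(all(coh$total_length > 0))
  expect_identical(as.character(coh$sex_class[coh$age < 4.8]),
                   rep("juvenile", sum(coh$age < 4.8)))
  expect_true(all(coh$sex_class[coh$age >= 4.8] %in% c("female", "male")))

  # a config whose expected length is non-positive at the youngest age fails
  expect_error(cohort_config(t0 = 4, age_range = c(3.3, 15.8)),
               "non-positive expected length")
})

test_that("cohorts at the default parameters bracket the observed study range", {
  # lengths 3.9-14.3 cm in most seeds: check a generous bracket across seeds
  covered <- vapply(1:20, function(s) {
    r <- range(simulate_cohort(cohort_config(), seed = s)$total_length)
    r[1] < 5 && r[2] > 12
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("reading sets respect n_reads, structure SDs, flooring and rounding", {
  coh <- simulate_cohort(cohort_config(n_fish = 50), seed = 2)
  rd <- simulate_readings(coh, n_reads = 3, seed = 3)
  expect_equal(nrow(rd), 50 * 3 * 2)
  expect_setequal(unique(rd$structure), c("otolith", "vertebra"))
  expect_true(all(rd$reading > 0))

  noiseless <- simulate_readings(coh, otolith_sd = 0, vertebra_sd = 0, seed = 4)
  expect_equal(age_precision(noiseless)$ape_percent, c(0, 0))
  expect_equal(age_precision(noiseless)$acv_percent, c(0, 0))

  ints <- simulate_readings(coh, rounding = "nearest_integer", seed = 5)
  expect_true(all(ints$reading == round(ints$reading)))
  expect_true(all(ints$reading >= 1))

  expect_error(simulate_readings(coh, otolith_sd = -1, seed = 6), "otolith_sd")
  expect_error(simulate_readings(coh, n_reads = 1, seed = 6), "n_reads")
})

test_that("lower otolith reading error yields lower otolith ACV (Monte Carlo)", {
  coh <- simulate_cohort(cohort_config(n_fish = 1000), seed = 21)
  rd <- simulate_readings(coh, otolith_sd = 0.5, vertebra_sd = 0.8, seed = 22)
  prec <- age_precision(rd)
  expect_lt(prec$acv_percent[prec$structure == "otolith"],
            prec$acv_percent[prec$structure == "vertebra"])
  expect_lt(prec$ape_percent[prec$structure == "otolith"],
            prec$ape_percent[prec$structure == "vertebra"])
})

test_that("zero-sd composition reproduces its generating lines to machine precision", {
  coh <- simulate_cohort(cohort_config(n_fish = 30), seed = 8)
  tr <- composition_trends(
    protein = c(150, -1, 0), lipid = c(-13, 11.3, 0),
    glycogen = c(15, -0.3, 0), ash = c(35, -0.5, 0)
  )
  cmp <- simulate_composition(coh, tr, seed = 9)
  for (spec in list(c("lipid", 11.3), c("protein", -1), c("ash", -0.5))) {
    fit <- fit_trend(cmp, spec[1])
    expect_equal(fit$slope, as.numeric(spec[2]), tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("a zero ash slope gives a nonsignificant trend at about the nominal rate", {
  zero_tr <- composition_trends(ash = c(120, 0, 25))
  hits0 <- vapply(1:200, function(i) {
    coh <- simulate_cohort(cohort_config(n_fish = 30), seed = 600 + i)
    cmp <- simulate_composition(coh, zero_tr, seed = 11000 + i)
    fit_trend(cmp, "ash")$p_slope < 0.05
  }, logical(1))
  expect_lt(mean(hits0), 0.12)  # ~5% nominal, binomial slack at 200 reps
})

test_that("truncation at zero is counted, and can be disabled", {
  coh <- simulate_cohort(cohort_config(n_fish = 200), seed = 12)
  tr <- composition_trends(glycogen = c(1, 0, 10))
  expect_warning(
    cmp <- simulate_composition(coh,
                                composition_trends(glycogen = c(5, -1, 0)),
                                seed = 13),
    "negative"
  )
  cmp2 <- simulate_composition(coh, tr, seed = 14)
  expect_gt(attr(cmp2, "n_truncated"), 0)
  expect_true(all(cmp2$glycogen >= 0))
  raw <- simulate_composition(coh, tr, seed = 14, truncate = "none")
  expect_true(any(raw$glycogen < 0))
  expect_equal(attr(raw, "n_truncated"), 0L)
})

test_that("species sets recover their generating allometry when noiseless", {
  sp <- simulate_species_set(species_sim_config(n_species = 12, residual_sd = 0),
                             seed = 15)
  fit <- fit_loglog_allometry(sp)
  expect_equal(fit$slope, -1.64, tolerance = 1e-10)
  expect_equal(fit$intercept, 1.09, tolerance = 1e-10)
  expect_equal(sp$phi_prime, log10(sp$K) + 2 * log10(sp$L_inf), tolerance = 1e-12)
})

test_that("tree-evolved residuals need a matching tree", {
  cfg <- species_sim_config(n_species = 10, evolve_on_tree = TRUE)
  expect_error(simulate_species_set(cfg, seed = 1), "tree.*required")
  expect_error(
    simulate_species_set(cfg, seed = 1, tree = simulate_tree(5, seed = 2)),
    "5 tips"
  )
  sp <- simulate_species_set(cfg, seed = 1, tree = simulate_tree(10, seed = 2))
  expect_equal(nrow(sp), 10)
})

test_that("Yule trees are binary with positive branch lengths", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2)
  expect_true(all(tr2$edge.length > 0))
  tr50 <- simulate_tree(50, seed = 2)
  expect_equal(tr50$Nnode, 49)  # 49 internal bifurcations for 50 tips
  expect_true(all(tr50$edge.length > 0))
  expect_error(simulate_tree(1, seed = 3), "n_taxa")
})

test_that("more length noise never helps the growth-curve fit (monotone error)", {
  med_err <- vapply(c(0.2, 0.6, 1.2), function(s) {
    errs <- vapply(1:60, function(i) {
      coh <- simulate_cohort(cohort_config(length_noise_sd = s), seed = 7000 + i)
      abs(fit_vbgf(coh)$estimate[["L_inf"]] - 23.4)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
})
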