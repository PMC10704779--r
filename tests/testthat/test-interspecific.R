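test_that("the cross-species allometry fit matches the normal equations", {
  for (i in 1:10) {
    set.seed(900 + i)
    sp <- tibble::tibble(
      species = paste0("s", 1:8),
      L_inf = 10^runif(8, 0.8, 1.5),
      K = 10^rnorm(8, -0.8, 0.3)
    )
    fit <- fit_loglog_allometry(sp)
    ref <- normal_equation_line(log10(sp$L_inf), log10(sp$K))
    expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  }
  # collinear species are a perfect fit
  col <- tibble::tibble(species = c("a", "b", "c"),
                        L_inf = c(10, 15, 20), K = 10^(1 - 2 * log10(c(10, 15, 20))))
  expect_equal(fit_loglog_allometry(col)$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_loglog_allometry(col[1:2, ]), "at least 3")
})

test_that("PGLS at lambda = 0 and on a star tree reproduces OLS exactly", {
  sp <- simulate_species_set(species_sim_config(n_species = 12, residual_sd = 0.1),
                             seed = 41)
  ols <- fit_loglog_allometry(sp)

  tree <- simulate_tree(12, seed = 42)
  sp$species <- tree$tip.label
  fixed0 <- fit_pgls(sp, tree, lambda = 0)
  expect_equal(fixed0$slope, ols$slope, tolerance = 1e-10)
  expect_equal(fixed0$intercept, ols$intercept, tolerance = 1e-10)
  expect_equal(fixed0$r_squared, ols$r_squared, tolerance = 1e-10)

  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:1", sp$species), collapse = ","), ");"
  ))
  for (lam in c(0, 0.5, 1, "ML")) {
    fstar <- fit_pgls(sp, star, lambda = if (identical(lam, "ML")) "ML" else as.numeric(lam))
    expect_equal(fstar$slope, ols$slope, tolerance = 1e-10)
    expect_equal(fstar$intercept, ols$intercept, tolerance = 1e-10)
  }
})

test_that("the GLS estimator agrees with brute-force matrix inversion", {
  for (i in 1:5) {
    tree <- simulate_tree(10, seed = 50 + i)
    sp <- simulate_species_set(
      species_sim_config(n_species = 10, evolve_on_tree = TRUE, residual_sd = 0.15),
      seed = 60 + i, tree = tree
    )
    lam <- c(0.3, 0.7, 1)[(i %% 3) + 1]
    fit <- fit_pgls(sp, tree, lambda = lam)
    C <- ape::vcv(tree)[sp$species, sp$species]
    V <- C * lam
    diag(V) <- diag(C)
    X <- cbind(1, log10(sp$L_inf))
    beta <- brute_force_gls(X, log10(sp$K), V)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  }
})

test_that("fixed-lambda PGLS matches the nlme/ape reference implementation", {
  skip_if_not_installed("nlme")
  tree <- simulate_tree(20, seed = 9)
  sp <- simulate_species_set(
    species_sim_config(n_species = 20, evolve_on_tree = TRUE, residual_sd = 0.2),
    seed = 10, tree = tree
  )
  d <- data.frame(y = log10(sp$K), x = log10(sp$L_inf), species = sp$species)
  for (lam in c(0, 0.4, 0.8, 1)) {
    mine <- fit_pgls(sp, tree, lambda = lam)
    ref <- nlme::gls(
      y ~ x, data = d,
      correlation = ape::corPagel(lam, tree, form = ~species, fixed = TRUE),
      method = "ML"
    )
    expect_equal(mine$slope, unname(coef(ref)[2]), tolerance = 1e-8)
    expect_equal(mine$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
    expect_equal(mine$log_likelihood, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  }
})

test_that("the ML profile dominates a lambda grid", {
  tree <- simulate_tree(15, seed = 71)
  sp <- simulate_species_set(
    species_sim_config(n_species = 15, evolve_on_tree = TRUE, residual_sd = 0.12),
    seed = 72, tree = tree
  )
  fit <- fit_pgls(sp, tree)
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_gte(fit$log_likelihood + 1e-8,
               fit_pgls(sp, tree, lambda = lam)$log_likelihood)
  }
})

test_that("lambda is recovered: near 1 under Brownian residuals, near 0 under iid", {
  bm <- vapply(1:25, function(i) {
    tree <- simulate_tree(50, seed = 2000 + i)
    sp <- simulate_species_set(
      species_sim_config(n_species = 50, evolve_on_tree = TRUE),
      seed = 3000 + i, tree = tree
    )
    fit_pgls(sp, tree)$lambda
  }, numeric(1))
  expect_gte(median(bm), 0.8)

  iid <- vapply(1:25, function(i) {
    tree <- simulate_tree(50, seed = 4000 + i)
    sp <- simulate_species_set(species_sim_config(n_species = 50), seed = 5000 + i)
    sp$species <- tree$tip.label
    f <- fit_pgls(sp, tree)
    c(f$lambda, abs(f$slope - fit_loglog_allometry(sp)$slope))
  }, numeric(2))
  expect_lte(median(iid[1, ]), 0.2)
  # with lambda near zero the PGLS slope is close to OLS
  expect_lt(median(iid[2, ]), 0.05)
})

test_that("species-tip matching normalises case and separators, and fails loudly", {
  tree <- simulate_tree(6, seed = 81)
  tree$tip.label <- c("Triplophysa_rosa", "Triplophysa_stenura", "Sp_three",
                      "Sp_four", "Sp_five", "Sp_six")
  sp <- simulate_species_set(species_sim_config(n_species = 6, residual_sd = 0.05),
                             seed = 82)
  sp$species <- c("triplophysa rosa", "TRIPLOPHYSA STENURA", "sp three",
                  "sp_four", "Sp five", "sp_SIX")
  fit <- fit_pgls(sp, tree)
  expect_s3_class(fit, "pgls_fit")

  sp$species[1] <- "missing species"
  expect_error(fit_pgls(sp, tree), "missing species")
})

test_that("group comparisons behave on identical, null and separated groups", {
  sp <- simulate_species_set(species_sim_config(n_species = 8), seed = 91)
  sp$grp <- rep(c("a", "b"), each = 4)
  dup <- sp
  dup$K <- rep(sp$K[1:4], 2)  # identical groups
  same <- compare_groups(dup, "grp", "K")
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # two groups from one distribution: about nominal false-positive rate
  hits <- vapply(1:200, function(i) {
    sp_i <- simulate_species_set(species_sim_config(n_species = 12), seed = 9200 + i)
    compare_groups(sp_i, rep(c("a", "b"), 6), "phi_prime")$p_value < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.11)

  # groups shifted by 3 pooled SDs at n = 6 vs 20: detected at alpha = 0.01
  power <- vapply(1:100, function(i) {
    set.seed(9500 + i)
    small <- tibble::tibble(species = paste0("c", 1:6), phi_prime = rnorm(6, 1.5, 0.2))
    big <- tibble::tibble(species = paste0("e", 1:20), phi_prime = rnorm(20, 2.1, 0.2))
    sp_i <- dplyr::bind_rows(small, big)
    compare_groups(sp_i, rep(c("cave", "epigean"), c(6, 20)), "phi_prime")$p_value < 0.01
  }, logical(1))
  expect_gt(mean(power), 0.95)

  expect_error(compare_groups(sp[1:3, ], rep(c("a", "b"), c(1, 2)), "K"),
               ">= 2 species")
})

test_that("auximetric tables log-transform correctly and carry iso-lines", {
  one <- tibble::tibble(species = "x", L_inf = 10, K = 0.1)
  aux <- auximetric_table(list(solo = one))
  expect_equal(aux$log10_L_inf, 1)
  expect_equal(aux$log10_K, -1)
  expect_equal(aux$phi_prime, 1)

  iso <- phi_iso_lines(aux)
  expect_equal(iso$slope, -2)
  expect_equal(iso$intercept, 1)
  # phi-prime is conserved along the slope -2 contour, e.g. at log10(L_inf) = 1.5
  expect_equal(growth_performance(10^1.5, 10^(iso$intercept[1] - 2 * 1.5)),
               aux$phi_prime[1], tolerance = 1e-12)

  sp <- triplophysa_growth()
  aux6 <- auximetric_table(list(Triplophysa = sp))
  expect_equal(round(aux6$phi_prime, 2),
               c(1.52, 1.40, 1.68, 1.56, 1.48, 1.52), tolerance = 0.011)
  expect_equal(nrow(phi_iso_lines(aux6)), 1)
})
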