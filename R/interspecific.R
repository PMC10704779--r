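## Cross-species growth-parameter allometry: ordinary least squares,
## phylogenetic generalized least squares with maximum-likelihood Pagel's
## lambda, group comparisons, and auximetric plot tables.

#' Fit the interspecific K versus L-infinity allometry
#'
#' Ordinary least squares of \eqn{\log_{10} K} on \eqn{\log_{10} L_\infty}
#' across species, with slope SE, \eqn{R^2} and a two-sided P on the
#' slope. Fast-growing species reach small asymptotic sizes and vice
#' versa, so the slope is typically negative.
#'
#' @param species Species table with positive `L_inf` and `K`; >= 3 rows.
#' @return A `linear_fit` (response `log10_K`, predictor `log10_L_inf`).
#' @export
fit_loglog_allometry <- function(species) {
  needs_columns(species, c("L_inf", "K"), "species table")
  if (nrow(species) < 3) abort("at least 3 species are required")
  check_positive(species$L_inf, "L_inf")
  check_positive(species$K, "K")
  d <- as_tibble(species)
  d$log10_L_inf <- log10(d$L_inf)
  d$log10_K <- log10(d$K)
  fit_line(d, "log10_K", "log10_L_inf")
}

normalise_taxon <- function(x) {
  gsub("[ _]+", "_", tolower(trimws(x)))
}

# Pagel's lambda transform: multiply off-diagonal shared-history entries
# of the Brownian covariance by lambda.
lambda_cov <- function(C, lambda) {
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

# ML log-likelihood of a GLS fit with covariance sigma2 * C, profiled over
# beta and sigma2.
pgls_profile <- function(X, y, C) {
  n <- length(y)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Xw <- backsolve(ch, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  yw <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  list(beta = fit$coefficients, rss = rss, loglik = ll,
       Xw = Xw, yw = yw, chol = ch)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Regresses \eqn{\log_{10} K} on \eqn{\log_{10} L_\infty} (or any other
#' pair of columns) across species with error covariance
#' \eqn{\sigma^2 C(\lambda)}, where \eqn{C} is the shared branch-length
#' (Brownian-motion) matrix of the tree and \eqn{C(\lambda)} multiplies
#' its off-diagonal entries by Pagel's \eqn{\lambda}. \eqn{\lambda} is
#' estimated by maximising the ML profile log-likelihood over \[0, 1\] by
#' bounded scalar optimization (endpoints included), or fixed by the
#' caller. At \eqn{\lambda = 0}, or on a star phylogeny, the estimator
#' reduces exactly to ordinary least squares.
#'
#' Species are matched to tree tips case-insensitively with spaces and
#' underscores equivalent; unmatched species are an error, never dropped.
#' \eqn{R^2} is computed in the GLS-whitened space, against the whitened
#' GLS intercept-only model. Coefficient SEs use
#' \eqn{s^2 (X^\top C(\lambda)^{-1} X)^{-1}} with
#' \eqn{s^2 = RSS_w / (n - 2)}.
#'
#' @param species Species table with `species`, `L_inf`, `K` (or the
#'   columns named by `response`/`predictor`).
#' @param tree An [ape] `phylo` covering every species.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param response,predictor Column names; defaults `log10(K)` on
#'   `log10(L_inf)` computed from the growth columns.
#' @return An object of class `pgls_fit`: `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `lambda`, `lambda_mode`,
#'   `log_likelihood`, `r_squared`, `n`, `p_slope`.
#' @export
fit_pgls <- function(species, tree, lambda = "ML",
                     response = NULL, predictor = NULL) {
  needs_columns(species, "species", "species table")
  d <- as_tibble(species)
  if (is.null(response)) {
    needs_columns(d, c("L_inf", "K"), "species table")
    check_positive(d$L_inf, "L_inf")
    check_positive(d$K, "K")
    d$log10_K <- log10(d$K)
    d$log10_L_inf <- log10(d$L_inf)
    response <- "log10_K"
    predictor <- "log10_L_inf"
  } else {
    needs_columns(d, c(response, predictor), "species table")
  }
  tip_key <- normalise_taxon(tree$tip.label)
  sp_key <- normalise_taxon(d$species)
  idx <- match(sp_key, tip_key)
  if (anyNA(idx)) {
    abort(sprintf(
      "species not found in tree: %s",
      paste(d$species[is.na(idx)], collapse = ", ")
    ))
  }
  n <- nrow(d)
  ml <- identical(lambda, "ML")
  if (ml && n < 4) abort("ML lambda estimation needs >= 4 species")
  if (!ml) check_number(lambda, "lambda", lower = 0, upper = 1)
  C_full <- ape::vcv(tree)
  C <- C_full[tree$tip.label[idx], tree$tip.label[idx]]
  y <- d[[response]]
  X <- cbind(`(Intercept)` = 1, slope = d[[predictor]])
  prof_at <- function(lam) pgls_profile(X, y, lambda_cov(C, lam))
  if (ml) {
    obj <- function(lam) {
      p <- prof_at(lam)
      if (is.null(p)) return(1e10)
      -p$loglik
    }
    opt <- optimize(obj, interval = c(0, 1), tol = 1e-8)
    cand <- c(opt$minimum, 0, 1)
    vals <- vapply(cand, obj, numeric(1))
    lambda_hat <- cand[which.min(vals)]
  } else {
    lambda_hat <- lambda
  }
  p <- prof_at(lambda_hat)
  if (is.null(p)) abort("phylogenetic covariance is not positive definite")
  s2 <- p$rss / (n - 2)
  XtX_inv <- chol2inv(chol(crossprod(p$Xw)))
  se <- setNames(sqrt(diag(s2 * XtX_inv)), colnames(p$Xw))
  # whitened-space R^2 against the GLS intercept-only model
  p0 <- pgls_profile(X[, 1, drop = FALSE], y, lambda_cov(C, lambda_hat))
  r2 <- 1 - p$rss / p0$rss
  t_slope <- p$beta[["slope"]] / se[["slope"]]
  structure(
    list(
      slope = p$beta[["slope"]],
      intercept = p$beta[["(Intercept)"]],
      se_slope = se[["slope"]],
      se_intercept = se[["(Intercept)"]],
      lambda = lambda_hat,
      lambda_mode = if (ml) "ML" else "fixed",
      log_likelihood = p$loglik,
      r_squared = r2,
      n = n,
      p_slope = 2 * pt(abs(t_slope), df = n - 2, lower.tail = FALSE),
      response = response,
      predictor = predictor,
      r_squared_definition = "1 - RSS/TSS in the GLS-whitened space"
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS (%s lambda = %.3f): %s = %.4g + %.4g * %s  (R^2 = %.3f, n = %d, P[slope] = %.3g)\n",
    x$lambda_mode, x$lambda, x$response, x$intercept, x$slope, x$predictor,
    x$r_squared, x$n, x$p_slope
  ))
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  est <- c(x$intercept, x$slope)
  se <- c(x$se_intercept, x$se_slope)
  stat <- est / se
  tibble(
    term = c("intercept", "slope"),
    estimate = est,
    std.error = se,
    statistic = stat,
    p.value = 2 * pt(abs(stat), df = x$n - 2, lower.tail = FALSE)
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda, logLik = x$log_likelihood, r.squared = x$r_squared,
    nobs = x$n, slope = x$slope, intercept = x$intercept, p.value = x$p_slope
  )
}

#' Compare a growth parameter between two species groups
#'
#' Two-sample t-test (Welch by default; the pooled-variance form is an
#' option) on `K`, `L_inf` or `phi_prime`, optionally log10-transformed.
#'
#' @param species Species table including the parameter column.
#' @param group Name of a column in `species` holding exactly two group
#'   labels, or a vector of labels of length `nrow(species)`.
#' @param parameter `"K"`, `"L_inf"` or `"phi_prime"`.
#' @param log10_transform Compare on the log10 scale?
#' @param var_equal Use the pooled-variance t-test?
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `mean_1`,
#'   `mean_2` (group means on the analysis scale), `group_1`, `group_2`,
#'   `method`.
#' @export
compare_groups <- function(species, group, parameter = c("K", "L_inf", "phi_prime"),
                           log10_transform = FALSE, var_equal = FALSE) {
  parameter <- match.arg(parameter)
  needs_columns(species, parameter, "species table")
  labels <- if (length(group) == 1 && is.character(group)) {
    needs_columns(species, group, "species table")
    species[[group]]
  } else {
    if (length(group) != nrow(species)) {
      abort("`group` must name a column or give one label per species")
    }
    group
  }
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) abort("exactly two groups are required")
  x <- species[[parameter]]
  if (log10_transform) {
    check_positive(x, parameter)
    x <- log10(x)
  }
  x1 <- x[labels == groups[1]]
  x2 <- x[labels == groups[2]]
  if (length(x1) < 2 || length(x2) < 2) abort("each group needs >= 2 species")
  tt <- t.test(x1, x2, var.equal = var_equal)
  tibble(
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_1 = mean(x1),
    mean_2 = mean(x2),
    group_1 = groups[1],
    group_2 = groups[2],
    method = if (var_equal) "pooled two-sample t" else "Welch two-sample t"
  )
}

#' Build a plot-ready auximetric table
#'
#' Log-transforms the growth parameters of one or more labelled species
#' sets for plotting on auximetric axes (\eqn{\log_{10} L_\infty} against
#' \eqn{\log_{10} K}), filling the growth performance index.
#'
#' @param species_sets A named list of species tables, or a single table
#'   (optionally with a `group` column).
#' @return A tibble: `species`, `group`, `log10_L_inf`, `log10_K`,
#'   `phi_prime`.
#' @seealso [phi_iso_lines()] for the slope -2 iso-performance contours;
#'   [plot_auximetric()].
#' @export
auximetric_table <- function(species_sets) {
  if (is.data.frame(species_sets)) {
    species_sets <- list(all = species_sets)
  }
  if (is.null(names(species_sets)) || any(names(species_sets) == "")) {
    abort("`species_sets` must be a named list of species tables")
  }
  map_dfr(species_sets, function(s) {
    needs_columns(s, c("species", "L_inf", "K"), "species table")
    check_positive(s$L_inf, "L_inf")
    check_positive(s$K, "K")
    grp <- if ("group" %in% names(s)) as.character(s$group) else NA_character_
    tibble(
      species = as.character(s$species),
      group_col = grp,
      log10_L_inf = log10(s$L_inf),
      log10_K = log10(s$K),
      phi_prime = growth_performance(s$L_inf, s$K)
    )
  }, .id = "set") |>
    mutate(group = dplyr::coalesce(.data$group_col, .data$set)) |>
    select("species", "group", "log10_L_inf", "log10_K", "phi_prime")
}

#' Iso-performance contour descriptors for an auximetric plot
#'
#' Lines of slope -2 in (log10 L_inf, log10 K) space are contours of equal
#' growth performance; each group's contour passes through its mean
#' phi-prime: \eqn{\log_{10} K = \Phi' - 2 \log_{10} L_\infty}.
#'
#' @param aux An [auximetric_table()] output.
#' @return A tibble per group: `group`, `mean_phi_prime`, `slope` (-2),
#'   `intercept` (= mean phi-prime).
#' @export
phi_iso_lines <- function(aux) {
  needs_columns(aux, c("group", "phi_prime"), "auximetric table")
  aux |>
    group_by(.data$group) |>
    summarise(mean_phi_prime = mean(.data$phi_prime), .groups = "drop") |>
    mutate(slope = -2, intercept = .data$mean_phi_prime)
}
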