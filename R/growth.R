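## Von Bertalanffy growth function: prediction, nonlinear least-squares
## fitting with per-parameter inference, partitioned fits, and the growth
## performance index.

#' Predict length at age under the von Bertalanffy growth function
#'
#' \eqn{L(t) = L_\infty (1 - e^{-K (t - t_0)})}. Strictly increasing in
#' age and bounded by \eqn{L_\infty} when \eqn{K > 0}; zero at
#' \eqn{t = t_0}.
#'
#' @param age Age(s) in years.
#' @param L_inf Asymptotic length, cm.
#' @param K Brody growth coefficient, 1/yr.
#' @param t0 Theoretical age at zero length, yr.
#' @return Predicted total length(s), cm.
#' @export
vbgf_predict <- function(age, L_inf, K, t0) {
  L_inf * (1 - exp(-K * (age - t0)))
}

vbgf_start <- function(age, len) {
  L0 <- 1.1 * max(len)
  # Ford-Walford-style linearisation: log(1 - L/L0) = -K (t - t0)
  ok <- len < L0
  z <- log(1 - len[ok] / L0)
  K0 <- if (sum(ok) >= 2 && sd(age[ok]) > 0) {
    -unname(coef(lm(z ~ age[ok]))[2])
  } else {
    NA_real_
  }
  if (!is.finite(K0) || K0 <= 0) K0 <- 0.1
  c(L_inf = L0, K = K0, t0 = 0)
}

#' Fit the von Bertalanffy growth function by nonlinear least squares
#'
#' Minimises \eqn{\sum_i (L_i - L_\infty(1 - e^{-K(t_i - t_0)}))^2} by
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]), unconstrained
#' in all three parameters (poorly informative data may legitimately push
#' \eqn{L_\infty} far beyond the observed lengths; that is reported, not
#' clipped). Standard errors come from the Jacobian-based covariance
#' \eqn{s^2 (J^\top J)^{-1}} at the optimum; each parameter is tested with
#' \eqn{t = \hat\theta / SE} against zero on \eqn{n - 3} degrees of
#' freedom, two-sided.
#'
#' Default starting values are data-driven: \eqn{L_\infty^0 = 1.1 \max L},
#' \eqn{K^0} from the slope of \eqn{\log(1 - L/L_\infty^0)} on age, and
#' \eqn{t_0^0 = 0}.
#'
#' @param data Data frame of one row per fish.
#' @param age_col,length_col Column names for age (yr) and length (cm).
#' @param start Optional named vector `c(L_inf, K, t0)` of starting values.
#' @param max_iter Maximum optimizer iterations.
#' @param partition_label Label stored with the fit (used by
#'   [fit_vbgf_partitions()]).
#' @return An object of class `vbgf_fit`: `estimate`, `se`, `t_stat`,
#'   `p_value` (each named L_inf/K/t0), `n`, `rss`, `converged`,
#'   `singular`, `partition_label`, and the fitting data. Non-convergence
#'   is flagged, never silent.
#' @export
fit_vbgf <- function(data, age_col = "age", length_col = "total_length",
                     start = NULL, max_iter = 200, partition_label = "all") {
  needs_columns(data, c(age_col, length_col), "growth data")
  keep <- stats::complete.cases(data[[age_col]], data[[length_col]])
  d <- tibble(age = data[[age_col]][keep], len = data[[length_col]][keep])
  if (nrow(d) < 4) abort("at least 4 (age, length) pairs are required")
  if (sd(d$age) == 0) abort("all ages are equal; growth curve unidentifiable")
  if (is.null(start)) start <- vbgf_start(d$age, d$len)
  start <- as.list(start[c("L_inf", "K", "t0")])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      len ~ L_inf * (1 - exp(-K * (age - t0))),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-10, ptol = 1e-10
      )
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_vbgf_fit_failed(d, partition_label, conditionMessage(fit)))
  }
  est <- coef(fit)
  n <- nrow(d)
  rss <- sum(stats::residuals(fit)^2)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  singular <- is.null(sm)
  se <- if (singular) setNames(rep(NA_real_, 3), names(est)) else sm$coefficients[, 2]
  t_stat <- est / se
  p <- 2 * pt(abs(t_stat), df = n - 3, lower.tail = FALSE)
  structure(
    list(
      estimate = est, se = se, t_stat = t_stat, p_value = p,
      n = n, rss = rss,
      converged = isTRUE(fit$convInfo$isConv),
      singular = singular,
      partition_label = partition_label,
      data = d,
      model = fit
    ),
    class = "vbgf_fit"
  )
}

new_vbgf_fit_failed <- function(d, partition_label, message) {
  nm <- c("L_inf", "K", "t0")
  na3 <- setNames(rep(NA_real_, 3), nm)
  structure(
    list(
      estimate = na3, se = na3, t_stat = na3, p_value = na3,
      n = nrow(d), rss = NA_real_,
      converged = FALSE, singular = TRUE,
      partition_label = partition_label,
      data = d, model = NULL, failure = message
    ),
    class = "vbgf_fit"
  )
}

#' @export
print.vbgf_fit <- function(x, ...) {
  cat(sprintf("VBGF fit [%s], n = %d%s\n", x$partition_label, x$n,
              if (!x$converged) " (NOT converged)" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy a von Bertalanffy fit
#'
#' @param x A `vbgf_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (L_inf, K, t0): estimate,
#'   std.error, statistic, p.value.
#' @export
tidy.vbgf_fit <- function(x, ...) {
  tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$se),
    statistic = unname(x$t_stat),
    p.value = unname(x$p_value)
  )
}

#' @rdname tidy.vbgf_fit
#' @return For `glance()`, a one-row tibble with n, rss, residual sigma,
#'   convergence flags and the growth performance index of the point
#'   estimates.
#' @export
glance.vbgf_fit <- function(x, ...) {
  tibble(
    nobs = x$n,
    rss = x$rss,
    sigma = if (is.finite(x$rss)) sqrt(x$rss / (x$n - 3)) else NA_real_,
    converged = x$converged,
    singular = x$singular,
    phi_prime = if (all(is.finite(x$estimate[c("L_inf", "K")])) &&
                    x$estimate[["K"]] > 0) {
      growth_performance(x$estimate[["L_inf"]], x$estimate[["K"]])
    } else {
      NA_real_
    },
    partition = x$partition_label
  )
}

vbgf_partition_rows <- function(individuals, label) {
  sc <- as.character(individuals$sex_class)
  switch(
    label,
    total = rep(TRUE, nrow(individuals)),
    female = sc == "female",
    male = sc == "male",
    female_juvenile = sc %in% c("female", "juvenile"),
    male_juvenile = sc %in% c("male", "juvenile"),
    abort(sprintf(
      "unknown partition label `%s`; expected total, female, male, female_juvenile, male_juvenile",
      label
    ))
  )
}

#' Fit the growth curve over the five standard data partitions
#'
#' Fits the von Bertalanffy curve separately to: all fish; females only;
#' males only; females plus juveniles; males plus juveniles (juveniles,
#' being unsexed, are duplicated into both mixed partitions). Partitions
#' with fewer than 4 fish are marked infeasible and the others proceed.
#'
#' @param individuals Data frame with `sex_class`, age and length columns.
#' @param partitions Character vector of partition labels (default all
#'   five).
#' @inheritParams fit_vbgf
#' @return A named list of `vbgf_fit` objects of class `vbgf_partitions`;
#'   `tidy()` stacks them into a partition-by-parameter table.
#' @export
fit_vbgf_partitions <- function(individuals,
                                partitions = c("total", "female", "male",
                                               "female_juvenile", "male_juvenile"),
                                age_col = "age", length_col = "total_length") {
  needs_columns(individuals, c("sex_class", age_col, length_col), "individuals")
  fits <- lapply(partitions, function(label) {
    rows <- vbgf_partition_rows(individuals, label)
    sub <- individuals[rows, , drop = FALSE]
    if (nrow(sub) < 4) {
      new_vbgf_fit_failed(
        tibble(age = sub[[age_col]], len = sub[[length_col]]),
        label, sprintf("partition has %d fish (< 4); fit infeasible", nrow(sub))
      )
    } else {
      fit_vbgf(sub, age_col = age_col, length_col = length_col,
               partition_label = label)
    }
  })
  structure(setNames(fits, partitions), class = "vbgf_partitions")
}

#' @export
tidy.vbgf_partitions <- function(x, ...) {
  map_dfr(unclass(x), function(f) {
    mutate(tidy(f), partition = f$partition_label, n = f$n,
           converged = f$converged, .before = 1)
  })
}

#' @export
print.vbgf_partitions <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Growth performance index (phi-prime)
#'
#' \eqn{\Phi' = \log_{10} K + 2 \log_{10} L_\infty}, the auximetric index
#' that collapses the negatively correlated \eqn{(K, L_\infty)} pair into
#' one comparable growth-performance number. Invariant along lines of
#' slope -2 in \eqn{(\log_{10} L_\infty, \log_{10} K)} space.
#'
#' @param L_inf Asymptotic length(s), cm (> 0).
#' @param K Growth coefficient(s), 1/yr (> 0).
#' @return phi-prime (dimensionless), vectorised.
#' @export
growth_performance <- function(L_inf, K) {
  if (any(!is.na(L_inf) & L_inf <= 0) || any(!is.na(K) & K <= 0)) {
    abort("growth_performance() requires L_inf > 0 and K > 0")
  }
  log10(K) + 2 * log10(L_inf)
}
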