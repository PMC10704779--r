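## Length-weight allometry, isometry and sex-covariate tests, and
## composition-versus-length trends.

#' Fit the length-weight power law
#'
#' Fits \eqn{W = a L^b} by ordinary least squares on
#' \eqn{\log_{10} W = \log_{10} a + b \log_{10} L}, the standard
#' fisheries approach. The coefficient is back-transformed,
#' \eqn{a = 10^{\text{intercept}}}; the exponent `b`, its standard error
#' and \eqn{R^2} are reported on the log scale where the model is linear.
#' An exponent of 3 indicates isometric (shape-preserving) growth.
#'
#' @param individuals Data frame with positive `total_length` (cm) and
#'   `body_weight` (g); at least 3 rows.
#' @return An object of class `lwr_fit` with elements `a`, `b`, `se_b`,
#'   `se_log10a`, `r_squared`, `n`, `p_b`, `residual_sd`, `log_base` (10).
#' @export
fit_lwr <- function(individuals) {
  needs_columns(individuals, c("total_length", "body_weight"), "individuals")
  keep <- stats::complete.cases(individuals$total_length, individuals$body_weight)
  d <- individuals[keep, , drop = FALSE]
  if (nrow(d) < 3) abort("at least 3 fish with length and weight are required")
  check_positive(d$total_length, "total_length")
  check_positive(d$body_weight, "body_weight")
  if (sd(d$total_length) == 0) abort("total_length has zero variance")
  d$log10_length <- log10(d$total_length)
  d$log10_weight <- log10(d$body_weight)
  line <- fit_line(d, "log10_weight", "log10_length")
  structure(
    list(
      a = 10^line$intercept,
      b = line$slope,
      se_b = line$se_slope,
      se_log10a = line$se_intercept,
      r_squared = line$r_squared,
      n = line$n,
      p_b = line$p_slope,
      residual_sd = line$residual_sd,
      log_base = 10,
      line = line,
      data = d
    ),
    class = "lwr_fit"
  )
}

#' @export
print.lwr_fit <- function(x, ...) {
  cat(sprintf("Length-weight relationship: W = %.4g * L^%.3g  (R^2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.lwr_fit <- function(x, ...) {
  tibble(
    term = c("log10_a", "b"),
    estimate = c(log10(x$a), x$b),
    std.error = c(x$se_log10a, x$se_b),
    statistic = c(log10(x$a) / x$se_log10a, x$b / x$se_b),
    p.value = 2 * pt(abs(c(log10(x$a) / x$se_log10a, x$b / x$se_b)),
                     df = x$n - 2, lower.tail = FALSE)
  )
}

#' @export
glance.lwr_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, se_b = x$se_b, r.squared = x$r_squared,
         sigma = x$residual_sd, nobs = x$n, p.value = x$p_b)
}

#' Test the length-weight exponent against isometry
#'
#' One-sample t-test of the fitted exponent against a reference value
#' (default 3, the isometric slope): \eqn{t = (b - b_0)/SE(b)} with
#' \eqn{n - 2} degrees of freedom and a two-sided P.
#'
#' @param fit An `lwr_fit` from [fit_lwr()].
#' @param b0 Reference exponent (default 3).
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `slope_1`
#'   (fitted b), `slope_2` (b0), `method`.
#' @export
test_isometry <- function(fit, b0 = 3) {
  stopifnot(inherits(fit, "lwr_fit"))
  if (!is.finite(fit$se_b) || fit$se_b <= 0) {
    abort("exponent standard error is zero or undefined; isometry test degenerate")
  }
  if (fit$n < 4) abort("isometry test needs n >= 4")
  t <- (fit$b - b0) / fit$se_b
  df <- fit$n - 2
  tibble(
    t_statistic = t,
    df = df,
    p_value = 2 * pt(abs(t), df, lower.tail = FALSE),
    slope_1 = fit$b,
    slope_2 = b0,
    method = "one-sample t on the length-weight exponent"
  )
}

#' Test for a sex difference in the length-weight relationship
#'
#' Covariate (ANCOVA-style) comparison of females and males on the log-log
#' scale. The slope test is the t on the sex-by-log10(length) interaction
#' in the full model; the intercept test is the t on the sex indicator in
#' the common-slope model. Juveniles are excluded: they are a life-stage
#' class, not a sex.
#'
#' @param individuals Data frame with `sex_class`, `total_length`,
#'   `body_weight`; at least 3 females and 3 males.
#' @return A two-row tibble (`term` = slope, intercept) with
#'   `t_statistic`, `df`, `p_value`, and the per-sex estimates.
#' @export
test_sex_effect <- function(individuals) {
  needs_columns(individuals, c("sex_class", "total_length", "body_weight"),
                "individuals")
  d <- individuals |>
    filter(.data$sex_class %in% c("female", "male")) |>
    mutate(sex_class = factor(as.character(.data$sex_class), levels = c("female", "male")))
  counts <- table(d$sex_class)
  if (any(counts < 3)) {
    abort(sprintf("need >= 3 fish per sex; got female = %d, male = %d",
                  counts[["female"]], counts[["male"]]))
  }
  d$lw <- log10(d$body_weight)
  d$ll <- log10(d$total_length)
  full <- lm(lw ~ ll * sex_class, data = d)
  common <- lm(lw ~ ll + sex_class, data = d)
  # noiseless covariate fixtures fit perfectly; that is expected, not suspect
  cf_full <- suppressWarnings(summary(full))$coefficients
  cf_common <- suppressWarnings(summary(common))$coefficients
  tibble(
    term = c("slope", "intercept"),
    estimate = c(cf_full["ll:sex_classmale", 1], cf_common["sex_classmale", 1]),
    t_statistic = c(cf_full["ll:sex_classmale", 3], cf_common["sex_classmale", 3]),
    df = c(full$df.residual, common$df.residual),
    p_value = c(cf_full["ll:sex_classmale", 4], cf_common["sex_classmale", 4])
  )
}

analytes <- c("protein", "lipid", "glycogen", "ash", "energy")

#' Fit a composition-versus-length trend
#'
#' Ordinary least squares of one proximate-composition analyte
#' (mg g\eqn{^{-1}}; kJ g\eqn{^{-1}} for energy) on total length (cm),
#' both untransformed.
#'
#' @param records Composition tibble with `total_length` and the analyte
#'   column.
#' @param analyte One of `"protein"`, `"lipid"`, `"glycogen"`, `"ash"`,
#'   `"energy"`.
#' @return A `linear_fit`.
#' @export
fit_trend <- function(records, analyte = c("protein", "lipid", "glycogen", "ash", "energy")) {
  analyte <- match.arg(analyte)
  fit_line(records, analyte, "total_length")
}

#' Compare the slopes of two straight-line trends
#'
#' Two-sample comparison of independent slopes:
#' \eqn{t = (b_2 - b_1)/\sqrt{SE_1^2 + SE_2^2}} with
#' \eqn{n_1 + n_2 - 4} degrees of freedom (two slopes and two intercepts
#' estimated) and a two-sided P. For analytes measured on the same
#' individuals a paired formulation is available via
#' [compare_trend_slopes_paired()].
#'
#' @param fit1,fit2 `linear_fit` objects with defined slope SEs.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `slope_1`,
#'   `slope_2`, `method`.
#' @export
compare_trend_slopes <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "linear_fit"), inherits(fit2, "linear_fit"))
  if (!is.finite(fit1$se_slope) || !is.finite(fit2$se_slope)) {
    abort("both fits need defined slope standard errors")
  }
  t <- (fit2$slope - fit1$slope) / sqrt(fit1$se_slope^2 + fit2$se_slope^2)
  df <- fit1$n + fit2$n - 4
  tibble(
    t_statistic = t,
    df = df,
    p_value = 2 * pt(abs(t), df, lower.tail = FALSE),
    slope_1 = fit1$slope,
    slope_2 = fit2$slope,
    method = "independent-slopes t"
  )
}

#' @rdname compare_trend_slopes
#' @param records Composition tibble carrying both analytes on the same
#'   individuals.
#' @param analyte1,analyte2 Analyte column names.
#' @details The paired form regresses the per-individual difference
#'   `analyte2 - analyte1` on length; its slope is exactly the slope
#'   difference, tested against zero with `n - 2` degrees of freedom.
#' @export
compare_trend_slopes_paired <- function(records, analyte1, analyte2) {
  needs_columns(records, c("total_length", analyte1, analyte2), "records")
  d <- tibble(
    total_length = records$total_length,
    diff = records[[analyte2]] - records[[analyte1]]
  )
  fit <- fit_line(d, "diff", "total_length")
  t <- fit$slope / fit$se_slope
  tibble(
    t_statistic = t,
    df = fit$n - 2,
    p_value = 2 * pt(abs(t), fit$n - 2, lower.tail = FALSE),
    slope_1 = NA_real_,
    slope_2 = NA_real_,
    method = "paired (difference-series) slope t"
  )
}
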