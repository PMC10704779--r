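## internal helpers shared across modules

sex_levels <- c("female", "male", "juvenile")

# Accepts full names or single-letter abbreviations, case-insensitive.
# Unknown labels are an error, never silently coerced to a fourth class.
normalise_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(
    female = "female", f = "female",
    male = "male", m = "male",
    juvenile = "juvenile", j = "juvenile", juv = "juvenile"
  )
  out <- unname(map[key])
  if (anyNA(out[!is.na(key) & key != ""])) {
    bad <- unique(key[is.na(out) & !is.na(key) & key != ""])
    abort(sprintf(
      "Unknown sex_class label(s): %s. Expected female/male/juvenile (or f/m/j).",
      paste(bad, collapse = ", ")
    ))
  }
  factor(out, levels = sex_levels)
}

check_positive <- function(x, name, rows = NULL) {
  bad <- which(!is.na(x) & x <= 0)
  if (length(bad)) {
    where <- if (is.null(rows)) bad else rows[bad]
    abort(sprintf(
      "%s must be strictly positive; violated at row(s) %s",
      name, paste(head(where, 10), collapse = ", ")
    ))
  }
  invisible(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %d", name, min))
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be supplied as a single integer: generators are pure functions of (config, seed)")
  }
  as.integer(seed)
}

needs_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

## ---- straight-line fit container -------------------------------------------
## One container for every straight-line relationship in the analysis
## (log-log length-weight, K vs L-infinity allometry, composition trends,
## otolith-vertebra agreement).

new_linear_fit <- function(model, data, response, predictor) {
  sm <- suppressWarnings(summary(model))  # perfect fits are legitimate here
  cf <- sm$coefficients
  r2 <- sm$r.squared
  # constant response: no variance to explain, not a numerically perfect fit
  if (!is.finite(r2) || sd(model$model[[1]]) == 0) r2 <- 0
  structure(
    list(
      slope = unname(cf[2, 1]),
      intercept = unname(cf[1, 1]),
      se_slope = unname(cf[2, 2]),
      se_intercept = unname(cf[1, 2]),
      r_squared = r2,
      n = length(model$residuals),
      p_slope = unname(cf[2, 4]),
      residual_sd = sm$sigma,
      response = response,
      predictor = predictor,
      model = model,
      data = data
    ),
    class = "linear_fit"
  )
}

#' Fit a straight line by ordinary least squares
#'
#' Thin wrapper around [stats::lm()] returning the package's common
#' straight-line container used for composition trends, interspecific
#' allometry and ageing-structure agreement. Requires at least three
#' observations so that standard errors are defined.
#'
#' @param data A data frame.
#' @param response,predictor Column names (strings) of the response and
#'   predictor variables.
#' @return A `linear_fit` object; see [tidy.linear_fit()] and
#'   [glance.linear_fit()].
#' @export
fit_line <- function(data, response, predictor) {
  needs_columns(data, c(response, predictor))
  keep <- stats::complete.cases(data[[response]], data[[predictor]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 3) {
    abort("at least 3 complete observations are required for a linear fit")
  }
  if (sd(data[[predictor]]) == 0) {
    abort(sprintf("`%s` has zero variance; slope undefined", predictor))
  }
  fml <- stats::reformulate(sprintf("`%s`", predictor), sprintf("`%s`", response))
  new_linear_fit(lm(fml, data = data), data, response, predictor)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit: %s = %.4g + %.4g * %s  (R^2 = %.3f, n = %d, P[slope] = %.3g)\n",
    x$response, x$intercept, x$slope, x$predictor, x$r_squared, x$n, x$p_slope
  ))
  invisible(x)
}

#' Tidy a straight-line fit
#'
#' @param x A `linear_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (intercept, slope).
#' @export
tidy.linear_fit <- function(x, ...) {
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

#' @rdname tidy.linear_fit
#' @return For `glance()`, a one-row tibble with fit-level summaries.
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    nobs = x$n,
    slope = x$slope,
    intercept = x$intercept,
    p.value = x$p_slope
  )
}
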