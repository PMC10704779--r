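## Age-reading precision: average percent error (APE), average coefficient
## of variation (ACV), consensus ages, and otolith-vs-vertebra agreement.
##
## Readings travel in long format: one row per read, columns fish_id,
## structure (optional when only one structure is present), read_index
## (optional), reading.

check_readings <- function(readings) {
  needs_columns(readings, c("fish_id", "reading"), "readings table")
  if (!"structure" %in% names(readings)) readings$structure <- "otolith"
  if (any(is.na(readings$reading)) || any(readings$reading <= 0)) {
    abort("all readings must be positive and non-missing")
  }
  counts <- dplyr::count(readings, .data$structure, .data$fish_id)
  if (any(counts$n < 2)) {
    bad <- counts$fish_id[counts$n < 2]
    abort(sprintf(
      "each fish needs >= 2 reads per structure; offender(s): %s",
      paste(unique(head(bad, 5)), collapse = ", ")
    ))
  }
  readings
}

per_fish_precision <- function(readings, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  readings |>
    group_by(.data$structure, .data$fish_id) |>
    summarise(
      n_reads = dplyr::n(),
      mean_read = mean(.data$reading),
      ape = 100 * mean(abs(.data$reading - mean(.data$reading))) / mean(.data$reading),
      cv = {
        s <- if (sd_type == "sample") sd(.data$reading) else
          sqrt(mean((.data$reading - mean(.data$reading))^2))
        100 * s / mean(.data$reading)
      },
      .groups = "drop"
    )
}

#' Average percent error (APE) of repeated age readings
#'
#' Beamish-Fournier index of ageing precision. For fish *j* with reads
#' \eqn{X_{1j}, \dots, X_{Rj}} and mean \eqn{\bar X_j},
#' \eqn{APE_j = 100 \cdot \frac{1}{R}\sum_i |X_{ij}-\bar X_j| / \bar X_j};
#' the reported value is the unweighted arithmetic mean of \eqn{APE_j} over
#' fish. Zero if and only if every fish's reads agree exactly, and
#' invariant under rescaling all reads by a common factor.
#'
#' @param readings Long tibble of reads for a single structure (`fish_id`,
#'   `reading`; an error is raised if several structures are mixed).
#' @return APE in percent (a single number).
#' @export
age_ape <- function(readings) {
  readings <- check_readings(readings)
  if (dplyr::n_distinct(readings$structure) > 1) {
    abort("age_ape() expects one structure; use age_precision() for several")
  }
  mean(per_fish_precision(readings)$ape)
}

#' Average coefficient of variation (ACV) of repeated age readings
#'
#' Per-fish coefficient of variation \eqn{CV_j = 100\, s_j / \bar X_j}
#' (sample SD, divisor R-1, by default), averaged without weights over
#' fish. For exactly two reads per fish, \eqn{ACV = \sqrt{2}\, APE}
#' identically.
#'
#' @inheritParams age_ape
#' @param sd_type `"sample"` (divisor R-1, default, per the standard
#'   precision literature) or `"population"` (divisor R).
#' @return ACV in percent (a single number).
#' @export
age_acv <- function(readings, sd_type = c("sample", "population")) {
  readings <- check_readings(readings)
  if (dplyr::n_distinct(readings$structure) > 1) {
    abort("age_acv() expects one structure; use age_precision() for several")
  }
  mean(per_fish_precision(readings, sd_type)$cv)
}

#' Precision summary per ageing structure
#'
#' Computes APE and ACV per structure from a long readings table.
#'
#' @inheritParams age_acv
#' @param readings Long tibble with `fish_id`, `structure`, `reading`.
#' @return A tibble with one row per structure: `structure`, `n_fish`,
#'   `ape_percent`, `acv_percent`. The per-fish values are attached as
#'   attribute `per_fish`.
#' @export
age_precision <- function(readings, sd_type = c("sample", "population")) {
  readings <- check_readings(readings)
  per_fish <- per_fish_precision(readings, sd_type)
  out <- per_fish |>
    group_by(.data$structure) |>
    summarise(
      n_fish = dplyr::n(),
      ape_percent = mean(.data$ape),
      acv_percent = mean(.data$cv),
      .groups = "drop"
    )
  attr(out, "per_fish") <- per_fish
  out
}

#' Consensus age per fish from repeated reads
#'
#' The `median` rule (default) takes the per-fish median read, which is
#' deterministic and needs no re-reading step. The `modal` rule takes the
#' most frequent read when one exists; ties and full three-way disagreement
#' are flagged for re-evaluation (the in-software analogue of re-reading a
#' structure) and the median is returned as a provisional value.
#'
#' @param readings Long tibble with `fish_id`, optional `structure`,
#'   `reading`.
#' @param rule `"median"` or `"modal"`.
#' @return A tibble: `fish_id`, `structure`, `age`, `flagged` (logical;
#'   always `FALSE` under the median rule).
#' @export
consensus_age <- function(readings, rule = c("median", "modal")) {
  rule <- match.arg(rule)
  readings <- check_readings(readings)
  readings |>
    group_by(.data$fish_id, .data$structure) |>
    summarise(
      age = if (rule == "median") median(.data$reading) else {
        tab <- table(.data$reading)
        if (max(tab) > 1 && sum(tab == max(tab)) == 1) {
          as.numeric(names(tab)[which.max(tab)])
        } else {
          median(.data$reading)
        }
      },
      flagged = if (rule == "median") FALSE else {
        tab <- table(.data$reading)
        !(max(tab) > 1 && sum(tab == max(tab)) == 1)
      },
      .groups = "drop"
    )
}

#' Compare ageing structures: agreement fit and paired precision
#'
#' Matches fish read on both structures by `fish_id`, regresses the
#' vertebra consensus age on the otolith consensus age by ordinary least
#' squares (default: free slope and intercept; `slope_mode = "fixed_one"`
#' constrains the slope to 1 so the intercept is the mean otolith-vertebra
#' offset), and summarises APE/ACV per structure over the matched fish
#' only. Fish read on a single structure are excluded from the comparison
#' but still appear in [age_precision()] run on the full table.
#'
#' @param readings Long tibble with both structures present.
#' @param rule Consensus rule passed to [consensus_age()].
#' @param slope_mode `"free"` or `"fixed_one"`.
#' @return A list of class `structure_comparison`: `fit` (a `linear_fit`;
#'   under `fixed_one` its slope is exactly 1 and `se_slope` is `NA`),
#'   `precision` (per-structure tibble on matched fish), `n_matched`,
#'   `consensus` (wide tibble of matched consensus ages).
#' @export
compare_structures <- function(readings, rule = c("median", "modal"),
                               slope_mode = c("free", "fixed_one")) {
  slope_mode <- match.arg(slope_mode)
  readings <- check_readings(readings)
  structures <- unique(readings$structure)
  if (!all(c("otolith", "vertebra") %in% structures)) {
    abort("readings must contain both 'otolith' and 'vertebra' structures")
  }
  cons <- consensus_age(readings, rule)
  wide <- cons |>
    select("fish_id", "structure", "age") |>
    tidyr::pivot_wider(names_from = "structure", values_from = "age") |>
    filter(!is.na(.data$otolith) & !is.na(.data$vertebra))
  if (nrow(wide) < 3) abort("fewer than 3 fish matched across both structures")
  fit <- if (slope_mode == "free") {
    fit_line(wide, "vertebra", "otolith")
  } else {
    offset_fit(wide)
  }
  matched <- readings |> filter(.data$fish_id %in% wide$fish_id)
  structure(
    list(
      fit = fit,
      precision = age_precision(matched),
      n_matched = nrow(wide),
      consensus = wide,
      slope_mode = slope_mode
    ),
    class = "structure_comparison"
  )
}

# slope fixed at 1: intercept is the mean offset; R^2 reported as the
# squared correlation of the two age series
offset_fit <- function(wide) {
  d <- wide$vertebra - wide$otolith
  model <- lm(d ~ 1)
  sm <- suppressWarnings(summary(model))  # a zero-residual offset is legitimate
  fit <- list(
    slope = 1,
    intercept = mean(d),
    se_slope = NA_real_,
    se_intercept = sm$coefficients[1, 2],
    r_squared = stats::cor(wide$otolith, wide$vertebra)^2,
    n = nrow(wide),
    p_slope = NA_real_,
    residual_sd = sm$sigma,
    response = "vertebra",
    predictor = "otolith",
    model = model,
    data = wide
  )
  class(fit) <- "linear_fit"
  fit
}

#' @export
print.structure_comparison <- function(x, ...) {
  cat(sprintf("Otolith-vertebra comparison on %d matched fish (%s slope)\n",
              x$n_matched, x$slope_mode))
  print(x$fit)
  print(x$precision)
  invisible(x)
}
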