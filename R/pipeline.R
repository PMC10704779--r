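## End-to-end orchestration: simulate or ingest a cohort, then run the
## ageing-precision, allometry, growth, interspecific and energy stages in
## dependency order, collecting results into one bundle.

#' Configuration for the full analysis pipeline
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param cohort A [cohort_config()] (used when no `individuals` are
#'   supplied).
#' @param individuals Optional pre-loaded individuals tibble; when absent
#'   a cohort is simulated from `cohort`.
#' @param reading_args List of arguments for [simulate_readings()]
#'   (ignored when `readings` supplied).
#' @param readings Optional pre-loaded long readings tibble.
#' @param trends A [composition_trends()] for simulated composition
#'   (ignored when `composition` supplied).
#' @param composition Optional pre-loaded composition tibble.
#' @param species Optional species growth table for the interspecific
#'   stage (default [triplophysa_growth()]).
#' @param tree Optional `phylo` for the PGLS stage.
#' @param coefficients An [energy_coefficients()] list.
#' @param maturity_age Earliest maturity in years (default 4.8); used for
#'   reporting the juvenile/adult split.
#' @param alpha Significance threshold used for annotation in the report
#'   (raw P-values are always reported).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "precision", "lwr", "growth", "interspecific",
#'   "energy")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            cohort = cohort_config(),
                            individuals = NULL,
                            reading_args = list(),
                            readings = NULL,
                            trends = composition_trends(),
                            composition = NULL,
                            species = triplophysa_growth(),
                            tree = NULL,
                            coefficients = energy_coefficients(),
                            maturity_age = 4.8,
                            alpha = 0.05,
                            stages = c("simulate", "precision", "lwr",
                                       "growth", "interspecific", "energy")) {
  seed <- check_seed(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!length(stages)) abort("at least one stage must be enabled")
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(maturity_age, "maturity_age", lower = 0)
  structure(
    list(
      seed = seed, cohort = cohort, individuals = individuals,
      reading_args = reading_args, readings = readings,
      trends = trends, composition = composition,
      species = species, tree = tree,
      coefficients = coefficients,
      maturity_age = maturity_age, alpha = alpha, stages = stages
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(status_env, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr), error = function(e) {
    list(ok = FALSE, value = NULL, message = conditionMessage(e))
  })
  status_env$status[[name]] <- tibble(
    stage = name,
    status = if (res$ok) "ok" else "error",
    message = if (res$ok) "" else res$message
  )
  res$value
}

#' Run the full life-history analysis pipeline
#'
#' Executes the enabled stages in dependency order: cohort acquisition
#' (simulated or supplied), age-reading precision and structure
#' comparison, length-weight allometry with isometry and sex tests, the
#' five-partition growth-curve fits with phi-prime, interspecific
#' allometry (plus PGLS when a tree is supplied) and the auximetric
#' table, and composition/energy trends. A failing stage is recorded in
#' the status table and does not abort stages that do not depend on it.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, [write_results()] writes
#'   every result and a manifest there.
#' @return A named list of class `analysis_bundle` with the stage results
#'   plus `status` (stage status tibble) and `config` echo.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- new.env()
  st$status <- list()
  bundle <- list()
  stages <- config$stages

  individuals <- config$individuals
  if (is.null(individuals) && ("simulate" %in% stages || is.null(config$individuals))) {
    individuals <- run_stage(st, "simulate_cohort",
                             simulate_cohort(config$cohort, seed = config$seed))
  } else if (!is.null(individuals)) {
    individuals <- run_stage(st, "validate_individuals", validate_individuals(individuals))
  }
  bundle$cohort <- individuals
  bundle$cohort_summary <- if (!is.null(individuals)) summarise_cohort(individuals) else NULL

  if ("precision" %in% stages) {
    readings <- config$readings
    if (is.null(readings) && !is.null(individuals) && "age" %in% names(individuals)) {
      readings <- run_stage(st, "simulate_readings", do.call(
        simulate_readings,
        c(list(individuals = individuals, seed = config$seed + 1L), config$reading_args)
      ))
    }
    if (!is.null(readings)) {
      bundle$readings <- readings
      bundle$precision <- run_stage(st, "precision", age_precision(readings))
      bundle$structure_comparison <- run_stage(st, "structure_comparison",
                                               compare_structures(readings))
    }
  }

  if ("lwr" %in% stages && !is.null(individuals)) {
    lwr <- run_stage(st, "lwr", fit_lwr(individuals))
    bundle$lwr <- lwr
    if (!is.null(lwr)) {
      bundle$isometry <- run_stage(st, "isometry", test_isometry(lwr))
    }
    bundle$sex_effect <- run_stage(st, "sex_effect", test_sex_effect(individuals))
  }

  if ("growth" %in% stages && !is.null(individuals)) {
    bundle$growth <- run_stage(st, "growth", fit_vbgf_partitions(individuals))
    if (!is.null(bundle$growth)) {
      est <- bundle$growth$total$estimate
      if (all(is.finite(est[c("L_inf", "K")])) && est[["K"]] > 0) {
        bundle$phi_prime <- growth_performance(est[["L_inf"]], est[["K"]])
      }
    }
  }

  if ("interspecific" %in% stages && !is.null(config$species)) {
    species <- run_stage(st, "species_validation", validate_species_table(config$species))
    if (!is.null(species)) {
      bundle$species <- species
      bundle$interspecific_ols <- run_stage(st, "interspecific_ols",
                                            fit_loglog_allometry(species))
      if (!is.null(config$tree)) {
        bundle$interspecific_pgls <- run_stage(st, "interspecific_pgls",
                                               fit_pgls(species, config$tree))
      }
      bundle$auximetric <- run_stage(st, "auximetric", auximetric_table(species))
    }
  }

  if ("energy" %in% stages && !is.null(individuals)) {
    composition <- config$composition
    if (is.null(composition)) {
      composition <- run_stage(st, "simulate_composition",
                               simulate_composition(individuals, config$trends,
                                                    seed = config$seed + 2L))
    }
    if (!is.null(composition)) {
      composition <- run_stage(st, "energy",
                               annotate_energy(composition, config$coefficients,
                                               quiet = TRUE))
      bundle$composition <- composition
      if (!is.null(composition)) {
        bundle$composition_trends <- run_stage(st, "composition_trends", {
          present <- intersect(analytes, names(composition))
          map_dfr(present, function(a) {
            mutate(glance(fit_trend(composition, a)), analyte = a, .before = 1)
          })
        })
      }
    }
  }

  bundle$status <- bind_rows(st$status)
  bundle$config <- config
  bundle <- structure(bundle, class = "analysis_bundle")
  if (!is.null(out_dir)) {
    writable <- bundle[!names(bundle) %in% c("config")]
    attr(bundle, "manifest") <- write_results(writable, out_dir)
  }
  bundle
}

summarise_cohort <- function(individuals) {
  individuals |>
    group_by(.data$sex_class) |>
    summarise(
      n = dplyr::n(),
      length_min = min(.data$total_length), length_max = max(.data$total_length),
      weight_min = min(.data$body_weight), weight_max = max(.data$body_weight),
      age_min = if ("age" %in% names(individuals)) min(.data$age) else NA_real_,
      age_max = if ("age" %in% names(individuals)) max(.data$age) else NA_real_,
      .groups = "drop"
    )
}

fmt_p <- function(p, alpha) {
  ifelse(p < 0.001, "< 0.001*",
         sprintf("%.3f%s", p, ifelse(p < alpha, "*", "")))
}

#' Render a human-readable report from a pipeline bundle
#'
#' One markdown document: cohort summary by sex class, ageing precision,
#' the fitted length-weight equation with isometry test, the
#' partition-by-parameter growth table, growth performance, interspecific
#' fits, and composition trends. P-values below the configured alpha are
#' starred; raw values are always shown.
#'
#' @param bundle An `analysis_bundle` from [run_pipeline()].
#' @return A character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  alpha <- bundle$config$alpha %||% 0.05
  out <- c("# Life-history analysis report", "")
  if (!is.null(bundle$cohort_summary)) {
    cs <- bundle$cohort_summary
    out <- c(out, "## Cohort", sprintf("Total n = %d", sum(cs$n)))
    out <- c(out, purrr::pmap_chr(cs, function(sex_class, n, length_min, length_max,
                                              weight_min, weight_max, age_min, age_max, ...) {
      sprintf("- %s: n = %d, length %.1f-%.1f cm, weight %.2f-%.2f g%s",
              sex_class, n, length_min, length_max, weight_min, weight_max,
              if (is.finite(age_min)) sprintf(", age %.1f-%.1f yr", age_min, age_max) else "")
    }), "")
  }
  if (!is.null(bundle$precision)) {
    pr <- bundle$precision
    out <- c(out, "## Age-reading precision",
             purrr::pmap_chr(pr, function(structure, n_fish, ape_percent, acv_percent) {
               sprintf("- %s: APE = %.2f%%, ACV = %.2f%% (n = %d fish)",
                       structure, ape_percent, acv_percent, n_fish)
             }))
    if (!is.null(bundle$structure_comparison)) {
      f <- bundle$structure_comparison$fit
      out <- c(out, sprintf(
        "- agreement: vertebra = %.3f + %.3f x otolith (R^2 = %.3f, n = %d)",
        f$intercept, f$slope, f$r_squared, f$n
      ))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$lwr)) {
    lw <- bundle$lwr
    out <- c(out, "## Length-weight relationship",
             sprintf("W = %.4g * L^%.3g (R^2 = %.3f, n = %d)",
                     lw$a, lw$b, lw$r_squared, lw$n))
    if (!is.null(bundle$isometry)) {
      iso <- bundle$isometry
      out <- c(out, sprintf("Isometry test vs b = 3: t = %.3f, df = %d, P = %s",
                            iso$t_statistic, iso$df, fmt_p(iso$p_value, alpha)))
    }
    if (!is.null(bundle$sex_effect)) {
      se <- bundle$sex_effect
      out <- c(out, purrr::pmap_chr(se, function(term, estimate, t_statistic, df, p_value) {
        sprintf("Sex %s test: t = %.3f, P = %s", term, t_statistic, fmt_p(p_value, alpha))
      }))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$growth)) {
    out <- c(out, "## Growth (von Bertalanffy), five partitions", "",
             knit_table(tidy(bundle$growth)), "")
    if (!is.null(bundle$phi_prime)) {
      out <- c(out, sprintf("Growth performance phi-prime (total fit): %.2f",
                            bundle$phi_prime), "")
    }
  }
  if (!is.null(bundle$interspecific_ols)) {
    f <- bundle$interspecific_ols
    out <- c(out, "## Interspecific allometry",
             sprintf("OLS: log10 K = %.2f %+.2f x log10 L_inf (R^2 = %.2f, P = %s)",
                     f$intercept, f$slope, f$r_squared, fmt_p(f$p_slope, alpha)))
    if (!is.null(bundle$interspecific_pgls)) {
      g <- bundle$interspecific_pgls
      out <- c(out, sprintf(
        "PGLS (lambda = %.2f): log10 K = %.2f %+.2f x log10 L_inf (R^2 = %.2f, P = %s)",
        g$lambda, g$intercept, g$slope, g$r_squared, fmt_p(g$p_slope, alpha)
      ))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$composition_trends)) {
    out <- c(out, "## Composition and energy trends", "",
             knit_table(bundle$composition_trends), "")
  }
  out
}

knit_table <- function(df) {
  df <- mutate(df, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 4)))
  header <- paste(names(df), collapse = " | ")
  sep <- paste(rep("---", ncol(df)), collapse = " | ")
  rows <- apply(df, 1, function(r) paste(r, collapse = " | "))
  c(header, sep, rows)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Analysis bundle with results:",
      paste(setdiff(names(x), c("status", "config")), collapse = ", "), "\n")
  cat("Stage status:\n")
  print(x$status)
  invisible(x)
}
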