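## Energy density from proximate composition, and size-based pooling of
## small individuals.

#' Combustion-energy coefficients
#'
#' Energy equivalents of the proximate components, kJ per g of component.
#' Defaults are the standard physiological combustion coefficients:
#' protein 23.6, lipid 39.5, glycogen 17.2 kJ g\eqn{^{-1}}. Ash carries no
#' energy.
#'
#' @param protein,lipid,glycogen Coefficients in kJ g^-1 (> 0).
#' @return A named list of class `energy_coefficients`.
#' @export
energy_coefficients <- function(protein = 23.6, lipid = 39.5, glycogen = 17.2) {
  for (nm in c("protein", "lipid", "glycogen")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0) {
      abort(sprintf("`%s` coefficient must be a single positive number", nm))
    }
  }
  structure(list(protein = protein, lipid = lipid, glycogen = glycogen),
            class = "energy_coefficients")
}

#' Energy density of body tissue from proximate composition
#'
#' \eqn{E = (P c_P + L c_L + G c_G) / 1000} kJ g\eqn{^{-1}}, with P, L, G
#' the protein, lipid and glycogen contents in mg g\eqn{^{-1}} and the
#' coefficients in kJ per g of component. Linear and homogeneous in the
#' analytes; ash contributes nothing. Missing analytes are an error, never
#' imputed.
#'
#' @param records Composition data frame with `protein`, `lipid`,
#'   `glycogen` columns (mg g^-1, >= 0).
#' @param coeffs An [energy_coefficients()] list.
#' @return Energy density in kJ g^-1, one value per row.
#' @export
energy_content <- function(records, coeffs = energy_coefficients()) {
  needs_columns(records, c("protein", "lipid", "glycogen"), "composition records")
  stopifnot(inherits(coeffs, "energy_coefficients"))
  for (nm in c("protein", "lipid", "glycogen")) {
    x <- records[[nm]]
    if (any(is.na(x))) {
      abort(sprintf("missing %s in row(s) %s; energy is never imputed",
                    nm, paste(head(which(is.na(x)), 10), collapse = ", ")))
    }
    if (any(x < 0)) abort(sprintf("negative %s content", nm))
  }
  (records$protein * coeffs$protein +
     records$lipid * coeffs$lipid +
     records$glycogen * coeffs$glycogen) / 1000
}

#' Fill the energy column of a composition table
#'
#' Computes [energy_content()] row-wise and writes it into the `energy`
#' column. Pre-existing non-missing energy values are overwritten with a
#' message (never silently).
#'
#' @inheritParams energy_content
#' @param quiet Suppress the overwrite message.
#' @return The table with `energy` (kJ g^-1) filled.
#' @export
annotate_energy <- function(records, coeffs = energy_coefficients(), quiet = FALSE) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    records$energy <- numeric(0)
    return(records)
  }
  e <- energy_content(records, coeffs)
  if ("energy" %in% names(records) && any(!is.na(records$energy)) && !quiet) {
    inform(sprintf("overwriting %d existing energy value(s)",
                   sum(!is.na(records$energy))))
  }
  records$energy <- e
  records
}

#' Pool small individuals of comparable size
#'
#' Greedy pooling from the smallest fish upward: consecutive individuals
#' (sorted by length) join the current pool while their length differs
#' from the pool's first member by at most `bin_width` (default 0.2 cm,
#' i.e. 2 mm); otherwise a new pool starts. Pooled records carry the mean
#' length, mean weight and mean analyte contents of their members, with
#' `pooled_n` the member count. Under an exactly linear
#' composition-length relationship, pooling leaves trend slopes unchanged.
#'
#' @param records Composition table with `total_length` and analyte
#'   columns; optionally `body_weight`.
#' @param bin_width Maximum within-pool length difference, cm.
#' @return A tibble of pooled records with `pool_id` and `pooled_n`.
#' @export
pool_small_individuals <- function(records, bin_width = 0.2) {
  needs_columns(records, "total_length", "composition records")
  check_number(bin_width, "bin_width", lower = 0)
  d <- as_tibble(records) |> arrange(.data$total_length)
  if (nrow(d) == 0) {
    return(mutate(d, pool_id = character(0), pooled_n = integer(0)))
  }
  pool <- integer(nrow(d))
  current <- 1L
  anchor <- d$total_length[1]
  for (i in seq_len(nrow(d))) {
    if (d$total_length[i] - anchor > bin_width + 1e-9) {
      current <- current + 1L
      anchor <- d$total_length[i]
    }
    pool[i] <- current
  }
  d$pool_id <- sprintf("pool_%03d", pool)
  avg_cols <- intersect(
    c("total_length", "body_weight", "protein", "lipid", "glycogen", "ash", "energy"),
    names(d)
  )
  d |>
    group_by(.data$pool_id) |>
    summarise(
      dplyr::across(dplyr::all_of(avg_cols), ~ mean(.x)),
      pooled_n = dplyr::n(),
      .groups = "drop"
    )
}
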