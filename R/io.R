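## CSV and newick input/output for the analysis tables.

individual_cols <- c(
  "fish_id", "sex_class", "total_length", "body_weight",
  "age", "age_otolith", "age_vertebra", "collection_label"
)

#' Read a table of individual fish records
#'
#' Reads a comma-separated file of one row per fish: identifier, sex class
#' (female / male / juvenile), total length in cm, body weight in g, and
#' optional consensus ages per ageing structure. Ages are continuous years,
#' so fractional values (e.g. 4.8) are accepted. Rows violating the record
#' invariants (non-positive length or weight, unknown sex labels) raise an
#' error naming the offending rows rather than being dropped silently.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping the package's
#'   column names (`fish_id`, `sex_class`, `total_length`, `body_weight`,
#'   `age`, `age_otolith`, `age_vertebra`, `collection_label`) to the
#'   column names used in the file, for files with a different layout.
#' @return A tibble of validated individual records with `sex_class` as a
#'   factor with levels female, male, juvenile.
#' @seealso [validate_individuals()] for checking an in-memory table.
#' @export
read_individuals <- function(path, col_map = NULL) {
  # read everything as character first: a sex column of bare F/M letters
  # must not be guessed as logical
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (internal in names(col_map)) {
      file_col <- col_map[[internal]]
      if (!file_col %in% names(raw)) {
        abort(sprintf("column `%s` (mapped to `%s`) not found in %s", file_col, internal, path))
      }
      names(raw)[names(raw) == file_col] <- internal
    }
  }
  numeric_cols <- intersect(c("total_length", "body_weight", "age",
                              "age_otolith", "age_vertebra"), names(raw))
  for (col in numeric_cols) {
    raw[[col]] <- readr::parse_double(raw[[col]])
  }
  for (col in setdiff(names(raw), c(numeric_cols, "fish_id", "sex_class", "collection_label"))) {
    raw[[col]] <- utils::type.convert(raw[[col]], as.is = TRUE)
  }
  validate_individuals(raw)
}

#' Validate a table of individual fish records
#'
#' @param data A data frame with at least `fish_id`, `sex_class`,
#'   `total_length` (cm) and `body_weight` (g).
#' @return The validated tibble, with `sex_class` normalised to a factor.
#' @export
validate_individuals <- function(data) {
  needs_columns(data, c("fish_id", "sex_class", "total_length", "body_weight"),
                what = "individuals table")
  out <- as_tibble(data)
  out$fish_id <- as.character(out$fish_id)
  out$sex_class <- normalise_sex(out$sex_class)
  check_positive(out$total_length, "total_length", seq_len(nrow(out)))
  check_positive(out$body_weight, "body_weight", seq_len(nrow(out)))
  for (col in intersect(c("age", "age_otolith", "age_vertebra"), names(out))) {
    check_positive(out[[col]], col, seq_len(nrow(out)))
  }
  keep <- intersect(individual_cols, names(out))
  extra <- setdiff(names(out), keep)
  out[, c(keep, extra)]
}

#' Read a species growth-parameter table
#'
#' Reads a CSV with one row per species carrying von Bertalanffy parameters
#' (`L_inf` in cm, `K` in 1/year, optionally `t0` in years) plus optional
#' habitat metadata. The growth-performance index `phi_prime`
#' (\eqn{\Phi' = \log_{10} K + 2 \log_{10} L_\infty}) is recomputed from
#' `L_inf` and `K` wherever it is absent; a supplied value differing from
#' the recomputed one by more than rounding plausibly explains triggers a
#' warning.
#'
#' @param path Path to a CSV file with at least `species`, `L_inf`, `K`.
#' @return A tibble of species growth records.
#' @export
read_species_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_species_table(raw)
}

#' @rdname read_species_table
#' @param data An in-memory species table to validate.
#' @export
validate_species_table <- function(data) {
  needs_columns(data, c("species", "L_inf", "K"), what = "species table")
  out <- as_tibble(data)
  out$species <- as.character(out$species)
  if (anyDuplicated(out$species)) {
    abort(sprintf(
      "duplicate species name(s): %s",
      paste(unique(out$species[duplicated(out$species)]), collapse = ", ")
    ))
  }
  check_positive(out$L_inf, "L_inf", seq_len(nrow(out)))
  check_positive(out$K, "K", seq_len(nrow(out)))
  recomputed <- growth_performance(out$L_inf, out$K)
  if (!"phi_prime" %in% names(out)) {
    out$phi_prime <- recomputed
  } else {
    supplied <- out$phi_prime
    off <- which(!is.na(supplied) & abs(supplied - recomputed) > 0.02)
    if (length(off)) {
      warn(sprintf(
        "phi_prime for %s differs from log10(K) + 2*log10(L_inf) by more than rounding",
        paste(out$species[off], collapse = ", ")
      ))
    }
    out$phi_prime <- ifelse(is.na(supplied), recomputed, supplied)
  }
  out
}

#' Read a phylogeny from a newick file
#'
#' Parses a single-tree newick string with branch lengths via
#' [ape::read.tree()] and validates it: unique tip labels, branch lengths
#' present and non-negative. Ultrametricity is reported (message) but not
#' enforced, since published time trees are often only approximately
#' ultrametric.
#'
#' @param path Path to a newick file containing one tree.
#' @param quiet Suppress the non-ultrametric message.
#' @return An [ape] `phylo` object.
#' @seealso [shared_depths()] for the implied Brownian covariance structure.
#' @export
read_newick <- function(path, quiet = FALSE) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)), error = function(e) {
    abort(sprintf("could not parse newick in %s: %s", path, conditionMessage(e)))
  })
  if (is.null(tree)) abort(sprintf("could not parse newick in %s", path))
  if (inherits(tree, "multiPhylo")) abort("expected a single tree, found several")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) abort("duplicate taxon names in tree")
  if (!quiet && !ape::is.ultrametric(tree, tol = 1e-6)) {
    inform("tree is not ultrametric (allowed; reported for awareness)")
  }
  tree
}

#' Write a phylogeny to a newick file
#'
#' @param tree An [ape] `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Shared root-to-tip path depths of a phylogeny
#'
#' Returns the matrix of shared branch-length depths between every pair of
#' tips (the Brownian-motion trait covariance up to a scale factor). The
#' diagonal holds each tip's root-to-tip distance.
#'
#' @param tree An [ape] `phylo` object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
shared_depths <- function(tree) {
  ape::vcv(tree)
}

#' Write a bundle of results to a directory
#'
#' Writes every element of a named result collection to `dir`: data frames
#' as CSV, fitted objects (anything with a [tidy()] method, e.g.
#' `linear_fit`, `vbgf_fit`, `pgls_fit`) as their tidied CSV, plus a JSON
#' manifest `manifest.json` enumerating every file written. Elements are
#' written in sorted-name order so manifests are deterministic.
#'
#' @param bundle A named list of results.
#' @param dir Output directory (created if absent).
#' @return A tibble manifest (name, file, class, rows), invisibly.
#' @export
write_results <- function(bundle, dir) {
  if (is.null(names(bundle)) && length(bundle)) {
    abort("`bundle` must be a named list")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory %s", dir))
  entries <- list()
  for (nm in sort(names(bundle))) {
    x <- bundle[[nm]]
    tb <- result_as_table(x)
    if (is.null(tb)) next
    file <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tb, file)
    entries[[nm]] <- tibble(
      name = nm, file = basename(file),
      class = class(x)[1], rows = nrow(tb)
    )
  }
  manifest <- if (length(entries)) bind_rows(entries) else
    tibble(name = character(), file = character(), class = character(), rows = integer())
  jsonlite::write_json(
    list(n_files = nrow(manifest), files = manifest),
    file.path(dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

result_as_table <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  if (inherits(x, c("linear_fit", "lwr_fit", "vbgf_fit", "pgls_fit",
                    "vbgf_partitions"))) {
    return(tidy(x))
  }
  if (inherits(x, "phylo")) return(tibble(newick = ape::write.tree(x)))
  if (is.list(x)) {
    tabs <- purrr::compact(map(x, result_as_table))
    if (length(tabs)) return(bind_rows(tabs, .id = "component"))
  }
  NULL
}
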