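#' Species parameter table
#'
#' Builds the per-species parameter table used throughout the model: one row
#' per species with its annual PM absorption rate, its leaf phenology class,
#' and a 12-element vector of monthly absorption weights stored in the
#' `"weights"` attribute (rows named by species). Weights are fractions of the
#' annual total assigned to each calendar month; they must be non-negative and
#' sum to 1 per species, so that the twelve seasonal monthly absorptions always
#' add back up to the annual rate.
#'
#' @param species_id character vector of species labels (unique, non-empty).
#' @param annual_pm_g numeric vector, grams of PM absorbed per tree per year
#'   (>= 0).
#' @param phenology character vector, each `"deciduous"` or `"evergreen"`.
#' @param monthly_weights optional numeric matrix (`length(species_id)` x 12)
#'   of monthly fractions; defaults to the flat profile (1/12 each month).
#' @return A `species_params` object: a data.frame with columns `species_id`,
#'   `annual_pm_g`, `phenology` and a `weights` matrix attribute.
#' @seealso [reference_species()] for the published Suwon parameter set,
#'   [apply_seasonal_profile()] to replace flat weights with phenology-driven
#'   seasonal ones.
#' @export
species_params <- function(species_id, annual_pm_g, phenology,
                           monthly_weights = NULL) {
  species_id <- as.character(species_id)
  n <- length(species_id)
  if (n == 0L) stop("at least one species is required")
  if (anyDuplicated(species_id)) stop("species_id values must be unique")
  if (any(!nzchar(species_id))) stop("species_id values must be non-empty")
  annual_pm_g <- as.numeric(annual_pm_g)
  if (length(annual_pm_g) != n) stop("annual_pm_g must match species_id in length")
  if (any(!is.finite(annual_pm_g)) || any(annual_pm_g < 0)) {
    stop("annual_pm_g must be finite and >= 0")
  }
  phenology <- as.character(phenology)
  if (length(phenology) != n) stop("phenology must match species_id in length")
  if (!all(phenology %in% c("deciduous", "evergreen"))) {
    stop("phenology must be 'deciduous' or 'evergreen'")
  }
  if (is.null(monthly_weights)) {
    monthly_weights <- matrix(1 / 12, nrow = n, ncol = 12)
  }
  monthly_weights <- as.matrix(monthly_weights)
  if (!is.numeric(monthly_weights) || nrow(monthly_weights) != n ||
      ncol(monthly_weights) != 12) {
    stop("monthly_weights must be a numeric matrix with one row per species and 12 columns")
  }
  if (any(!is.finite(monthly_weights)) || any(monthly_weights < 0)) {
    stop("monthly weights must be finite and >= 0")
  }
  sums <- rowSums(monthly_weights)
  if (any(abs(sums - 1) > 1e-9)) {
    bad <- species_id[abs(sums - 1) > 1e-9][1L]
    stop(sprintf("monthly weights for '%s' must sum to 1 (got %.12g)",
                 bad, sums[abs(sums - 1) > 1e-9][1L]))
  }
  dimnames(monthly_weights) <- list(species_id, month.abb)
  out <- data.frame(species_id = species_id,
                    annual_pm_g = annual_pm_g,
                    phenology = phenology,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- monthly_weights
  class(out) <- c("species_params", "data.frame")
  out
}

#' Monthly absorption weights of a parameter table
#'
#' @param params a [species_params()] object.
#' @return Numeric matrix, one row per species (rownames = species ids), one
#'   column per calendar month; each row sums to 1.
#' @export
monthly_weights <- function(params) {
  stopifnot(inherits(params, "species_params"))
  attr(params, "weights")
}

#' Published species parameters for the Suwon street-tree site
#'
#' The four parameter rows used by the reference scenario study: annual PM
#' absorption of 66.6 g/tree for *Zelkova serrata*, 45.3 for *Prunus
#' yedoensis*, 24.2 for *Pinus densiflora* (the only evergreen), and the
#' Korean national per-tree estimate of 35.7 g/tree for the pooled "other"
#' species, treated as a single deciduous pseudo-species. Monthly weights
#' default to the flat profile (1/12); use [apply_seasonal_profile()] for
#' leaf-phenology-aware weights.
#'
#' @param other_phenology phenology class assumed for the pooled "other"
#'   category (not published; deciduous by default).
#' @return A [species_params()] table with four rows.
#' @export
reference_species <- function(other_phenology = c("deciduous", "evergreen")) {
  other_phenology <- match.arg(other_phenology)
  species_params(
    species_id  = c("Zelkova serrata", "Prunus yedoensis",
                    "Pinus densiflora", "other"),
    annual_pm_g = c(66.6, 45.3, 24.2, 35.7),
    phenology   = c("deciduous", "deciduous", "evergreen", other_phenology)
  )
}

#' Validate a site composition
#'
#' A site composition is the model's stock vector: a continuous, non-negative
#' tree count per species. Counts are reals, not integers — first-order
#' turnover moves fractional trees per month — and are only rounded in
#' reports.
#'
#' @param counts named numeric vector or named list mapping species id to a
#'   tree count; an existing `site_composition` passes through unchanged
#'   (validation is idempotent).
#' @return A `site_composition`: a named numeric vector with the same totals
#'   as the input.
#' @export
validate_composition <- function(counts) {
  if (inherits(counts, "site_composition")) counts <- unclass(counts)
  if (is.list(counts)) counts <- unlist(counts)
  if (length(counts) == 0L) {
    out <- numeric(0)
    names(out) <- character(0)
    class(out) <- "site_composition"
    return(out)
  }
  nm <- names(counts)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("composition counts must be named by species")
  }
  if (anyDuplicated(nm)) stop("composition species names must be unique")
  if (!is.numeric(counts)) {
    stop(sprintf("count for species '%s' is not numeric", nm[!vapply(counts, is.numeric, TRUE)][1L]))
  }
  counts <- as.numeric(stats::setNames(counts, nm))
  names(counts) <- nm
  bad <- !is.finite(counts) | counts < 0
  if (any(bad)) {
    stop(sprintf("invalid count for species '%s': counts must be finite and >= 0",
                 nm[bad][1L]))
  }
  class(counts) <- "site_composition"
  counts
}

#' Total tree count of a composition
#'
#' @param composition a [validate_composition()] result (or coercible input).
#' @return The sum of all per-species counts.
#' @export
total_trees <- function(composition) {
  sum(unclass(validate_composition(composition)))
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters (", nrow(x), " species)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  flat <- all(abs(attr(x, "weights") - 1 / 12) < 1e-12)
  cat(if (flat) "Monthly weights: flat (1/12 per month)\n" else
    "Monthly weights: seasonal (see monthly_weights())\n")
  invisible(x)
}

#' @export
print.site_composition <- function(x, ...) {
  cat("Site composition (", format(sum(x)), " trees)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
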