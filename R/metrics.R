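#' Seasonal absorption profile parameters
#'
#' Parameterized stand-in for species-level seasonal leaf-area patterns:
#' deciduous species absorb only during a leaf-on window (with optional linear
#' ramps into and out of it), evergreens absorb year-round with winter months
#' damped to a fraction of the growing-season level. The resulting monthly
#' weights always sum to 1, so seasonal and flat modes agree on any whole-year
#' total.
#'
#' @param leaf_on_start_month,leaf_on_end_month calendar months (1-12)
#'   bounding the deciduous leaf-on window, inclusive (default April-November;
#'   a wrapped window, e.g. Oct-Mar, is allowed).
#' @param ramp_months number of transition months on each side of the window
#'   over which deciduous absorption ramps linearly between 0 and the plateau
#'   (default 1).
#' @param evergreen_winter_fraction winter (Dec-Feb) absorption of evergreens
#'   relative to their rest-of-year plateau, in (0, 1\] (default 0.6).
#' @return A `seasonal_profile` object.
#' @export
seasonal_profile <- function(leaf_on_start_month = 4, leaf_on_end_month = 11,
                             ramp_months = 1, evergreen_winter_fraction = 0.6) {
  chk_month <- function(m, what) {
    if (!is.numeric(m) || length(m) != 1L || m < 1 || m > 12 || m != round(m)) {
      stop(sprintf("%s must be a calendar month in 1..12", what))
    }
  }
  chk_month(leaf_on_start_month, "leaf_on_start_month")
  chk_month(leaf_on_end_month, "leaf_on_end_month")
  if (!is.numeric(ramp_months) || length(ramp_months) != 1L ||
      ramp_months < 0 || ramp_months != round(ramp_months)) {
    stop("ramp_months must be a non-negative integer")
  }
  if (!is.numeric(evergreen_winter_fraction) || length(evergreen_winter_fraction) != 1L ||
      evergreen_winter_fraction <= 0 || evergreen_winter_fraction > 1) {
    stop("evergreen_winter_fraction must be in (0, 1]")
  }
  structure(list(leaf_on_start_month = as.integer(leaf_on_start_month),
                 leaf_on_end_month = as.integer(leaf_on_end_month),
                 ramp_months = as.integer(ramp_months),
                 evergreen_winter_fraction = as.numeric(evergreen_winter_fraction)),
            class = "seasonal_profile")
}

#' Months counted as winter (December, January, February)
#' @return Integer vector `c(12, 1, 2)`.
#' @export
winter_months <- function() c(12L, 1L, 2L)

#' Monthly absorption weights for a phenology class
#'
#' @param phenology `"deciduous"` or `"evergreen"`.
#' @param profile a [seasonal_profile()].
#' @return 12 non-negative fractions (one per calendar month) summing to 1.
#' @export
seasonal_weights <- function(phenology = c("deciduous", "evergreen"),
                             profile = seasonal_profile()) {
  phenology <- match.arg(phenology)
  stopifnot(inherits(profile, "seasonal_profile"))
  m <- 1:12
  if (phenology == "evergreen") {
    w <- ifelse(m %in% winter_months(), profile$evergreen_winter_fraction, 1)
  } else {
    s <- profile$leaf_on_start_month
    e <- profile$leaf_on_end_month
    # position of each month relative to the (possibly wrapped) leaf-on window
    in_window <- if (s <= e) m >= s & m <= e else m >= s | m <= e
    w <- as.numeric(in_window)
    r <- profile$ramp_months
    if (r > 0) {
      for (d in seq_len(r)) {
        lvl <- 1 - d / (r + 1)
        before <- ((s - 1 - d) %% 12) + 1  # d months before window start
        after <- ((e - 1 + d) %% 12) + 1   # d months after window end
        w[before] <- max(w[before], lvl)
        w[after] <- max(w[after], lvl)
      }
    }
    if (sum(w) == 0) stop("leaf-on window assigns zero weight to every month")
  }
  stats::setNames(w / sum(w), month.abb)
}

#' Replace flat weights with phenology-driven seasonal weights
#'
#' @param params a [species_params()] table.
#' @param profile a [seasonal_profile()].
#' @return The parameter table with each species' monthly weights rebuilt from
#'   its phenology class.
#' @export
apply_seasonal_profile <- function(params, profile = seasonal_profile()) {
  stopifnot(inherits(params, "species_params"))
  w <- t(vapply(params$phenology, seasonal_weights, numeric(12),
                profile = profile))
  species_params(params$species_id, params$annual_pm_g, params$phenology,
                 monthly_weights = w)
}

#' Monthly PM absorption of a site
#'
#' Total grams of particulate matter absorbed by the site in one month:
#' the sum over species of tree count times per-tree monthly absorption.
#' In flat mode the per-tree monthly rate is `annual_pm_g / 12` regardless of
#' season; in seasonal mode it is `annual_pm_g * weight[calendar_month]`,
#' using each species' monthly weights.
#'
#' @param composition a site composition.
#' @param params a [species_params()] table covering every species present.
#' @param calendar_month calendar month 1-12 (required in seasonal mode).
#' @param mode `"flat"` or `"seasonal"`.
#' @return Grams of PM absorbed that month (>= 0).
#' @export
monthly_pm_absorption <- function(composition, params, calendar_month = NULL,
                                  mode = c("flat", "seasonal")) {
  mode <- match.arg(mode)
  composition <- validate_composition(composition)
  stopifnot(inherits(params, "species_params"))
  counts <- unclass(composition)
  if (length(counts) == 0L) return(0)
  missing_sp <- setdiff(names(counts), params$species_id)
  if (length(missing_sp)) {
    stop(sprintf("no parameters for species '%s'", missing_sp[1L]))
  }
  idx <- match(names(counts), params$species_id)
  annual <- params$annual_pm_g[idx]
  if (mode == "flat") {
    return(sum(counts * annual / 12))
  }
  if (is.null(calendar_month) || !is.numeric(calendar_month) ||
      length(calendar_month) != 1L || !calendar_month %in% 1:12) {
    stop("seasonal mode requires calendar_month in 1..12")
  }
  w <- monthly_weights(params)[idx, calendar_month]
  sum(counts * annual * w)
}

#' Shannon diversity index of a composition
#'
#' `H = -sum_i p_i log(p_i)` over species with positive count, where `p_i` is
#' the species' share of the total. Zero-count species contribute nothing
#' (`0 log 0 := 0`). `H` is 0 for a monoculture and at most `log(k)` for `k`
#' species present, attained at the even composition; it is invariant to
#' rescaling all counts.
#'
#' @param composition a site composition with positive total.
#' @param base logarithm base (default `exp(1)`: natural-log units, the
#'   standard ecological convention).
#' @return The Shannon index (>= 0).
#' @export
shannon_index <- function(composition, base = exp(1)) {
  composition <- validate_composition(composition)
  counts <- unclass(composition)
  tot <- sum(counts)
  if (tot <= 0) stop("Shannon index is undefined for an empty composition")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Mean winter PM absorption of a trajectory
#'
#' Arithmetic mean of monthly absorption over the winter months (December,
#' January, February) of a simulated trajectory, excluding the initial
#' snapshot.
#'
#' @param trajectory a [run_scenario()] result (or any data.frame with
#'   `month_index`, `calendar_month` and `mpa_g` columns).
#' @return Mean winter absorption in g/month.
#' @export
winter_mean_absorption <- function(trajectory) {
  stopifnot(is.data.frame(trajectory),
            all(c("month_index", "calendar_month", "mpa_g") %in% names(trajectory)))
  rows <- trajectory$month_index >= 1 &
    trajectory$calendar_month %in% winter_months()
  if (!any(rows)) stop("trajectory covers no winter months")
  mean(trajectory$mpa_g[rows])
}
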