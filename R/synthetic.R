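#' Specification for synthetic test data
#'
#' Parameters of the randomized fixtures used for property testing: a site of
#' `total_trees` split across `n_species` by a symmetric Dirichlet draw, and
#' per-species annual absorption rates drawn log-normal around the national
#' per-tree estimate of 35.7 g/year. These are declared testing conventions,
#' not fitted distributions.
#'
#' @param seed integer RNG seed (each generator call is independently seeded;
#'   no global RNG state is touched).
#' @param n_species number of species (>= 1).
#' @param total_trees site total (> 0).
#' @param composition_concentration symmetric Dirichlet concentration for the
#'   composition split (> 0; large values approach an even split).
#' @param absorption_log_mean,absorption_log_sd log-scale mean and sd of the
#'   annual absorption distribution (defaults: median 35.7 g/year, sd 0.4).
#' @param evergreen_prob probability that a species is evergreen, in \[0, 1\].
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed, n_species = 4, total_trees = 208,
                           composition_concentration = 1,
                           absorption_log_mean = log(35.7),
                           absorption_log_sd = 0.4,
                           evergreen_prob = 0.25) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a finite number")
  }
  if (!is.numeric(n_species) || n_species < 1 || n_species != round(n_species)) {
    stop("n_species must be an integer >= 1")
  }
  if (!is.numeric(total_trees) || total_trees <= 0) stop("total_trees must be > 0")
  if (!is.numeric(composition_concentration) || composition_concentration <= 0) {
    stop("composition_concentration must be > 0")
  }
  if (!is.numeric(absorption_log_sd) || absorption_log_sd < 0) {
    stop("absorption_log_sd must be >= 0")
  }
  if (!is.numeric(evergreen_prob) || evergreen_prob < 0 || evergreen_prob > 1) {
    stop("evergreen_prob must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed),
                 n_species = as.integer(n_species),
                 total_trees = as.numeric(total_trees),
                 composition_concentration = as.numeric(composition_concentration),
                 absorption_log_mean = as.numeric(absorption_log_mean),
                 absorption_log_sd = as.numeric(absorption_log_sd),
                 evergreen_prob = as.numeric(evergreen_prob)),
            class = "synthetic_spec")
}

#' Generate a synthetic species parameter table
#'
#' @param spec a [synthetic_spec()].
#' @return A [species_params()] table with `n_species` rows, flat monthly
#'   weights, log-normal annual rates (median `exp(absorption_log_mean)`), and
#'   Bernoulli(`evergreen_prob`) phenology. Reproducible from `spec$seed`.
#' @export
generate_species <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_species
    annual <- stats::rlnorm(n, meanlog = spec$absorption_log_mean,
                            sdlog = spec$absorption_log_sd)
    phen <- ifelse(stats::runif(n) < spec$evergreen_prob, "evergreen", "deciduous")
    species_params(sprintf("sp%02d", seq_len(n)), annual, phen)
  })
}

#' Generate a synthetic site composition
#'
#' Splits `total_trees` across the species by a symmetric Dirichlet draw with
#' the spec's concentration parameter (gamma normalization), so counts are
#' continuous, non-negative and sum exactly to the total.
#'
#' @param spec a [synthetic_spec()].
#' @param species a [species_params()] table naming the species.
#' @return A `site_composition` over `species$species_id`.
#' @export
generate_site <- function(spec, species) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(species, "species_params"))
  withr::with_seed(spec$seed + 1L, {
    k <- nrow(species)
    g <- stats::rgamma(k, shape = spec$composition_concentration, rate = 1)
    if (sum(g) == 0) g <- rep(1, k)  # numerically degenerate draw
    counts <- spec$total_trees * g / sum(g)
    validate_composition(stats::setNames(counts, species$species_id))
  })
}

#' Generate a random planting policy
#'
#' Picks one of the three policy modes uniformly; single-priority policies
#' name a uniformly chosen existing species with a target ratio drawn from
#' (0.05, 0.95), fixed-mix policies use a symmetric Dirichlet(1) mix.
#'
#' @param seed integer seed.
#' @param species a [species_params()] table (>= 1 species).
#' @return A valid [planting_policy()].
#' @export
generate_policy <- function(seed, species) {
  stopifnot(inherits(species, "species_params"), nrow(species) >= 1)
  withr::with_seed(seed, {
    mode <- sample(c("status_quo", "single_priority", "fixed_mix"), 1L)
    switch(mode,
      status_quo = planting_policy("status_quo"),
      single_priority = planting_policy(
        "single_priority",
        priority_species = sample(species$species_id, 1L),
        target_ratio = stats::runif(1, 0.05, 0.95)
      ),
      fixed_mix = {
        g <- stats::rgamma(nrow(species), shape = 1, rate = 1)
        mix <- g / sum(g)
        # renormalize exactly so the policy invariant holds to 1e-9
        planting_policy("fixed_mix",
                        mix = stats::setNames(mix / sum(mix), species$species_id))
      }
    )
  })
}
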