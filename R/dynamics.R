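#' Planting policy
#'
#' The rule by which replacement plantings are allocated across species each
#' month:
#'
#' * `status_quo` — plant in proportion to the current composition (every
#'   retired tree is replaced by the same species on average); the composition
#'   is a fixed point under this policy.
#' * `single_priority` — a designated species receives a fixed fraction
#'   `target_ratio` of all replacement plantings; the remaining
#'   `1 - target_ratio` is split across the other species in proportion to
#'   their current counts (the priority species excluded from the proportions).
#' * `fixed_mix` — plantings follow a fixed species mix regardless of the
#'   current composition.
#'
#' @param mode one of `"status_quo"`, `"single_priority"`, `"fixed_mix"`.
#' @param priority_species species id receiving the priority share
#'   (required for `single_priority`).
#' @param target_ratio fraction in \[0, 1\] of plantings given to the priority
#'   species (required for `single_priority`).
#' @param mix named numeric vector of planting fractions (>= 0, summing to 1;
#'   required for `fixed_mix`).
#' @return A `planting_policy` object.
#' @export
planting_policy <- function(mode = c("status_quo", "single_priority", "fixed_mix"),
                            priority_species = NULL, target_ratio = NULL,
                            mix = NULL) {
  mode <- match.arg(mode)
  if (mode == "single_priority") {
    if (is.null(priority_species) || length(priority_species) != 1L ||
        !nzchar(priority_species)) {
      stop("single_priority requires a priority_species")
    }
    if (is.null(target_ratio) || !is.numeric(target_ratio) ||
        length(target_ratio) != 1L || !is.finite(target_ratio) ||
        target_ratio < 0 || target_ratio > 1) {
      stop("single_priority requires target_ratio in [0, 1]")
    }
  }
  if (mode == "fixed_mix") {
    if (is.null(mix) || !is.numeric(mix) || is.null(names(mix)) ||
        any(!nzchar(names(mix)))) {
      stop("fixed_mix requires a named numeric mix")
    }
    if (any(!is.finite(mix)) || any(mix < 0)) stop("mix fractions must be >= 0")
    if (abs(sum(mix) - 1) > 1e-9) {
      stop(sprintf("mix fractions must sum to 1 (got %.12g)", sum(mix)))
    }
  }
  structure(list(mode = mode,
                 priority_species = if (mode == "single_priority") as.character(priority_species) else NULL,
                 target_ratio = if (mode == "single_priority") as.numeric(target_ratio) else NULL,
                 mix = if (mode == "fixed_mix") mix else NULL),
            class = "planting_policy")
}

#' Turnover settings
#'
#' @param replacement_period_months replacement cycle length in months
#'   (default 240 = the 20-year cycle). Under first-order turnover the monthly
#'   per-species retirement outflow is `count / replacement_period_months`.
#' @param dt_months Euler step size in months (default 1; must not exceed the
#'   replacement period).
#' @param scheme turnover scheduling: `"first_order"` (exponential turnover,
#'   outflow proportional to current stock; the default and the mode all
#'   reference results use) or `"cohort"` (the initial stock retires at a
#'   constant rate over one replacement period — a uniform initial age spread —
#'   after which turnover reverts to first-order; provided for sensitivity
#'   analysis).
#' @return A `turnover_settings` object.
#' @export
turnover_settings <- function(replacement_period_months = 240, dt_months = 1,
                              scheme = c("first_order", "cohort")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(replacement_period_months) || length(replacement_period_months) != 1L ||
      !is.finite(replacement_period_months) || replacement_period_months <= 0) {
    stop("replacement_period_months must be a positive number")
  }
  if (!is.numeric(dt_months) || length(dt_months) != 1L || !is.finite(dt_months) ||
      dt_months <= 0 || dt_months > replacement_period_months) {
    stop("dt_months must satisfy 0 < dt_months <= replacement_period_months")
  }
  structure(list(replacement_period_months = as.numeric(replacement_period_months),
                 dt_months = as.numeric(dt_months),
                 scheme = scheme),
            class = "turnover_settings")
}

#' Monthly retirement outflow (first-order turnover)
#'
#' Each species loses stock at rate `count / replacement_period_months`
#' trees per month, so the whole site turns over with mean residence time
#' equal to the replacement period.
#'
#' @param composition a site composition.
#' @param settings a [turnover_settings()] object.
#' @return Named numeric vector of per-species outflows (trees/month).
#' @export
retirement_flow <- function(composition, settings) {
  composition <- validate_composition(composition)
  stopifnot(inherits(settings, "turnover_settings"))
  unclass(composition) / settings$replacement_period_months
}

#' Allocate replacement plantings under a policy
#'
#' Splits a total replacement planting flow across species according to the
#' policy. Allocations always sum to `total_replacements` exactly (up to
#' floating point).
#'
#' @param total_replacements total planting flow to allocate (trees/month,
#'   >= 0).
#' @param composition current site composition (supplies the proportions for
#'   `status_quo` and `single_priority`).
#' @param policy a [planting_policy()].
#' @return Named numeric vector of per-species planting flows covering every
#'   species in the composition (plus any mix-only species).
#' @export
allocate_plantings <- function(total_replacements, composition, policy) {
  composition <- validate_composition(composition)
  stopifnot(inherits(policy, "planting_policy"))
  if (!is.numeric(total_replacements) || length(total_replacements) != 1L ||
      !is.finite(total_replacements) || total_replacements < 0) {
    stop("total_replacements must be a finite number >= 0")
  }
  counts <- unclass(composition)
  alloc <- stats::setNames(numeric(length(counts)), names(counts))
  if (total_replacements == 0) return(alloc)

  if (policy$mode == "status_quo") {
    tot <- sum(counts)
    if (tot <= 0) stop("status_quo allocation is undefined for an empty composition")
    alloc <- total_replacements * counts / tot
  } else if (policy$mode == "single_priority") {
    b <- policy$priority_species
    if (!b %in% names(counts)) {
      stop(sprintf("priority species '%s' is not present in the composition", b))
    }
    tot <- sum(counts)
    if (tot <= 0) stop("single_priority allocation is undefined for an empty composition")
    r <- policy$target_ratio
    rest <- counts[setdiff(names(counts), b)]
    rest_tot <- sum(rest)
    if (rest_tot > 0) {
      alloc[names(rest)] <- total_replacements * (1 - r) * rest / rest_tot
      alloc[b] <- total_replacements * r
    } else {
      # nothing but the priority species remains: it takes the whole flow
      alloc[b] <- total_replacements
    }
  } else { # fixed_mix
    mix <- policy$mix
    extra <- setdiff(names(mix), names(counts))
    if (length(extra)) {
      alloc <- c(alloc, stats::setNames(numeric(length(extra)), extra))
    }
    alloc[names(mix)] <- total_replacements * mix
  }
  alloc
}

#' One Euler step of the turnover model
#'
#' Updates every stock by `(planting - retirement) * dt`. Total tree count is
#' conserved because plantings are allocated to exactly match total
#' retirements. Tiny negative stocks from floating-point error are clipped to
#' zero with a warning.
#'
#' @param composition current site composition.
#' @param policy a [planting_policy()].
#' @param settings a [turnover_settings()] (first-order scheme; cohort
#'   scheduling is handled inside [run_dynamics()]).
#' @return The updated `site_composition`.
#' @export
step_composition <- function(composition, policy, settings) {
  composition <- validate_composition(composition)
  retire <- retirement_flow(composition, settings)
  plant <- allocate_plantings(sum(retire), composition, policy)
  counts <- unclass(composition)
  all_sp <- union(names(counts), names(plant))
  full <- stats::setNames(numeric(length(all_sp)), all_sp)
  full[names(counts)] <- counts
  full <- full + (plant[all_sp] %0% 0) - (retire[all_sp] %0% 0)
  if (any(full < 0)) {
    if (min(full) < -1e-8) {
      warning(sprintf("stock for '%s' dipped to %.3g; clipped to 0",
                      names(full)[which.min(full)], min(full)))
    }
    full[full < 0] <- 0
  }
  validate_composition(full)
}

# elementwise NA-to-default for name-indexed vectors
`%0%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

#' Closed-form priority-species stock (verification oracle)
#'
#' Under single-priority replacement with continuous first-order turnover the
#' priority species' stock follows the linear ODE
#' `dB/dt = (r N - B) / T`, whose exact solution is
#' `B(t) = r N + (B0 - r N) exp(-t / T)`. The stock moves monotonically from
#' `B0` toward its equilibrium `r N`. This closed form is independent of the
#' Euler integrator and serves as its verification oracle.
#'
#' @param t_months time since start (months; vectorized).
#' @param B0 initial stock of the priority species (trees).
#' @param r target planting ratio in \[0, 1\].
#' @param N total site tree count (conserved).
#' @param T_months replacement period (months, > 0).
#' @return Stock of the priority species at `t_months` (trees).
#' @export
closed_form_priority_share <- function(t_months, B0, r, N, T_months) {
  stopifnot(T_months > 0)
  r * N + (B0 - r * N) * exp(-t_months / T_months)
}

#' Run the turnover dynamics
#'
#' Integrates the stock-flow model with explicit Euler steps of
#' `settings$dt_months`, applying the policy at monthly resolution. The run is
#' fully deterministic (no randomness anywhere in the dynamics).
#'
#' With `settings$scheme = "cohort"`, the initial stock of each species is
#' treated as a uniformly aged cohort retiring at the constant rate
#' `initial_count / T` until exhausted (full conversion after exactly one
#' period), after which that species reverts to first-order turnover of its
#' current stock.
#'
#' @param initial initial site composition.
#' @param policy a [planting_policy()].
#' @param settings a [turnover_settings()].
#' @param horizon_months number of months to simulate (>= 1).
#' @return A numeric matrix with `horizon_months / dt + 1` rows (the initial
#'   state plus one row per step) and one column per species; rownames are the
#'   month indices. Class `"composition_path"`.
#' @export
run_dynamics <- function(initial, policy, settings, horizon_months) {
  initial <- validate_composition(initial)
  stopifnot(inherits(policy, "planting_policy"),
            inherits(settings, "turnover_settings"))
  if (!is.numeric(horizon_months) || length(horizon_months) != 1L ||
      horizon_months < 1) {
    stop("horizon_months must be >= 1")
  }
  dt <- settings$dt_months
  T_m <- settings$replacement_period_months
  n_steps <- as.integer(round(horizon_months / dt))

  sp <- names(initial)
  if (policy$mode == "fixed_mix") sp <- union(sp, names(policy$mix))
  counts <- stats::setNames(numeric(length(sp)), sp)
  counts[names(initial)] <- unclass(initial)

  path <- matrix(0, nrow = n_steps + 1L, ncol = length(sp),
                 dimnames = list(format(seq(0, by = dt, length.out = n_steps + 1L),
                                        trim = TRUE), sp))
  path[1L, ] <- counts
  cohort <- settings$scheme == "cohort"
  if (cohort) {
    orig_rate <- counts / T_m
    remaining <- counts
  }
  for (k in seq_len(n_steps)) {
    if (cohort) {
      retire <- ifelse(remaining > 0, pmin(orig_rate, remaining / dt), counts / T_m)
      remaining <- pmax(remaining - retire * dt, 0)
    } else {
      retire <- counts / T_m
    }
    plant <- allocate_plantings(sum(retire), validate_composition(counts), policy)
    counts <- counts + (plant[sp] %0% 0 - retire) * dt
    if (any(counts < 0)) {
      if (min(counts) < -1e-8) {
        warning(sprintf("stock for '%s' dipped to %.3g at step %d; clipped to 0",
                        sp[which.min(counts)], min(counts), k))
      }
      counts[counts < 0] <- 0
    }
    path[k + 1L, ] <- counts
  }
  class(path) <- c("composition_path", class(path))
  path
}
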