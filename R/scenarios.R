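#' Scenario specification
#'
#' Bundles everything needed to simulate one planting scenario: the initial
#' composition, the planting policy, turnover settings, the start date, the
#' simulation horizon and the absorption mode.
#'
#' @param name scenario name.
#' @param initial_composition a site composition (see
#'   [validate_composition()]).
#' @param policy a [planting_policy()].
#' @param settings a [turnover_settings()] (default: 240-month period,
#'   monthly Euler steps, first-order turnover).
#' @param start_year,start_month simulation start (default January 2021).
#' @param horizon_months months to simulate (default 360 = 2021-2050).
#' @param mode `"flat"` or `"seasonal"` absorption accounting.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name, initial_composition, policy,
                          settings = turnover_settings(),
                          start_year = 2021, start_month = 1,
                          horizon_months = 360,
                          mode = c("flat", "seasonal")) {
  mode <- match.arg(mode)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("name must be a non-empty string")
  }
  if (!is.numeric(horizon_months) || length(horizon_months) != 1L ||
      horizon_months < 1) {
    stop("horizon_months must be >= 1")
  }
  if (!start_month %in% 1:12) stop("start_month must be in 1..12")
  structure(list(name = name,
                 initial_composition = validate_composition(initial_composition),
                 policy = policy,
                 settings = settings,
                 start_year = as.integer(start_year),
                 start_month = as.integer(start_month),
                 horizon_months = as.integer(horizon_months),
                 mode = mode),
            class = "scenario_spec")
}

#' The nine reference planting scenarios
#'
#' Builds the published scenario set for the 208-tree Suwon street segment
#' (112 *Zelkova serrata*, 70 *Prunus yedoensis*, no *Pinus densiflora*,
#' 26 pooled other): a baseline with status-quo replacement; four
#' Replace-only scenarios (total fixed at 208) replacing intensively with
#' Zelkova, Prunus, Pinus, or a fixed 30/30/30/10 mix; and four Additional
#' Tree Planting scenarios that start from an expanded 388-tree composition
#' (180 extra trees already planted) and keep the corresponding policy.
#'
#' @param target_ratio intensive planting ratio for the single-priority
#'   scenarios (the study uses 0.7, raised to 0.9 as a sensitivity setting).
#' @param mode `"flat"` or `"seasonal"` absorption accounting for every
#'   scenario.
#' @param settings turnover settings shared by all scenarios.
#' @param horizon_months simulation horizon (default 360).
#' @return Named list of nine [scenario_spec()] objects, baseline first.
#' @export
reference_scenarios <- function(target_ratio = 0.7,
                                mode = c("flat", "seasonal"),
                                settings = turnover_settings(),
                                horizon_months = 360) {
  mode <- match.arg(mode)
  if (!is.numeric(target_ratio) || target_ratio < 0 || target_ratio > 1) {
    stop("target_ratio must be in [0, 1]")
  }
  sp <- c("Zelkova serrata", "Prunus yedoensis", "Pinus densiflora", "other")
  comp <- function(z, p, pi, o) validate_composition(stats::setNames(c(z, p, pi, o), sp))
  base_comp <- comp(112, 70, 0, 26)
  mix <- stats::setNames(c(0.3, 0.3, 0.3, 0.1), sp)
  prio <- function(s) planting_policy("single_priority", priority_species = s,
                                      target_ratio = target_ratio)
  mk <- function(name, comp, policy) {
    scenario_spec(name, comp, policy, settings = settings,
                  horizon_months = horizon_months, mode = mode)
  }
  specs <- list(
    mk("Baseline", base_comp, planting_policy("status_quo")),
    mk("Rep_only_Zelko", base_comp, prio("Zelkova serrata")),
    mk("Rep_only_Prun", base_comp, prio("Prunus yedoensis")),
    mk("Rep_only_Pinus", base_comp, prio("Pinus densiflora")),
    mk("Rep_only_Mix", base_comp, planting_policy("fixed_mix", mix = mix)),
    mk("Plant_more_Zelko", comp(292, 70, 0, 26), prio("Zelkova serrata")),
    mk("Plant_more_Prun", comp(112, 250, 0, 26), prio("Prunus yedoensis")),
    mk("Plant_more_Pinus", comp(112, 70, 180, 26), prio("Pinus densiflora")),
    mk("Plant_more_Mix", comp(172, 130, 60, 26), planting_policy("fixed_mix", mix = mix))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Simulate a scenario
#'
#' Runs the turnover dynamics for the scenario and evaluates monthly PM
#' absorption and the Shannon index along the trajectory. Fully
#' deterministic.
#'
#' @param spec a [scenario_spec()].
#' @param params a [species_params()] table (default [reference_species()]).
#' @param profile a [seasonal_profile()] used to build monthly weights when
#'   `spec$mode == "seasonal"` (ignored in flat mode).
#' @return A `tree_trajectory` data.frame with one row per month from the
#'   initial snapshot (month 0) to the horizon: `month_index`, `date`
#'   (`"YYYY-MM"`), `calendar_month`, one `count_<species>` column per
#'   species, `mpa_g`, `shannon`.
#' @export
run_scenario <- function(spec, params = reference_species(),
                         profile = seasonal_profile()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "species_params"))
  if (spec$mode == "seasonal") {
    params <- apply_seasonal_profile(params, profile)
  }
  path <- run_dynamics(spec$initial_composition, spec$policy, spec$settings,
                       spec$horizon_months)
  n <- nrow(path)
  month_index <- seq_len(n) - 1L
  abs_month <- (spec$start_month - 1L) + month_index
  calendar_month <- (abs_month %% 12L) + 1L
  year <- spec$start_year + abs_month %/% 12L
  sp <- colnames(path)
  mpa <- vapply(seq_len(n), function(i) {
    monthly_pm_absorption(validate_composition(path[i, ]), params,
                          calendar_month = calendar_month[i], mode = spec$mode)
  }, numeric(1))
  shan <- vapply(seq_len(n), function(i) {
    shannon_index(validate_composition(path[i, ]))
  }, numeric(1))
  out <- data.frame(month_index = month_index,
                    date = sprintf("%04d-%02d", year, calendar_month),
                    calendar_month = calendar_month,
                    stringsAsFactors = FALSE)
  counts <- as.data.frame(path)
  names(counts) <- paste0("count_", sp)
  out <- cbind(out, counts, row.names = NULL)
  out$mpa_g <- mpa
  out$shannon <- shan
  attr(out, "scenario") <- spec$name
  attr(out, "mode") <- spec$mode
  class(out) <- c("tree_trajectory", "data.frame")
  out
}

#' Summarize a scenario trajectory
#'
#' Trajectory means are arithmetic means over simulated months 1..horizon;
#' the month-0 initial snapshot enters only `initial_mpa_g`.
#'
#' @param trajectory a [run_scenario()] result.
#' @return One-row data.frame: `name`, `mean_mpa_g`, `initial_mpa_g`,
#'   `final_shannon`, `mean_shannon`, `winter_mean_mpa_g`.
#' @export
summarize_trajectory <- function(trajectory) {
  stopifnot(is.data.frame(trajectory))
  if (nrow(trajectory) == 0L) stop("trajectory is empty")
  sim <- trajectory[trajectory$month_index >= 1, , drop = FALSE]
  if (nrow(sim) == 0L) stop("trajectory has no simulated months")
  data.frame(
    name = attr(trajectory, "scenario") %||% "scenario",
    mean_mpa_g = mean(sim$mpa_g),
    initial_mpa_g = trajectory$mpa_g[trajectory$month_index == 0][1L],
    final_shannon = sim$shannon[which.max(sim$month_index)],
    mean_shannon = mean(sim$shannon),
    winter_mean_mpa_g = winter_mean_absorption(trajectory),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank scenarios under the four assessment criteria
#'
#' Produces the machine twin of the study's assessment table:
#'
#' 1. `pm` — maximize PM absorption: scenarios ordered by mean monthly
#'    absorption, descending.
#' 2. `diversity` — maximize species diversity: ordered by final-month
#'    Shannon index, descending.
#' 3. `both` — improve both against the baseline: scenarios whose mean
#'    absorption AND final Shannon both strictly exceed the baseline's,
#'    ordered by mean absorption (possibly empty).
#' 4. `winter` — maximize winter absorption: ordered by winter-mean
#'    absorption, descending (meaningful for seasonal-mode summaries).
#'
#' Ties are broken lexicographically by scenario name (with a message).
#'
#' @param summaries data.frame of [summarize_trajectory()] rows (one per
#'   scenario).
#' @param baseline_name name of the baseline scenario (must be present).
#' @return A `ranking_report`: list with character vectors `pm`,
#'   `diversity`, `both`, `winter` and the `baseline` row used.
#' @export
rank_scenarios <- function(summaries, baseline_name = "Baseline") {
  stopifnot(is.data.frame(summaries),
            all(c("name", "mean_mpa_g", "final_shannon", "winter_mean_mpa_g")
                %in% names(summaries)))
  if (!baseline_name %in% summaries$name) {
    stop(sprintf("baseline scenario '%s' is missing from the summaries",
                 baseline_name))
  }
  base <- summaries[summaries$name == baseline_name, , drop = FALSE][1L, ]
  ord_by <- function(value) {
    if (anyDuplicated(value)) message("ties broken lexicographically by scenario name")
    summaries$name[order(-value, summaries$name)]
  }
  both_rows <- summaries$mean_mpa_g > base$mean_mpa_g &
    summaries$final_shannon > base$final_shannon
  both <- summaries[both_rows, , drop = FALSE]
  structure(list(pm = ord_by(summaries$mean_mpa_g),
                 diversity = ord_by(summaries$final_shannon),
                 both = both$name[order(-both$mean_mpa_g, both$name)],
                 winter = ord_by(summaries$winter_mean_mpa_g),
                 baseline = baseline_name),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  lab <- c(pm = "Maximize PM absorption",
           diversity = "Maximize species diversity (final Shannon)",
           both = "Improve both vs baseline",
           winter = "Maximize winter PM absorption")
  cat("Scenario ranking (baseline: ", x$baseline, ")\n", sep = "")
  for (k in names(lab)) {
    v <- x[[k]]
    cat(sprintf("  %-45s %s\n", paste0(lab[[k]], ":"),
                if (length(v)) paste(v, collapse = " > ") else "(none)"))
  }
  invisible(x)
}

#' @export
plot.tree_trajectory <- function(x, which = c("counts", "mpa", "shannon"), ...) {
  which <- match.arg(which)
  cols <- grep("^count_", names(x), value = TRUE)
  if (which == "counts") {
    graphics::matplot(x$month_index, as.matrix(x[cols]), type = "l", lty = 1,
                      xlab = "month", ylab = "trees",
                      main = attr(x, "scenario"), ...)
    graphics::legend("topright", legend = sub("^count_", "", cols),
                     col = seq_along(cols), lty = 1, cex = 0.8, bty = "n")
  } else {
    y <- if (which == "mpa") x$mpa_g else x$shannon
    graphics::plot(x$month_index, y, type = "l",
                   xlab = "month",
                   ylab = if (which == "mpa") "PM absorption (g/month)" else "Shannon index",
                   main = attr(x, "scenario"), ...)
  }
  invisible(x)
}
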