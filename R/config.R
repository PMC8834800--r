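#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration describing which scenarios to run and
#' with what settings, validates it and applies defaults: replacement period
#' 240 months, horizon 360 months, start 2021-01, target ratio 0.7, flat
#' mode. Unknown top-level keys are rejected so typos fail loudly.
#'
#' Recognized keys:
#' * `scenarios` — character vector of reference scenario names (see
#'   [reference_scenarios()]), or `"all"` for all nine, and/or a list of
#'   custom scenario blocks (`name`, `initial_composition`, `policy`,
#'   optional `horizon_months`).
#' * `mode` — `"flat"` or `"seasonal"`.
#' * `target_ratio` — intensive planting ratio in \[0, 1\].
#' * `replacement_period_months`, `horizon_months`, `start_year`,
#'   `start_month`, `scheme` — turnover / horizon settings.
#' * `species` — optional list of per-species blocks (`species_id`,
#'   `annual_pm_g`, `phenology`, optional `monthly_weights`) overriding
#'   [reference_species()].
#' * `seasonal_profile` — optional block with [seasonal_profile()] fields.
#' * `output_dir`, `seed`, `log_level` — run plumbing.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` list with all defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop(sprintf("config parse error in '%s': %s",
                                              path, conditionMessage(e))))
  }
  if (!is.list(raw)) stop("config must be a mapping of keys to values")
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw a named list as produced by parsing a config file.
#' @return A `run_config` with defaults applied.
#' @export
validate_config <- function(raw) {
  allowed <- c("scenarios", "mode", "target_ratio", "replacement_period_months",
               "horizon_months", "start_year", "start_month", "scheme",
               "species", "seasonal_profile", "output_dir", "seed", "log_level")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    scenarios = raw$scenarios %||% "all",
    mode = raw$mode %||% "flat",
    target_ratio = raw$target_ratio %||% 0.7,
    replacement_period_months = raw$replacement_period_months %||% 240,
    horizon_months = raw$horizon_months %||% 360,
    start_year = raw$start_year %||% 2021,
    start_month = raw$start_month %||% 1,
    scheme = raw$scheme %||% "first_order",
    species = raw$species,
    seasonal_profile = raw$seasonal_profile,
    output_dir = raw$output_dir %||% ".",
    seed = raw$seed %||% 1L,
    log_level = raw$log_level %||% "info"
  )
  if (!cfg$mode %in% c("flat", "seasonal")) {
    stop("config schema violation: mode must be 'flat' or 'seasonal'")
  }
  if (!is.numeric(cfg$target_ratio) || cfg$target_ratio < 0 || cfg$target_ratio > 1) {
    stop("config schema violation: target_ratio must be in [0, 1]")
  }
  if (!cfg$scheme %in% c("first_order", "cohort")) {
    stop("config schema violation: scheme must be 'first_order' or 'cohort'")
  }
  if (!is.numeric(cfg$horizon_months) || cfg$horizon_months < 1) {
    stop("config schema violation: horizon_months must be >= 1")
  }
  # settings constructor enforces its own invariants
  turnover_settings(cfg$replacement_period_months, scheme = cfg$scheme)
  if (!is.null(cfg$seasonal_profile)) {
    do.call(seasonal_profile, cfg$seasonal_profile)
  }
  if (!is.null(cfg$species)) config_species(cfg)
  known <- names(reference_scenarios(cfg$target_ratio))
  chr <- unlist(Filter(is.character, as.list(cfg$scenarios)))
  bad <- setdiff(setdiff(chr, "all"), known)
  if (length(bad)) {
    stop(sprintf("unknown scenario name(s): %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Species table of a configuration
#'
#' @param config a `run_config`.
#' @return The configured [species_params()] table, or
#'   [reference_species()] when the config has no `species` block.
#' @export
config_species <- function(config) {
  sp <- config$species
  if (is.null(sp)) return(reference_species())
  ids <- vapply(sp, function(s) as.character(s$species_id), character(1))
  annual <- vapply(sp, function(s) as.numeric(s$annual_pm_g), numeric(1))
  phen <- vapply(sp, function(s) as.character(s$phenology), character(1))
  w <- NULL
  if (any(vapply(sp, function(s) !is.null(s$monthly_weights), logical(1)))) {
    w <- t(vapply(sp, function(s) {
      if (is.null(s$monthly_weights)) rep(1 / 12, 12) else as.numeric(s$monthly_weights)
    }, numeric(12)))
  }
  species_params(ids, annual, phen, monthly_weights = w)
}

#' Resolve the scenario specs of a configuration
#'
#' @param config a `run_config`.
#' @return Named list of [scenario_spec()] objects in config order.
#' @export
config_scenarios <- function(config) {
  stopifnot(inherits(config, "run_config"))
  settings <- turnover_settings(config$replacement_period_months,
                                scheme = config$scheme)
  refs <- reference_scenarios(config$target_ratio, mode = config$mode,
                              settings = settings,
                              horizon_months = config$horizon_months)
  entries <- as.list(config$scenarios)
  if (length(entries) == 1L && is.character(entries[[1L]]) &&
      length(entries[[1L]]) > 1L) {
    entries <- as.list(entries[[1L]])
  }
  specs <- list()
  for (e in entries) {
    if (is.character(e)) {
      if (identical(e, "all")) {
        specs <- c(specs, refs)
      } else {
        specs <- c(specs, refs[e])
      }
    } else if (is.list(e)) {
      policy <- do.call(planting_policy, c(list(mode = e$policy$mode),
                                           e$policy[setdiff(names(e$policy), "mode")]))
      comp <- unlist(e$initial_composition)
      specs[[e$name]] <- scenario_spec(
        e$name, comp, policy, settings = settings,
        start_year = config$start_year, start_month = config$start_month,
        horizon_months = e$horizon_months %||% config$horizon_months,
        mode = config$mode
      )
    } else {
      stop("each scenario entry must be a name or a scenario block")
    }
  }
  specs
}

#' Write a configuration (or any serializable list) to YAML
#'
#' Writes with enough floating-point precision that reading the file back
#' reproduces the values bit-identically.
#'
#' @param config a `run_config` (or plain list).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Serialize a species table into config form
#'
#' Produces the list-of-blocks representation accepted by the `species`
#' config key; `write_config()` + `load_config()` round-trips a parameter
#' table exactly.
#'
#' @param params a [species_params()] table.
#' @return List of per-species blocks.
#' @export
species_to_config <- function(params) {
  stopifnot(inherits(params, "species_params"))
  w <- monthly_weights(params)
  lapply(seq_len(nrow(params)), function(i) {
    list(species_id = params$species_id[i],
         annual_pm_g = params$annual_pm_g[i],
         phenology = params$phenology[i],
         monthly_weights = as.numeric(w[i, ]))
  })
}
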