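#' Write a trajectory to CSV
#'
#' Plain-text comma-separated table with one row per month (initial snapshot
#' included) and header `date`, one `count_<species>` column per species,
#' `mpa_g`, `shannon`. Floating values are written at 6 significant digits;
#' UTF-8, LF line endings.
#'
#' @param trajectory a [run_scenario()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(is.data.frame(trajectory))
  cols <- c("date", grep("^count_", names(trajectory), value = TRUE),
            "mpa_g", "shannon")
  out <- trajectory[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(signif(x, 6), format = "g",
                                                   digits = 6))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con, sep = "\n", useBytes = TRUE)
  lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' Restores `month_index` and `calendar_month` from the `date` column so the
#' result can be fed back to [summarize_trajectory()] and
#' [winter_mean_absorption()].
#'
#' @param path CSV file path.
#' @return A data.frame in trajectory layout.
#' @export
read_trajectory <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"date" %in% names(x)) stop("not a trajectory file: no 'date' column")
  x$calendar_month <- as.integer(sub("^\\d{4}-", "", x$date))
  x$month_index <- seq_len(nrow(x)) - 1L
  class(x) <- c("tree_trajectory", "data.frame")
  x
}

#' Write scenario summaries to CSV
#'
#' @param summaries data.frame of [summarize_trajectory()] rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a set of scenarios and summarize them
#'
#' Convenience driver used by the analysis scripts and the acceptance
#' pipeline: simulates each spec and binds the one-row summaries.
#'
#' @param specs named list of [scenario_spec()] objects (e.g.
#'   [reference_scenarios()]).
#' @param params a [species_params()] table.
#' @param profile a [seasonal_profile()] for seasonal-mode specs.
#' @return List with `trajectories` (named list) and `summaries`
#'   (data.frame, one row per scenario).
#' @export
run_scenarios <- function(specs, params = reference_species(),
                          profile = seasonal_profile()) {
  trajs <- lapply(specs, run_scenario, params = params, profile = profile)
  summaries <- do.call(rbind, lapply(trajs, summarize_trajectory))
  rownames(summaries) <- NULL
  list(trajectories = trajs, summaries = summaries)
}
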