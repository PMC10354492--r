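# Tidy-CSV and results-JSON readers/writers, and the end-to-end driver.

session_schema <- function() {
  c(set_id = "integer", session_seed = "integer", round_index = "integer",
    group_id = "character", player_id = "integer",
    threshold_active = "logical", punishment_level = "character",
    inequality_condition = "character", points_before = "numeric",
    trust_rating = "integer", steal_likelihood_rating = "integer",
    action = "character", steal_outcome = "character",
    delta_points = "numeric", perturbation = "integer",
    points_after = "numeric", below_threshold_flag = "logical",
    active = "logical")
}

#' Write a session log to CSV
#'
#' Plain comma-separated UTF-8 with a header row, `.` decimal separator and
#' no index column; one row per player-round.
#'
#' @param dataset Session log data frame.
#' @param path Output path.
#' @export
write_session_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a session log CSV
#'
#' Reads a CSV written by [write_session_csv()] (or any file following the
#' same schema), types every column, and checks the row-wise invariants:
#' `points_after = points_before + delta_points + perturbation`, and
#' `steal_outcome != "n/a"` exactly for steal actions. Violations are
#' reported with their row index.
#'
#' @param path Input path.
#' @return Typed session log data frame, row order preserved.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  schema <- session_schema()
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(schema), names(d))
  if (length(missing_cols)) {
    stop("session CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in names(schema)) {
    d[[cl]] <- switch(schema[[cl]],
      integer = as.integer(d[[cl]]),
      numeric = as.numeric(d[[cl]]),
      logical = as.logical(d[[cl]]),
      character = as.character(d[[cl]])
    )
  }
  bad_sum <- which(abs(d$points_after -
                         (d$points_before + d$delta_points +
                            d$perturbation)) > 1e-9)
  if (length(bad_sum)) {
    stop("points accounting invariant violated at row(s): ",
         paste(utils::head(bad_sum, 5), collapse = ", "), call. = FALSE)
  }
  bad_outcome <- which((d$action == "steal") == (d$steal_outcome == "n/a"))
  if (length(bad_outcome)) {
    stop("steal_outcome/action invariant violated at row(s): ",
         paste(utils::head(bad_outcome, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' Write a results table as JSON
#'
#' Serializes a prediction-suite table (or any data frame) as a JSON array
#' of row objects with stable key order and fixed numeric precision, and
#' reads back with [read_results_json()].
#'
#' @param results Non-empty data frame (e.g. from [run_prediction_suite()]).
#' @param path Output path.
#' @param digits Decimal digits for numeric fields (default 6).
#' @export
write_results_json <- function(results, path, digits = 6) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("results table is empty", call. = FALSE)
  }
  jsonlite::write_json(as.data.frame(results), path, dataframe = "rows",
                       digits = digits, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::fromJSON(path)
}

#' Simulate, filter and analyse one study end to end
#'
#' The composition used by the analysis drivers: simulate `n_sets` sessions
#' of the study with the chosen synthetic-agent preset, apply the
#' completion exclusions, run the registered prediction suite (for study 4
#' this covers all rounds and the first four rounds), and optionally write
#' the session CSV, the results JSON and a run manifest (YAML echo of seed,
#' study, policy and condition counts) next to them.
#'
#' @param study Integer 1:4.
#' @param n_sets Sets to simulate.
#' @param policy Policy object or preset name (see [policy_preset()]).
#' @param master_seed Master seed for the whole run.
#' @param out_dir Optional output directory; when given, writes
#'   `sim_study<k>.csv`, `results_study<k>.json` and
#'   `manifest_study<k>.yaml`.
#' @param n_bootstrap Mediation bootstrap draws (study 1).
#' @return List with `dataset` (post-exclusion), `suite`, `payouts`,
#'   `manifest`.
#' @export
replicate_study <- function(study, n_sets, policy = "paper_like",
                            master_seed = 1L, out_dir = NULL,
                            n_bootstrap = 200L) {
  if (is.character(policy)) policy <- policy_preset(policy)
  sim <- run_study(study, n_sets, policy, master_seed)
  dat <- apply_exclusions(sim)
  suite <- run_prediction_suite(study, dat, n_bootstrap = n_bootstrap)
  manifest <- c(attr(sim, "manifest"), list(
    n_players = length(unique(sim$player_id)),
    n_excluded = length(attr(dat, "excluded_players")),
    condition_counts = as.list(table(paste0(
      "thr_", sim$threshold_active[!duplicated(sim$player_id)]
    )))
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session_csv(sim, file.path(out_dir,
                                     sprintf("sim_study%d.csv", study)))
    write_results_json(suite, file.path(out_dir,
                                        sprintf("results_study%d.json",
                                                study)))
    yaml::write_yaml(manifest, file.path(out_dir,
                                         sprintf("manifest_study%d.yaml",
                                                 study)))
  }
  list(dataset = dat, suite = suite, payouts = attr(sim, "payouts"),
       manifest = manifest)
}
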