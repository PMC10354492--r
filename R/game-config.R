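#' Game configuration for one microsociety study
#'
#' Bundles every numeric parameter of the economic game: payoffs for
#' cooperating, stealing and working alone, the desperation threshold, the
#' per-round random perturbation, cash conversion, the below-threshold payout
#' penalty, and the round structure. The four study presets are available
#' through [study_config()].
#'
#' Stealing must have a negative expected return:
#' `steal_success_prob * steal_gain + (1 - steal_success_prob) * penalty < 0`
#' for every admissible penalty. [validate_config()] enforces this and the
#' other structural invariants.
#'
#' @param study_label Study id, one of 1:4.
#' @param cooperate_gain Points gained by each cooperator when cooperation
#'   succeeds (at least two cooperators, no steal attempt in the group).
#' @param stolen_loss Points change (negative) for a cooperator when at least
#'   one steal attempt in the group succeeds.
#' @param steal_gain Points gained by a successful stealer.
#' @param steal_penalty_lenient,steal_penalty_harsh Points change (negative)
#'   for a caught stealer under lenient / harsh punishment.
#'   `steal_penalty_harsh` is `NA` except in study 3.
#' @param work_alone_payoff Points for working alone (always 0).
#' @param steal_success_prob Probability a steal attempt succeeds.
#' @param threshold_level Desperation threshold in points.
#' @param perturbation_sd Standard deviation of the per-round discretized
#'   Gaussian shock to points (0 disables it).
#' @param conversion_rate Currency units per point at payout.
#' @param below_round_penalty Currency penalty per real round spent strictly
#'   below `threshold_level` (applied only in threshold conditions).
#' @param n_mock_rounds Number of practice rounds before points reset.
#' @param real_round_rule `"uniform_8_16"` (number of real rounds uniform on
#'   8..16) or `"fixed_12"`.
#' @param set_size Players per session set.
#' @param group_size Players per interaction group.
#' @param currency `"GBP"` or `"USD"`, informational only.
#'
#' @return A list of class `"micsoc_config"`.
#' @seealso [study_config()], [validate_config()]
#' @export
game_config <- function(study_label,
                        cooperate_gain = 5,
                        stolen_loss = -5,
                        steal_gain = 20,
                        steal_penalty_lenient = -40,
                        steal_penalty_harsh = NA_real_,
                        work_alone_payoff = 0,
                        steal_success_prob = 0.5,
                        threshold_level = 100,
                        perturbation_sd = 3,
                        conversion_rate = 0.02,
                        below_round_penalty = 0.50,
                        n_mock_rounds = 5,
                        real_round_rule = c("uniform_8_16", "fixed_12"),
                        set_size = 8L,
                        group_size = 4L,
                        currency = "GBP") {
  real_round_rule <- match.arg(real_round_rule)
  cfg <- list(
    study_label = as.integer(study_label),
    cooperate_gain = cooperate_gain,
    stolen_loss = stolen_loss,
    steal_gain = steal_gain,
    steal_penalty_lenient = steal_penalty_lenient,
    steal_penalty_harsh = steal_penalty_harsh,
    work_alone_payoff = work_alone_payoff,
    steal_success_prob = steal_success_prob,
    threshold_level = threshold_level,
    perturbation_sd = perturbation_sd,
    conversion_rate = conversion_rate,
    below_round_penalty = below_round_penalty,
    n_mock_rounds = as.integer(n_mock_rounds),
    real_round_rule = real_round_rule,
    set_size = as.integer(set_size),
    group_size = as.integer(group_size),
    currency = currency
  )
  class(cfg) <- "micsoc_config"
  validate_config(cfg)
  cfg
}

#' Validate a game configuration
#'
#' Checks the structural invariants of a [game_config()]: stealing has a
#' negative expected return under every admissible punishment, the set size is
#' an exact multiple of the group size, probabilities are in range, and the
#' point perturbation is disabled in studies 3-4.
#'
#' @param config A `"micsoc_config"` object.
#' @param stop_on_error If `TRUE` (default) signal an error listing every
#'   violated invariant; if `FALSE` return the character vector of violations
#'   (length zero when valid).
#' @return Invisibly, the (valid) config, or the violation messages when
#'   `stop_on_error = FALSE`.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  bad <- character(0)
  p <- config$steal_success_prob
  if (!is.numeric(p) || p < 0 || p > 1) {
    bad <- c(bad, "steal_success_prob must lie in [0, 1]")
  }
  penalties <- c(config$steal_penalty_lenient, config$steal_penalty_harsh)
  penalties <- penalties[!is.na(penalties)]
  for (pen in penalties) {
    ev <- p * config$steal_gain + (1 - p) * pen
    if (!(ev < 0)) {
      bad <- c(bad, sprintf(
        "stealing must have negative expected return: %g * %g + %g * %g = %g >= 0",
        p, config$steal_gain, 1 - p, pen, ev
      ))
    }
  }
  if (config$set_size %% config$group_size != 0) {
    bad <- c(bad, "set_size must be an exact multiple of group_size")
  }
  if (config$study_label %in% c(3L, 4L) && config$perturbation_sd != 0) {
    bad <- c(bad, "perturbation_sd must be 0 in studies 3 and 4")
  }
  if (config$n_mock_rounds < 0) bad <- c(bad, "n_mock_rounds must be >= 0")
  if (config$perturbation_sd < 0) bad <- c(bad, "perturbation_sd must be >= 0")
  if (config$below_round_penalty < 0) {
    bad <- c(bad, "below_round_penalty must be >= 0")
  }
  if (length(bad) && stop_on_error) {
    stop("invalid game configuration:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  if (stop_on_error) invisible(config) else bad
}

#' Study presets: configuration and condition scheme
#'
#' Returns the exact parameterization of one of the four studies together
#' with its condition-assignment scheme. Studies 1-2 (UK): cooperate +5 /
#' stolen -5, steal +20 / caught -40, threshold 100, 2 pence per point,
#' 50 pence per below-threshold round, 5 mock rounds, 8-16 real rounds.
#' Studies 3-4 (US): steal +10, caught -15 (study 3 adds a harsh -30 arm),
#' threshold 200, no point perturbation, 1 cent per point, 20 cents per
#' below round, 4 mock rounds; study 4 plays a fixed 12 real rounds.
#'
#' The condition scheme records how treatments are allocated: study 1 runs
#' every set in the threshold condition; study 2 varies threshold presence
#' between sets; study 3 crosses threshold presence with punishment severity
#' within each set; study 4 crosses threshold presence with starting-points
#' inequality between sets.
#'
#' @param study Integer in 1:4.
#' @return A list with elements `config` (a [game_config()]) and `scheme`
#'   (a list with `threshold_assignment`, `punishment_assignment`,
#'   `inequality_assignment`).
#' @examples
#' study_config(3)$config$steal_penalty_harsh  # -30
#' @export
study_config <- function(study) {
  study <- as.integer(study)
  if (length(study) != 1L || is.na(study) || !study %in% 1:4) {
    stop("unknown study id: must be 1, 2, 3 or 4", call. = FALSE)
  }
  config <- switch(study,
    # study 1
    game_config(1L),
    # study 2
    game_config(2L),
    # study 3
    game_config(3L,
      steal_gain = 10, steal_penalty_lenient = -15, steal_penalty_harsh = -30,
      threshold_level = 200, perturbation_sd = 0, conversion_rate = 0.01,
      below_round_penalty = 0.20, n_mock_rounds = 4,
      real_round_rule = "uniform_8_16", currency = "USD"
    ),
    # study 4
    game_config(4L,
      steal_gain = 10, steal_penalty_lenient = -15,
      threshold_level = 200, perturbation_sd = 0, conversion_rate = 0.01,
      below_round_penalty = 0.20, n_mock_rounds = 4,
      real_round_rule = "fixed_12", currency = "USD"
    )
  )
  scheme <- switch(study,
    list(threshold_assignment = "all_threshold",
         punishment_assignment = "none",
         inequality_assignment = "none"),
    list(threshold_assignment = "between_sets",
         punishment_assignment = "none",
         inequality_assignment = "none"),
    list(threshold_assignment = "within_set",
         punishment_assignment = "within_set",
         inequality_assignment = "none"),
    list(threshold_assignment = "between_sets",
         punishment_assignment = "fixed_lenient",
         inequality_assignment = "between_sets")
  )
  list(config = config, scheme = scheme)
}

#' Read or write a study configuration as YAML
#'
#' `write_config_yaml()` serializes one or more configurations (field names
#' as in [game_config()]); `read_config_yaml()` reads them back and
#' validates each block, reporting every violated invariant.
#'
#' @param configs A named list of `"micsoc_config"` objects (names are block
#'   labels, e.g. `"study1"`).
#' @param path File path.
#' @return `read_config_yaml()`: a named list of validated configs.
#' @export
write_config_yaml <- function(configs, path) {
  if (inherits(configs, "micsoc_config")) configs <- list(config = configs)
  plain <- lapply(configs, function(cfg) unclass(cfg))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  blocks <- yaml::read_yaml(path)
  out <- lapply(blocks, function(b) {
    b$steal_penalty_harsh <- if (is.null(b$steal_penalty_harsh)) NA_real_ else b$steal_penalty_harsh
    do.call(game_config, b)
  })
  out
}

#' @export
print.micsoc_config <- function(x, ...) {
  cat(sprintf("<micsoc_config> study %d (%s)\n", x$study_label, x$currency))
  cat(sprintf("  cooperate %+g / stolen %+g; steal %+g / caught %+g",
              x$cooperate_gain, x$stolen_loss, x$steal_gain,
              x$steal_penalty_lenient))
  if (!is.na(x$steal_penalty_harsh)) {
    cat(sprintf(" (harsh %+g)", x$steal_penalty_harsh))
  }
  cat("\n")
  cat(sprintf("  threshold %g, perturbation sd %g, %d mock rounds, %s\n",
              x$threshold_level, x$perturbation_sd, x$n_mock_rounds,
              x$real_round_rule))
  cat(sprintf("  payout %g %s/point, below-round penalty %g %s\n",
              x$conversion_rate, x$currency, x$below_round_penalty, x$currency))
  invisible(x)
}
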