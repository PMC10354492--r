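#' Randomly partition a set of eight players into two interaction groups
#'
#' Each round the eight players of a set are re-drawn at random into two
#' disjoint interaction groups of four. The partition is uniform over all
#' ways of splitting the set and independent across rounds; it is
#' deterministic given the R random-number stream.
#'
#' @param set_members Vector of exactly `set_size` player ids.
#' @param group_size Players per group (default 4).
#' @return A list with `A` and `B`, each a vector of `group_size` ids, and
#'   `group_of`, a named vector mapping id to `"A"`/`"B"`.
#' @examples
#' set.seed(1)
#' form_groups(1:8)
#' @export
form_groups <- function(set_members, group_size = 4L) {
  n <- length(set_members)
  if (n != 2L * group_size) {
    stop(sprintf("form_groups() needs exactly %d members, got %d",
                 2L * group_size, n), call. = FALSE)
  }
  idx <- sample.int(n)
  a <- set_members[idx[seq_len(group_size)]]
  b <- set_members[idx[group_size + seq_len(group_size)]]
  group_of <- stats::setNames(rep(c("A", "B"), each = group_size),
                              c(as.character(a), as.character(b)))
  list(A = a, B = b, group_of = group_of)
}

#' Draw success flags for a round's steal attempts
#'
#' A steal attempt succeeds or is caught with equal probability (more
#' generally, with `steal_success_prob`), independently per attempt.
#'
#' @param n_stealers Number of attempts this round (>= 0).
#' @param steal_success_prob Success probability (default 0.5).
#' @return Logical vector of length `n_stealers` (`TRUE` = success).
#' @export
draw_steal_outcomes <- function(n_stealers, steal_success_prob = 0.5) {
  if (n_stealers < 0) stop("n_stealers must be >= 0", call. = FALSE)
  if (n_stealers == 0L) return(logical(0))
  stats::runif(n_stealers) < steal_success_prob
}

#' Resolve one interaction group's actions into point changes
#'
#' Applies the payoff rules of the game to a group of four:
#' * `work_alone` never gains or loses points;
#' * each cooperator gains `cooperate_gain` iff the group holds at least two
#'   cooperators and nobody attempted to steal;
#' * when at least one steal attempt succeeds, every cooperator loses
#'   `|stolen_loss|` exactly once that round (a caught attempt harms no one,
#'   but its mere occurrence already cancels the cooperation gain);
#' * a stealer needs at least one cooperator present to have a target: with
#'   one, the attempt succeeds (`+steal_gain`) or is caught (their own
#'   punishment-level penalty) according to the supplied flag; with none the
#'   attempt fizzles (`no_target`, delta 0, no punishment risk).
#'
#' @param actions Character vector of `group_size` actions among
#'   `"cooperate"`, `"steal"`, `"work_alone"`.
#' @param steal_success_flags Logical vector, one flag per stealer in the
#'   order they appear in `actions`.
#' @param config A [game_config()].
#' @param punishment_levels Per-player punishment level (`"lenient"`,
#'   `"harsh"` or `"n/a"`); levels may differ inside one group because the
#'   punishment treatment can be assigned within a set.
#' @return A list with `delta` (numeric per player) and `steal_outcome`
#'   (`"success"`, `"caught"`, `"no_target"` for stealers, `"n/a"` otherwise).
#' @export
resolve_group <- function(actions, steal_success_flags, config,
                          punishment_levels = rep("lenient", length(actions))) {
  g <- config$group_size
  if (length(actions) != g) {
    stop(sprintf("expected %d actions, got %d", g, length(actions)),
         call. = FALSE)
  }
  if (length(punishment_levels) != g) {
    stop("punishment_levels must have one entry per player", call. = FALSE)
  }
  bad <- setdiff(actions, c("cooperate", "steal", "work_alone"))
  if (length(bad)) stop("unknown action(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  is_coop <- actions == "cooperate"
  is_steal <- actions == "steal"
  n_coop <- sum(is_coop)
  n_steal <- sum(is_steal)
  if (length(steal_success_flags) != n_steal) {
    stop(sprintf("expected %d steal success flags, got %d", n_steal,
                 length(steal_success_flags)), call. = FALSE)
  }

  delta <- rep(0, g)
  outcome <- rep("n/a", g)

  # Cooperators: small gain only with >= 2 cooperators and zero attempts;
  # one stolen_loss hit if any attempt succeeded.
  any_success <- n_steal > 0L && n_coop > 0L && any(steal_success_flags)
  if (n_coop >= 2L && n_steal == 0L) {
    delta[is_coop] <- config$cooperate_gain
  } else if (any_success) {
    delta[is_coop] <- config$stolen_loss
  }

  # Stealers: the gamble runs only when a cooperator is present.
  if (n_steal > 0L) {
    if (n_coop == 0L) {
      outcome[is_steal] <- "no_target"
    } else {
      pen <- ifelse(punishment_levels[is_steal] == "harsh",
                    config$steal_penalty_harsh, config$steal_penalty_lenient)
      delta[is_steal] <- ifelse(steal_success_flags, config$steal_gain, pen)
      outcome[is_steal] <- ifelse(steal_success_flags, "success", "caught")
    }
  }

  list(delta = delta, steal_outcome = outcome)
}

#' Apply the per-round random shock to a player's points
#'
#' In studies 1-2 every real round adds a shock drawn from a discretized
#' Gaussian with mean 0 and standard deviation `perturbation_sd`, implemented
#' as the nearest-integer rounding of a continuous Normal draw (the rounding
#' adds roughly 1/12 to the variance, i.e. inflates the sd by about 1/216
#' relative at sd 3). With `perturbation_sd = 0` (studies 3-4) the shock is
#' identically zero.
#'
#' @param points Current integer points.
#' @param config A [game_config()].
#' @return A list with `points` (new level) and `perturbation` (the integer
#'   shock applied).
#' @export
apply_perturbation <- function(points, config) {
  if (config$perturbation_sd == 0) {
    return(list(points = points, perturbation = rep(0L, length(points))))
  }
  shock <- as.integer(round(stats::rnorm(length(points), 0,
                                         config$perturbation_sd)))
  list(points = points + shock, perturbation = shock)
}

#' Convert final points to a cash payout
#'
#' Final points convert at `conversion_rate`; in threshold conditions a
#' penalty of `below_round_penalty` is then subtracted for every real round
#' the player spent strictly below the threshold. The payout is floored at
#' zero (a few below-threshold rounds are enough to wipe out game earnings,
#' but earnings never go negative).
#'
#' @param final_points Points at the end of the last real round.
#' @param below_round_count Number of real rounds with points below the
#'   threshold.
#' @param threshold_active Is this player in a threshold condition?
#' @param config A [game_config()].
#' @return Cash amount (in `config$currency` units), >= 0.
#' @examples
#' settle_payout(120, 2, TRUE, study_config(1)$config)  # 1.40
#' @export
settle_payout <- function(final_points, below_round_count, threshold_active,
                          config) {
  if (any(below_round_count < 0)) {
    stop("below_round_count must be >= 0", call. = FALSE)
  }
  gross <- final_points * config$conversion_rate
  penalty <- ifelse(threshold_active,
                    below_round_count * config$below_round_penalty, 0)
  pmax(0, gross - penalty)
}

# Internal: run one round for all 8 players, mutating the state environment.
# Returns the per-round record as a list of column vectors.
run_round_impl <- function(state, config, policy, round_index, is_real) {
  n <- config$set_size
  pts_before <- state$points
  groups <- form_groups(seq_len(n), config$group_size)
  group_id <- unname(groups$group_of[as.character(seq_len(n))])

  # trust elicited before the decision
  ratings <- emit_ratings(state$latent_trust, state$policy_params,
                          with_steal_rating = config$study_label %in% c(3L, 4L))

  actions <- policy_actions(policy, state, round_index, config)
  actions[!state$active] <- "work_alone"

  delta <- numeric(n)
  outcome <- rep("n/a", n)
  for (g in c("A", "B")) {
    members <- if (g == "A") groups$A else groups$B
    acts <- actions[members]
    flags <- draw_steal_outcomes(sum(acts == "steal"),
                                 config$steal_success_prob)
    res <- resolve_group(acts, flags, config,
                         punishment_levels = state$punishment_level[members])
    delta[members] <- res$delta
    outcome[members] <- res$steal_outcome
  }

  if (is_real && config$perturbation_sd > 0) {
    pert <- apply_perturbation(state$points, config)$perturbation
  } else {
    pert <- rep(0L, n)
  }
  pts_after <- pts_before + delta + pert
  state$points <- pts_after
  below_after <- pts_after < config$threshold_level
  if (is_real) {
    state$below_round_count <- state$below_round_count + as.integer(below_after)
  }

  # trust updates from the player's own group's attempts by *other* players
  n_steal_grp <- tapply(actions == "steal", group_id, sum)[group_id]
  others_stealing <- n_steal_grp - (actions == "steal")
  state$latent_trust <- update_trust(state$latent_trust, others_stealing,
                                     config$group_size,
                                     state$policy_params$lambda_trust)

  list(
    round_index = rep(round_index, n), group_id = group_id,
    player_id = state$player_id, threshold_active = state$threshold_active,
    punishment_level = state$punishment_level,
    inequality_condition = state$inequality_condition,
    points_before = pts_before, trust_rating = ratings$trust_rating,
    steal_likelihood_rating = ratings$steal_likelihood_rating,
    action = actions, steal_outcome = outcome, delta_points = delta,
    perturbation = pert, points_after = pts_after,
    below_threshold_flag = below_after, active = state$active
  )
}

#' Run one full session of the microsociety game
#'
#' Plays `n_mock_rounds` practice rounds (indexed `-(n_mock_rounds-1) .. 0`),
#' resets points to a fresh starting allocation (mock and real allocations
#' are independent draws), then plays the real rounds (indexed `1..R`, with
#' `R` drawn uniformly from 8..16 or fixed at 12 according to the config),
#' and settles payouts. Each round: interaction groups are redrawn, trust is
#' elicited, actions are chosen by the policy (inactive players work alone),
#' groups are resolved, and in studies 1-2 the random point perturbation is
#' applied. The whole session is reproducible from `seed`.
#'
#' @param config A [game_config()].
#' @param players Data frame with one row per player: `player_id`,
#'   `threshold_active` (logical), `punishment_level`,
#'   `inequality_condition`, `random_intercept` (log-odds offset, default 0).
#'   See [assign_conditions()].
#' @param policy A policy object from [policy_preset()] or
#'   [make_generative_policy()].
#' @param seed Integer seed for the session substream.
#' @param set_id Session/set identifier recorded in the log.
#' @param start_fun Function `(n)` returning the starting points allocation;
#'   called once for the mock rounds and once, independently, for the real
#'   rounds. Defaults to the study's allocation rule via
#'   [draw_starting_points()].
#' @param inactivation_prob Per-round probability that an active player drops
#'   out (then works alone for the rest of the session). Default 0.
#' @return A data frame of one row per player-round (the session log), with
#'   a `payouts` attribute (data frame: player_id, final_points,
#'   below_round_count, payout).
#' @export
run_session <- function(config, players, policy, seed, set_id = 1L,
                        start_fun = NULL, inactivation_prob = 0) {
  validate_config(config)
  n <- config$set_size
  if (nrow(players) != n) {
    stop(sprintf("players must have %d rows", n), call. = FALSE)
  }
  if (is.null(players$random_intercept)) players$random_intercept <- 0
  if (is.null(start_fun)) {
    start_fun <- function(k) {
      draw_starting_points(config$study_label,
                           players$inequality_condition[1], k)
    }
  }
  set.seed(as.integer(seed))

  pp <- policy$params %||% policy_params()
  state <- new.env(parent = emptyenv())
  state$player_id <- players$player_id
  state$threshold_active <- players$threshold_active
  state$punishment_level <- as.character(players$punishment_level)
  state$inequality_condition <- as.character(players$inequality_condition)
  state$random_intercept <- players$random_intercept
  state$latent_trust <- rep(pp$trust_init, n)
  state$below_round_count <- rep(0L, n)
  state$active <- rep(TRUE, n)
  state$policy_params <- pp
  state$threshold_level <- config$threshold_level

  records <- list()
  # mock rounds: indices -(m-1) .. 0, points from a first allocation draw
  state$points <- start_fun(n)
  m <- config$n_mock_rounds
  mock_idx <- if (m > 0) seq(-(m - 1L), 0L) else integer(0)
  for (r in mock_idx) {
    if (inactivation_prob > 0) {
      state$active <- state$active &
        (stats::runif(n) >= inactivation_prob)
    }
    records[[length(records) + 1L]] <-
      run_round_impl(state, config, policy, r, is_real = FALSE)
  }

  # reset: real-round allocation is an independent draw
  state$points <- start_fun(n)
  state$below_round_count <- rep(0L, n)

  n_real <- draw_n_real_rounds(config)
  for (r in seq_len(n_real)) {
    if (inactivation_prob > 0) {
      state$active <- state$active &
        (stats::runif(n) >= inactivation_prob)
    }
    records[[length(records) + 1L]] <-
      run_round_impl(state, config, policy, r, is_real = TRUE)
  }

  cols <- names(records[[1]])
  log <- as.data.frame(
    stats::setNames(lapply(cols, function(cl) {
      unlist(lapply(records, `[[`, cl), use.names = FALSE)
    }), cols),
    stringsAsFactors = FALSE
  )
  log <- cbind(set_id = set_id, session_seed = as.integer(seed), log)

  payouts <- data.frame(
    player_id = state$player_id,
    final_points = state$points,
    below_round_count = state$below_round_count,
    payout = settle_payout(state$points, state$below_round_count,
                           state$threshold_active, config)
  )
  attr(log, "payouts") <- payouts
  attr(log, "n_real_rounds") <- n_real
  log
}

#' Draw the number of real rounds for a session
#'
#' Uniform on 8..16 (`"uniform_8_16"`, studies 1-3; players are not told the
#' session length) or a fixed 12 rounds (`"fixed_12"`, study 4).
#'
#' @param config A [game_config()].
#' @return Integer round count.
#' @export
draw_n_real_rounds <- function(config) {
  switch(config$real_round_rule,
    uniform_8_16 = sample(8:16, 1L),
    fixed_12 = 12L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
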