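#' Starting points allocation for a set
#'
#' Study 1 and 2: every player starts on 100 points (exactly at the
#' threshold in study 1's design). Study 3: i.i.d. draws from
#' \{180, 190, 200\} with equal probability (most players start below the
#' 200 threshold). Study 4, equal condition: all on 205; unequal condition:
#' exactly two players per value of \{180, 190, 220, 230\}, randomly
#' assigned, so the set mean is 205 and half the players start below 200.
#'
#' @param study Integer 1:4.
#' @param inequality_condition `"equal"`, `"unequal"` or `"n/a"`;
#'   required for study 4.
#' @param n Number of players (default 8).
#' @return Integer vector of starting points, length `n`.
#' @export
draw_starting_points <- function(study, inequality_condition = "n/a", n = 8L) {
  study <- as.integer(study)
  if (study %in% c(1L, 2L)) {
    return(rep(100L, n))
  }
  if (study == 3L) {
    return(sample(c(180L, 190L, 200L), n, replace = TRUE))
  }
  if (study == 4L) {
    if (identical(inequality_condition, "equal")) {
      return(rep(205L, n))
    }
    if (identical(inequality_condition, "unequal")) {
      if (n %% 4L != 0L) {
        stop("unequal allocation needs a multiple of 4 players", call. = FALSE)
      }
      return(sample(rep(c(180L, 190L, 220L, 230L), n / 4L)))
    }
    stop("study 4 needs inequality_condition 'equal' or 'unequal'",
         call. = FALSE)
  }
  stop("unknown study id: must be 1, 2, 3 or 4", call. = FALSE)
}

#' Assign treatment conditions to one set's players
#'
#' Study 1: every set plays with the threshold in force. Study 2: threshold
#' presence alternates deterministically between sets (odd set index:
#' threshold; even: no threshold), so half the sets are in each condition
#' for even set counts. Study 3: threshold presence and punishment severity
#' are crossed *within* each set, two players per cell, with random
#' assignment of players to cells. Study 4: sets rotate round-robin through
#' the four cells of \{equal, unequal\} x \{threshold, no threshold\};
#' punishment is lenient throughout.
#'
#' @param study Integer 1:4.
#' @param set_index 1-based index of the set within the study.
#' @param set_size Players per set (default 8).
#' @return Data frame with `player_id` (1..set_size, local ids),
#'   `threshold_active`, `punishment_level`, `inequality_condition`.
#' @export
assign_conditions <- function(study, set_index, set_size = 8L) {
  study <- as.integer(study)
  pid <- seq_len(set_size)
  base <- data.frame(
    player_id = pid,
    threshold_active = TRUE,
    punishment_level = "n/a",
    inequality_condition = "n/a",
    stringsAsFactors = FALSE
  )
  if (study == 1L) {
    return(base)
  }
  if (study == 2L) {
    base$threshold_active <- (set_index %% 2L) == 1L
    return(base)
  }
  if (study == 3L) {
    # 2 players per cell of {threshold, no} x {lenient, harsh}, randomized
    cells <- expand.grid(thr = c(TRUE, FALSE),
                         pun = c("lenient", "harsh"),
                         stringsAsFactors = FALSE)
    cell_of <- sample(rep(seq_len(4L), each = set_size / 4L))
    base$threshold_active <- cells$thr[cell_of]
    base$punishment_level <- cells$pun[cell_of]
    return(base)
  }
  if (study == 4L) {
    cells <- expand.grid(ineq = c("equal", "unequal"),
                         thr = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
    cell <- ((set_index - 1L) %% 4L) + 1L
    base$threshold_active <- cells$thr[cell]
    base$punishment_level <- "lenient"
    base$inequality_condition <- cells$ineq[cell]
    return(base)
  }
  stop("unknown study id: must be 1, 2, 3 or 4", call. = FALSE)
}

#' Derive a session substream seed from a master seed
#'
#' Fixed derivation
#' `(master_seed + 1000003 * set_index + 7919 * stream) mod (2^31 - 1)`,
#' keeping the result a valid 32-bit integer seed. `stream` separates the
#' different uses of randomness for one set (0: the session itself,
#' 1: condition assignment and random intercepts).
#'
#' @param master_seed Integer master seed.
#' @param set_index 1-based set index.
#' @param stream Small non-negative integer stream id.
#' @return Integer seed for [run_session()].
#' @export
session_seed <- function(master_seed, set_index, stream = 0L) {
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(set_index) +
                7919 * as.numeric(stream)) %% 2147483647)
}

#' Simulate a whole study as one tidy dataset
#'
#' Runs `n_sets` independent sessions of the given study design with
#' synthetic agents, each on its own derived random substream, and
#' concatenates the session logs. Player ids are globally unique
#' (`set_index * 100 + local id`). Random intercepts are drawn per set from
#' the policy's `sigma_id`.
#'
#' @param study Integer 1:4.
#' @param n_sets Number of 8-player sets to simulate (>= 1).
#' @param policy Policy object (see [policy_preset()]); default
#'   `"paper_like"`.
#' @param master_seed Master seed; session substreams are derived via
#'   [session_seed()].
#' @param inactivation_prob Optional per-round dropout probability
#'   (default 0), to exercise the inactivity and exclusion rules.
#' @return Data frame of [run_session()] logs row-bound across sets, with
#'   attributes `payouts` (row-bound) and `manifest` (list: study, n_sets,
#'   master_seed, policy type, n_real_rounds per set).
#' @export
run_study <- function(study, n_sets, policy = policy_preset("paper_like"),
                      master_seed = 1L, inactivation_prob = 0) {
  if (n_sets < 1L) stop("n_sets must be >= 1", call. = FALSE)
  sc <- study_config(study)
  config <- sc$config
  logs <- vector("list", n_sets)
  pays <- vector("list", n_sets)
  n_real <- integer(n_sets)
  for (s in seq_len(n_sets)) {
    seed_s <- session_seed(master_seed, s)
    set.seed(session_seed(master_seed, s, stream = 1L))
    players <- assign_conditions(study, s, config$set_size)
    players$player_id <- s * 100L + players$player_id
    players$random_intercept <-
      stats::rnorm(config$set_size, 0, policy$params$sigma_id)
    log <- run_session(config, players, policy, seed = seed_s, set_id = s,
                       inactivation_prob = inactivation_prob)
    logs[[s]] <- log
    pays[[s]] <- cbind(set_id = s, attr(log, "payouts"))
    n_real[s] <- attr(log, "n_real_rounds")
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "payouts") <- do.call(rbind, pays)
  attr(out, "manifest") <- list(
    study = as.integer(study), n_sets = as.integer(n_sets),
    master_seed = as.integer(master_seed), policy = policy$type,
    n_real_rounds = n_real
  )
  out
}

#' Apply the analysis exclusions to a session dataset
#'
#' Removes mock rounds (`round_index <= 0`) and all rows of players who
#' completed (were active for) fewer than four real rounds.
#'
#' @param dataset A session log data frame (see [run_session()]).
#' @param min_real_rounds Minimum completed real rounds to be retained
#'   (default 4).
#' @return The filtered dataset, with attribute `excluded_players` listing
#'   the removed player ids.
#' @export
apply_exclusions <- function(dataset, min_real_rounds = 4L) {
  if (nrow(dataset) == 0L) {
    attr(dataset, "excluded_players") <- integer(0)
    return(dataset)
  }
  real <- dataset[dataset$round_index >= 1L, , drop = FALSE]
  completed <- tapply(real$active, real$player_id, sum)
  excluded <- as.numeric(names(completed)[completed < min_real_rounds])
  out <- real[!(real$player_id %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_players") <- excluded
  out
}
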