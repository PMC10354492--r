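# Independent oracles used across the suite.

# Exhaustive rule-table oracle for group resolution: a from-first-principles
# per-player case analysis, deliberately written as scalar case work rather
# than the engine's vectorized bookkeeping.
oracle_resolve <- function(actions, flags, config, punishment_levels) {
  n_coop <- sum(actions == "cooperate")
  any_attempt <- any(actions == "steal")
  stealer_idx <- which(actions == "steal")
  success_of <- stats::setNames(flags, stealer_idx)
  any_success <- n_coop > 0 && any_attempt && any(flags)
  delta <- numeric(length(actions))
  outcome <- character(length(actions))
  k <- 0L
  for (i in seq_along(actions)) {
    a <- actions[i]
    if (a == "work_alone") {
      delta[i] <- 0
      outcome[i] <- "n/a"
    } else if (a == "cooperate") {
      outcome[i] <- "n/a"
      if (!any_attempt && n_coop >= 2) {
        delta[i] <- config$cooperate_gain
      } else if (any_success) {
        delta[i] <- config$stolen_loss
      } else {
        delta[i] <- 0
      }
    } else { # steal
      k <- k + 1L
      if (n_coop == 0) {
        delta[i] <- 0
        outcome[i] <- "no_target"
      } else if (flags[k]) {
        delta[i] <- config$steal_gain
        outcome[i] <- "success"
      } else {
        delta[i] <- if (punishment_levels[i] == "harsh") {
          config$steal_penalty_harsh
        } else {
          config$steal_penalty_lenient
        }
        outcome[i] <- "caught"
      }
    }
  }
  list(delta = delta, steal_outcome = outcome)
}

# All 3^4 action profiles.
all_action_profiles <- function() {
  acts <- c("cooperate", "steal", "work_alone")
  expand.grid(a1 = acts, a2 = acts, a3 = acts, a4 = acts,
              stringsAsFactors = FALSE)
}

# A small simulated decision frame with known generative structure, for
# fitter tests: independent Bernoulli outcomes from a logistic model.
make_logit_frame <- function(n = 200, beta = c(-1, 0.8), seed = 42) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  eta <- beta[1] + beta[2] * x
  data.frame(y = as.numeric(stats::runif(n) < stats::plogis(eta)), x = x)
}
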