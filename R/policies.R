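#' Parameters of the synthetic-agent policies
#'
#' Collects the generative coefficients and trust-dynamics parameters used by
#' the synthetic players. The steal decision follows a logistic model on the
#' log-odds scale:
#' `beta0_steal + beta_below * [points < threshold] +
#'  beta_thr_interact * [points < threshold] * [threshold condition] +
#'  beta_punish * [harsh punishment] + beta_round * round + random intercept`.
#' Conditional on not stealing, cooperation (vs working alone) has probability
#' `plogis(gamma0 + gamma_trust * latent_trust)`. Latent trust lives on
#' `[0, 1]` and is updated each round by an exponential moving average of the
#' observed cooperativeness of the player's own group; the 1-10 trust rating
#' is a noisy affine readout of the latent value.
#'
#' @param beta0_steal Log-odds intercept of stealing.
#' @param beta_below Log-odds effect of being below the threshold level
#'   (present in every condition: loss response / propensity).
#' @param beta_thr_interact Additional below-threshold effect when the
#'   desperation threshold is actually in force (the interaction of interest).
#' @param beta_punish Log-odds effect of harsh (vs lenient) punishment.
#' @param beta_round Per-round linear trend in the steal log-odds.
#' @param sigma_id Standard deviation of player random intercepts (>= 0).
#' @param gamma0,gamma_trust Cooperate-vs-work-alone logistic parameters
#'   (on the latent-trust scale).
#' @param lambda_trust Trust learning rate in `[0, 1]`.
#' @param rho_ratings Target correlation magnitude between the trust rating
#'   and the steal-likelihood rating (studies 3-4), in `[-1, 1]`.
#' @param rating_noise_sd Noise sd of the rating readout on the latent scale.
#' @param trust_init Initial latent trust in `[0, 1]`.
#' @return A list of class `"micsoc_policy_params"`.
#' @export
policy_params <- function(beta0_steal = -2.5, beta_below = 0,
                          beta_thr_interact = 0, beta_punish = 0,
                          beta_round = 0, sigma_id = 0,
                          gamma0 = -1.5, gamma_trust = 3,
                          lambda_trust = 0.3, rho_ratings = 0.44,
                          rating_noise_sd = 0.15, trust_init = 0.65) {
  stopifnot(sigma_id >= 0, lambda_trust >= 0, lambda_trust <= 1,
            rho_ratings >= -1, rho_ratings <= 1, rating_noise_sd >= 0,
            trust_init >= 0, trust_init <= 1)
  structure(list(
    beta0_steal = beta0_steal, beta_below = beta_below,
    beta_thr_interact = beta_thr_interact, beta_punish = beta_punish,
    beta_round = beta_round, sigma_id = sigma_id,
    gamma0 = gamma0, gamma_trust = gamma_trust,
    lambda_trust = lambda_trust, rho_ratings = rho_ratings,
    rating_noise_sd = rating_noise_sd, trust_init = trust_init
  ), class = "micsoc_policy_params")
}

#' Named policy presets
#'
#' * `"null_agent"`: no below-threshold, interaction, punishment, round or
#'   trust effects; moderate baseline stealing and player heterogeneity.
#'   Used for type-I / null calibration.
#' * `"paper_like"`: positive below-threshold effect, a larger additional
#'   effect when the threshold is in force, mild punishment sensitivity, and
#'   trust-dependent cooperation — the qualitative structure the human
#'   studies exhibit.
#' * `"cn_threshold"`: a near-deterministic threshold strategy (steal when
#'   desperate, otherwise cooperate iff trust is high enough), the strategy
#'   profile predicted by the desperation-threshold theory.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [policy_params()] (generative presets) or
#'   entries of `cutoffs` (`cn_threshold`).
#' @return A policy object (list with `type`, `params`, and for
#'   `cn_threshold` a `cutoffs` list).
#' @export
policy_preset <- function(name = c("null_agent", "paper_like", "cn_threshold"),
                          ...) {
  name <- match.arg(name)
  switch(name,
    null_agent = make_generative_policy(policy_params(
      beta0_steal = -2.2, sigma_id = 0.5, gamma_trust = 0, gamma0 = 0, ...
    )),
    paper_like = make_generative_policy(policy_params(
      beta0_steal = -2.5, beta_below = 0.3, beta_thr_interact = 0.9,
      beta_punish = -0.3, beta_round = -0.03, sigma_id = 0.8,
      gamma0 = -1.5, gamma_trust = 4, ...
    )),
    cn_threshold = {
      cut <- utils::modifyList(
        list(tau = 0.5, p_steal_below = 0.8, p_steal_above = 0.02),
        list(...)
      )
      structure(list(type = "threshold", params = policy_params(),
                     cutoffs = cut), class = "micsoc_policy")
    }
  )
}

#' Build a generative-logistic policy
#'
#' @param params A [policy_params()] object.
#' @return A policy object usable with [run_session()] / [run_study()].
#' @export
make_generative_policy <- function(params = policy_params()) {
  structure(list(type = "generative", params = params),
            class = "micsoc_policy")
}

#' Build a policy that always plays one fixed action
#'
#' Useful for exercising the engine (e.g. all-work-alone rounds).
#' @param action One of `"cooperate"`, `"steal"`, `"work_alone"`.
#' @return A policy object.
#' @export
forced_policy <- function(action = c("work_alone", "cooperate", "steal")) {
  action <- match.arg(action)
  structure(list(type = "forced", params = policy_params(), action = action),
            class = "micsoc_policy")
}

#' Sample a synthetic player population
#'
#' Draws i.i.d. `Normal(0, sigma_id^2)` random intercepts, mirroring the
#' player-level grouping of the mixed models fitted downstream.
#'
#' @param n_players Total players; must be a multiple of `set_size`.
#' @param params A [policy_params()].
#' @param set_size Players per set (default 8).
#' @return Data frame with `player_id` and `random_intercept`.
#' @export
make_population <- function(n_players, params = policy_params(),
                            set_size = 8L) {
  if (n_players %% set_size != 0) {
    stop(sprintf("n_players (%d) must be a multiple of set_size (%d)",
                 n_players, set_size), call. = FALSE)
  }
  data.frame(
    player_id = seq_len(n_players),
    random_intercept = stats::rnorm(n_players, 0, params$sigma_id)
  )
}

# Internal: vectorized action draw for all players of a set in one round.
policy_actions <- function(policy, state, round_index, config) {
  n <- length(state$player_id)
  below <- state$points < config$threshold_level
  switch(policy$type,
    forced = rep(policy$action, n),
    generative = {
      p <- policy$params
      eta <- p$beta0_steal + p$beta_below * below +
        p$beta_thr_interact * below * state$threshold_active +
        p$beta_punish * (state$punishment_level == "harsh") +
        p$beta_round * round_index + state$random_intercept
      steal <- stats::runif(n) < stats::plogis(eta)
      coop <- stats::runif(n) <
        stats::plogis(p$gamma0 + p$gamma_trust * state$latent_trust)
      ifelse(steal, "steal", ifelse(coop, "cooperate", "work_alone"))
    },
    threshold = {
      cut <- policy$cutoffs
      p_steal <- ifelse(below & state$threshold_active,
                        cut$p_steal_below, cut$p_steal_above)
      steal <- stats::runif(n) < p_steal
      coop <- state$latent_trust >= cut$tau
      ifelse(steal, "steal", ifelse(coop, "cooperate", "work_alone"))
    },
    stop("unknown policy type: ", policy$type, call. = FALSE)
  )
}

#' One player's action under the generative-logistic policy
#'
#' Scalar version of the decision rule used inside [run_session()]:
#' P(steal) follows the logistic model of [policy_params()]; conditional on
#' not stealing, cooperate with probability
#' `plogis(gamma0 + gamma_trust * latent_trust)`, else work alone.
#'
#' @param state List with `points`, `threshold_level`, `threshold_active`,
#'   `punishment_level`, `latent_trust`, `random_intercept`.
#' @param round_index Current round (mock rounds <= 0).
#' @param params A [policy_params()].
#' @return One of `"cooperate"`, `"steal"`, `"work_alone"`.
#' @export
generative_policy_decide <- function(state, round_index, params) {
  below <- state$points < state$threshold_level
  eta <- params$beta0_steal + params$beta_below * below +
    params$beta_thr_interact * below * isTRUE(state$threshold_active) +
    params$beta_punish * identical(state$punishment_level, "harsh") +
    params$beta_round * round_index +
    (state$random_intercept %||% 0)
  if (stats::runif(1) < stats::plogis(eta)) return("steal")
  p_coop <- stats::plogis(params$gamma0 +
                            params$gamma_trust * state$latent_trust)
  if (stats::runif(1) < p_coop) "cooperate" else "work_alone"
}

#' One player's action under the threshold (CN-style) policy
#'
#' Steal with probability `p_steal_below` when desperate (threshold in force
#' and points below it), otherwise with `p_steal_above`; if not stealing,
#' cooperate iff latent trust reaches the cutoff `tau`, else work alone.
#'
#' @param state As in [generative_policy_decide()].
#' @param cutoffs List with `tau`, `p_steal_below`, `p_steal_above`.
#' @return One of `"cooperate"`, `"steal"`, `"work_alone"`.
#' @export
threshold_policy_decide <- function(state, cutoffs) {
  below <- state$points < state$threshold_level
  p_steal <- if (below && isTRUE(state$threshold_active)) {
    cutoffs$p_steal_below
  } else {
    cutoffs$p_steal_above
  }
  if (stats::runif(1) < p_steal) return("steal")
  if (state$latent_trust >= cutoffs$tau) "cooperate" else "work_alone"
}

#' Exponential-moving-average trust update
#'
#' After each round a player sees their own group's outcome page and moves
#' latent trust towards the observed cooperativeness signal
#' `1 - stealers_observed / (group_size - 1)` at rate `lambda`:
#' `trust <- (1 - lambda) * trust + lambda * signal`, clamped to `[0, 1]`.
#' Before any round has been observed, trust is unchanged.
#'
#' @param latent_trust Current trust values in `[0, 1]` (vectorized).
#' @param stealers_observed Steal attempts by the *other* members of the
#'   player's own group last round.
#' @param group_size Interaction-group size (default 4).
#' @param lambda Learning rate in `[0, 1]`.
#' @return Updated trust values in `[0, 1]`.
#' @export
update_trust <- function(latent_trust, stealers_observed, group_size = 4L,
                         lambda = 0.3) {
  signal <- 1 - stealers_observed / (group_size - 1L)
  signal <- pmin(1, pmax(0, signal))
  pmin(1, pmax(0, (1 - lambda) * latent_trust + lambda * signal))
}

#' Emit integer 1-10 ratings from latent trust
#'
#' The trust rating is `round(1 + 9 * clamp(latent_trust + noise))`. In
#' studies 3-4 a second elicitation asks how likely others are to steal; its
#' latent value is `1 - latent_trust` plus noise negatively correlated with
#' the trust noise, calibrated (with an analytic correction for the
#' integer-rounding attenuation) so that at a fixed latent trust the two
#' ratings correlate with magnitude `rho_ratings`.
#'
#' @param latent_trust Latent trust values in `[0, 1]` (vectorized).
#' @param params A [policy_params()].
#' @param with_steal_rating Emit the steal-likelihood rating (studies 3-4)?
#' @return List with integer `trust_rating` and `steal_likelihood_rating`
#'   (the latter `NA` when not elicited).
#' @export
emit_ratings <- function(latent_trust, params = policy_params(),
                         with_steal_rating = FALSE) {
  n <- length(latent_trust)
  sd0 <- params$rating_noise_sd
  clamp01 <- function(x) pmin(1, pmax(0, x))
  if (sd0 == 0) {
    trust_rating <- as.integer(round(1 + 9 * clamp01(latent_trust)))
    steal <- if (with_steal_rating) {
      as.integer(round(1 + 9 * clamp01(1 - latent_trust)))
    } else {
      rep(NA_integer_, n)
    }
    return(list(trust_rating = trust_rating, steal_likelihood_rating = steal))
  }
  e1 <- stats::rnorm(n, 0, sd0)
  trust_rating <- as.integer(round(1 + 9 * clamp01(latent_trust + e1)))
  if (with_steal_rating) {
    # rounding adds variance 1/12 on the 1-10 scale = 1/972 on the latent
    # scale; inflate the latent noise correlation to compensate
    atten <- sd0^2 / (sd0^2 + 1 / 972)
    cc <- min(1, abs(params$rho_ratings) / atten)
    e2 <- -cc * e1 + sqrt(max(0, 1 - cc^2)) * stats::rnorm(n, 0, sd0)
    steal <- as.integer(round(1 + 9 * clamp01(1 - latent_trust + e2)))
  } else {
    steal <- rep(NA_integer_, n)
  }
  list(trust_rating = trust_rating, steal_likelihood_rating = steal)
}
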