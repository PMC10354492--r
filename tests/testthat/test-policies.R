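test_that("population intercepts have the requested spread", {
  set.seed(8)
  pop0 <- make_population(80, policy_params(sigma_id = 0))
  expect_true(all(pop0$random_intercept == 0))

  set.seed(8)
  pop <- make_population(10000, policy_params(sigma_id = 1))
  expect_equal(sd(pop$random_intercept), 1, tolerance = 0.03)

  set.seed(12); a <- make_population(64, policy_params(sigma_id = 0.5))
  set.seed(12); b <- make_population(64, policy_params(sigma_id = 0.5))
  expect_identical(a, b)
  expect_error(make_population(50), "multiple of set_size")
})

test_that("generative policy realizes the programmed below-threshold odds ratio", {
  # beta_below = log(3), everything else flat: the empirical odds ratio of
  # stealing below vs above the threshold has closed form 3
  params <- policy_params(beta0_steal = -1.5, beta_below = log(3))
  mk_state <- function(points) {
    list(points = points, threshold_level = 100, threshold_active = TRUE,
         punishment_level = "n/a", latent_trust = 0.5, random_intercept = 0)
  }
  set.seed(41)
  n <- 5e4
  steals_below <- sum(vapply(seq_len(n), function(i) {
    generative_policy_decide(mk_state(80), 1, params) == "steal"
  }, logical(1)))
  steals_above <- sum(vapply(seq_len(n), function(i) {
    generative_policy_decide(mk_state(120), 1, params) == "steal"
  }, logical(1)))
  or <- (steals_below / (n - steals_below)) / (steals_above / (n - steals_above))
  expect_equal(or, 3, tolerance = 0.05)
})

test_that("steal-disabled policy never steals; cooperation rises with trust", {
  params <- policy_params(beta0_steal = -Inf, gamma0 = 0, gamma_trust = 3)
  set.seed(2)
  acts <- vapply(seq_len(500), function(i) {
    generative_policy_decide(
      list(points = 50, threshold_level = 100, threshold_active = TRUE,
           punishment_level = "n/a", latent_trust = runif(1),
           random_intercept = 0), 1, params)
  }, character(1))
  expect_false(any(acts == "steal"))

  # cooperation rate strictly increases across trust bins
  set.seed(3)
  rates <- vapply(c(0.1, 0.5, 0.9), function(tr) {
    mean(vapply(seq_len(4000), function(i) {
      generative_policy_decide(
        list(points = 150, threshold_level = 100, threshold_active = TRUE,
             punishment_level = "n/a", latent_trust = tr,
             random_intercept = 0), 1, params) == "cooperate"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("threshold policy steals when desperate and follows the trust cutoff otherwise", {
  cut <- list(tau = 0.5, p_steal_below = 1, p_steal_above = 0)
  below_state <- list(points = 150, threshold_level = 200,
                      threshold_active = TRUE, latent_trust = 1)
  expect_equal(threshold_policy_decide(below_state, cut), "steal")
  above_state <- list(points = 250, threshold_level = 200,
                      threshold_active = TRUE, latent_trust = 1)
  expect_equal(threshold_policy_decide(above_state, cut), "cooperate")
  above_state$latent_trust <- 0.2
  expect_equal(threshold_policy_decide(above_state, cut), "work_alone")
  # without a threshold in force, desperation does not trigger stealing
  below_state$threshold_active <- FALSE
  expect_equal(threshold_policy_decide(below_state, cut), "cooperate")
})

test_that("threshold-policy populations show the desperation-driven stealing asymmetry", {
  pol <- policy_preset("cn_threshold", p_steal_below = 0.6,
                       p_steal_above = 0.05)
  sim <- run_study(2, n_sets = 10, pol, master_seed = 99)
  d <- prepare_decision_frame(apply_exclusions(sim), 100)
  tab <- tabulate_steal_by_threshold(d, by = "thr")
  or_thr <- tab$or[tab$stratum == "1"][1]
  or_nothr <- tab$or[tab$stratum == "0"][1]
  expect_gt(or_thr, 1)
  # in the no-threshold condition stealing is p_steal_above-driven: no
  # below/above asymmetry beyond sampling noise
  expect_lt(abs(log(or_nothr)), log(or_thr))
})

test_that("trust updates are a clamped EMA with the right fixed points", {
  expect_equal(update_trust(0.4, 3, lambda = 0), 0.4)
  # observing all three others steal drives trust to 0 geometrically
  tr <- 0.9
  for (i in 1:8) tr <- update_trust(tr, 3, lambda = 0.5)
  expect_equal(tr, 0.9 * 0.5^8)
  # all-cooperate rounds drive trust to 1
  tr <- 0.1
  for (i in 1:60) tr <- update_trust(tr, 0, lambda = 0.3)
  expect_equal(tr, 1, tolerance = 1e-8)
  expect_true(all(update_trust(c(0, 1), c(3, 0)) >= 0))
  expect_true(all(update_trust(c(0, 1), c(3, 0)) <= 1))
})

test_that("ratings are integers in 1..10 and hit the calibrated correlation", {
  expect_equal(emit_ratings(1, policy_params(rating_noise_sd = 0))$trust_rating,
               10L)
  expect_equal(emit_ratings(0, policy_params(rating_noise_sd = 0))$trust_rating,
               1L)

  set.seed(10)
  r <- emit_ratings(runif(5000), policy_params(), with_steal_rating = TRUE)
  expect_true(all(r$trust_rating %in% 1:10))
  expect_true(all(r$steal_likelihood_rating %in% 1:10))

  # at a fixed latent trust, the two ratings' correlation magnitude matches
  # the calibration target 0.44
  set.seed(20)
  r <- emit_ratings(rep(0.5, 1e4), policy_params(rho_ratings = 0.44),
                    with_steal_rating = TRUE)
  expect_equal(abs(cor(r$trust_rating, r$steal_likelihood_rating)), 0.44,
               tolerance = 0.05 / 0.44)

  # studies 1-2 do not elicit the steal-likelihood rating
  log1 <- run_study(1, 2, policy_preset("paper_like"), master_seed = 3)
  expect_true(all(is.na(log1$steal_likelihood_rating)))
  log3 <- run_study(3, 2, policy_preset("paper_like"), master_seed = 3)
  expect_false(any(is.na(log3$steal_likelihood_rating)))
})

test_that("scalar policy rules agree with the engine's vectorized path", {
  # drive every decision to probability 0 or 1 so the two code paths must
  # produce identical actions; each configuration isolates one indicator
  cfg <- study_config(1)$config
  state <- new.env()
  state$player_id <- 1:8
  state$points <- c(50, 150, 99, 100, 200, 10, 120, 80)
  state$threshold_active <- rep(c(TRUE, FALSE), 4)
  state$punishment_level <- rep(c("harsh", "lenient"), each = 4)
  state$latent_trust <- seq(0.05, 0.75, by = 0.1)
  state$random_intercept <- rep(0, 8)

  configs <- list(
    below = policy_params(beta0_steal = -100, beta_below = 200,
                          gamma0 = -1000, gamma_trust = 3000),
    interact = policy_params(beta0_steal = -100, beta_thr_interact = 200,
                             gamma0 = -1000, gamma_trust = 3000),
    punish = policy_params(beta0_steal = -100, beta_punish = 200,
                           gamma0 = -1000, gamma_trust = 3000)
  )
  for (nm in names(configs)) {
    params <- configs[[nm]]
    vec <- micsoc:::policy_actions(make_generative_policy(params), state,
                                   3, cfg)
    scalar <- vapply(1:8, function(i) {
      generative_policy_decide(
        list(points = state$points[i], threshold_level = cfg$threshold_level,
             threshold_active = state$threshold_active[i],
             punishment_level = state$punishment_level[i],
             latent_trust = state$latent_trust[i],
             random_intercept = state$random_intercept[i]),
        3, params)
    }, character(1))
    expect_identical(vec, scalar)
  }
})
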