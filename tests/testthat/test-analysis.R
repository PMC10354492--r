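test_that("contingency tables give the cross-product odds ratio", {
  d <- data.frame(
    below = rep(c(1, 0), times = c(100, 100)),
    steal = c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  )
  tab <- tabulate_steal_by_threshold(d)
  expect_equal(unique(tab$or), (30 * 90) / (70 * 10))
  expect_equal(tab$rate[tab$status == "below"], 0.3)
  expect_equal(tab$se[tab$status == "above"], sqrt(0.1 * 0.9 / 100))

  # identical rates above and below: OR exactly 1
  d2 <- data.frame(below = rep(c(1, 0), each = 50),
                   steal = rep(c(1, 0, 1, 0), times = c(10, 40, 10, 40)))
  expect_equal(unique(tabulate_steal_by_threshold(d2)$or), 1)

  # an all-steal stratum is flagged as degenerate
  d3 <- data.frame(below = rep(c(1, 0), each = 10),
                   steal = c(rep(1, 10), rep(c(0, 1), 5)))
  tab3 <- tabulate_steal_by_threshold(d3)
  expect_true(all(tab3$degenerate))
  expect_true(all(is.na(tab3$or)))
})

test_that("set-level aggregation counts attempts and lags by one round", {
  sim <- run_study(2, n_sets = 3, policy_preset("paper_like"),
                   master_seed = 61)
  sl <- build_set_level(sim, 100)
  expect_true(all(is.na(sl$lag_n_stealers[sl$round_index == 1])))
  expect_true(all(is.na(sl$lag_n_below[sl$round_index == 1])))

  real <- sim[sim$round_index >= 1, ]
  r2 <- real[real$set_id == 1 & real$round_index == 2, ]
  expect_equal(sl$mean_trust[sl$set_id == 1 & sl$round_index == 2],
               mean(r2$trust_rating))
  # attempts, not successes
  expect_equal(sl$n_stealers[sl$set_id == 1 & sl$round_index == 2],
               sum(r2$action == "steal"))
  # lag columns equal the previous round's contemporaneous counts
  r1 <- real[real$set_id == 1 & real$round_index == 1, ]
  expect_equal(sl$lag_n_stealers[sl$set_id == 1 & sl$round_index == 2],
               sum(r1$action == "steal"))
  expect_equal(sl$lag_n_below[sl$set_id == 1 & sl$round_index == 2],
               sum(r1$points_after < 100))
})

test_that("mediation recovers a known linear path structure", {
  # synthetic set-level frame: below -> stealers (a = 0.5), stealers ->
  # trust (b = -0.3), direct -0.2; true proportion 0.15/0.35 = 0.43.
  # noise variances chosen so every variable has unit variance and the
  # generative coefficients are already standardized ones
  set.seed(71)
  n_sets <- 40; n_rounds <- 11
  frames <- lapply(seq_len(n_sets), function(s) {
    lb <- rnorm(n_rounds)
    ls <- 0.5 * lb + rnorm(n_rounds, 0, sqrt(1 - 0.25))
    tr <- -0.3 * ls - 0.2 * lb + rnorm(n_rounds, 0, sqrt(0.45))
    data.frame(set_id = s, round_index = seq_len(n_rounds) + 1,
               mean_trust = tr, n_stealers = NA, n_below = NA,
               lag_n_stealers = ls, lag_n_below = lb)
  })
  med <- mediation_analysis(do.call(rbind, frames), n_bootstrap = 60)
  expect_equal(med$a, 0.5, tolerance = 0.15)
  expect_equal(med$b, -0.3, tolerance = 0.25)
  expect_equal(med$indirect, med$a * med$b)
  true_prop <- (0.5 * -0.3) / (0.5 * -0.3 - 0.2)
  expect_gt(true_prop, med$ci["proportion_paths", 1])
  expect_lt(true_prop, med$ci["proportion_paths", 2])
  expect_true(med$proportion_valid)

  expect_error(mediation_analysis(frames[[1]]), "at least 2 sets")
})

test_that("a null mediator path yields a near-zero indirect effect", {
  set.seed(72)
  n_sets <- 30; n_rounds <- 10
  frames <- lapply(seq_len(n_sets), function(s) {
    lb <- rnorm(n_rounds)
    ls <- 0.5 * lb + rnorm(n_rounds, 0, 1)   # a path present
    tr <- -0.3 * lb + rnorm(n_rounds, 0, 1)  # but b = 0
    data.frame(set_id = s, round_index = seq_len(n_rounds) + 1,
               mean_trust = tr, n_stealers = NA, n_below = NA,
               lag_n_stealers = ls, lag_n_below = lb)
  })
  med <- mediation_analysis(do.call(rbind, frames), n_bootstrap = 0)
  expect_lt(abs(med$indirect), 0.08)
})

test_that("first-round subsetting keeps rounds 1..k and never mock rounds", {
  sim <- run_study(4, n_sets = 2, policy_preset("paper_like"),
                   master_seed = 81)
  dat <- apply_exclusions(sim)
  f4 <- first_k_rounds(dat, 4)
  expect_equal(sort(unique(f4$round_index)), 1:4)
  expect_equal(first_k_rounds(dat, 99), dat, ignore_attr = TRUE)
  expect_error(first_k_rounds(dat, 0), "k must be >= 1")
  expect_false(any(first_k_rounds(sim, 4)$round_index <= 0))
})

test_that("simple effects separate a programmed interaction", {
  pol <- make_generative_policy(policy_params(
    beta0_steal = -2, beta_below = 0.2, beta_thr_interact = 1.1,
    sigma_id = 0.5
  ))
  sim <- run_study(2, n_sets = 30, pol, master_seed = 91)
  d <- prepare_decision_frame(apply_exclusions(sim), 100)
  d$round_z <- as.numeric(scale(d$round_index))
  se <- simple_effects(d, "steal", "below", "thr")
  or_thr <- se$strata[["thr=1"]]$or[se$strata[["thr=1"]]$term == "below"]
  or_nothr <- se$strata[["thr=0"]]$or[se$strata[["thr=0"]]$term == "below"]
  expect_gt(or_thr, or_nothr)
  expect_true("below:thr" %in% se$interaction$term)
  # interaction estimate in the right direction
  expect_gt(se$interaction$estimate[se$interaction$term == "below:thr"], 0)
})

test_that("prediction suites produce the registered rows per study", {
  sim1 <- replicate_study(1, n_sets = 8, master_seed = 101, n_bootstrap = 0)
  expect_setequal(sim1$suite$prediction, c("P1.1", "P1.2", "P1.3"))
  expect_true(all(sim1$suite$bf > 0))
  expect_true(all(sim1$suite$ci_lo < sim1$suite$ci_hi))

  sim2 <- replicate_study(2, n_sets = 8, master_seed = 102)
  expect_true(all(c("P2.1", "P2.1.simple_threshold",
                    "P2.1.simple_nothreshold", "P2.2", "P2.3")
                  %in% sim2$suite$prediction))

  sim3 <- replicate_study(3, n_sets = 8, master_seed = 103)
  expect_true(all(c("P3.1", "P3.7") %in% sim3$suite$prediction))

  sim4 <- replicate_study(4, n_sets = 8, master_seed = 104)
  expect_true(all(paste0("P4.", 1:6) %in% sim4$suite$prediction))
  # study 4 reports all rounds and the first four rounds
  expect_setequal(unique(sim4$suite$rounds[sim4$suite$prediction == "P4.1"]),
                  c("all", "first4"))
  expect_error(run_prediction_suite(1, sim4$dataset), "does not look like")
})
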