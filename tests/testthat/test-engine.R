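cfg1 <- study_config(1)$config
cfg3 <- study_config(3)$config

test_that("group formation gives disjoint exhaustive groups of four", {
  set.seed(11)
  g <- form_groups(1:8)
  expect_length(g$A, 4)
  expect_length(g$B, 4)
  expect_setequal(c(g$A, g$B), 1:8)
  expect_length(intersect(g$A, g$B), 0)
  expect_error(form_groups(1:7), "exactly 8")

  # same rng state twice gives the identical partition
  set.seed(99); g1 <- form_groups(1:8)
  set.seed(99); g2 <- form_groups(1:8)
  expect_identical(g1, g2)
})

test_that("partitions are uniform: two given players share a group 3/7 of the time", {
  # of the 7 slots around player 1, 3 are in player 1's group
  set.seed(202)
  same <- logical(1e5)
  for (i in seq_len(1e5)) {
    g <- form_groups(1:8)
    same[i] <- (1 %in% g$A) == (2 %in% g$A)
  }
  expect_equal(mean(same), 3 / 7, tolerance = 0.01 / (3 / 7))
})

test_that("steal outcome draws are fair and reproducible", {
  expect_length(draw_steal_outcomes(0), 0)
  set.seed(5)
  flags <- draw_steal_outcomes(1e5)
  expect_equal(mean(flags), 0.5, tolerance = 0.005 / 0.5)
  set.seed(77); a <- draw_steal_outcomes(50)
  set.seed(77); b <- draw_steal_outcomes(50)
  expect_identical(a, b)
})

test_that("group resolution follows the payoff rules", {
  # two cooperators, no stealers: both gain
  r <- resolve_group(c("cooperate", "cooperate", "work_alone", "work_alone"),
                     logical(0), cfg1)
  expect_equal(r$delta, c(5, 5, 0, 0))
  expect_equal(r$steal_outcome, rep("n/a", 4))

  # everyone works alone: nothing happens
  r <- resolve_group(rep("work_alone", 4), logical(0), cfg1)
  expect_equal(r$delta, rep(0, 4))

  # successful steal: stealer +20, each cooperator loses 5 once
  r <- resolve_group(c("steal", "cooperate", "cooperate", "work_alone"),
                     TRUE, cfg1)
  expect_equal(r$delta, c(20, -5, -5, 0))
  expect_equal(r$steal_outcome[1], "success")

  # caught steal: stealer -40; cooperators unpaid (an attempt occurred)
  # but unharmed (the loss requires a successful theft)
  r <- resolve_group(c("steal", "cooperate", "cooperate", "work_alone"),
                     FALSE, cfg1)
  expect_equal(r$delta, c(-40, 0, 0, 0))
  expect_equal(r$steal_outcome[1], "caught")

  # a lone cooperator gains nothing even without stealers
  r <- resolve_group(c("cooperate", "work_alone", "work_alone", "work_alone"),
                     logical(0), cfg1)
  expect_equal(r$delta, rep(0, 4))

  # stealing with no cooperator present fizzles with no punishment risk
  r <- resolve_group(c("steal", "work_alone", "work_alone", "work_alone"),
                     TRUE, cfg1)
  expect_equal(r$delta, rep(0, 4))
  expect_equal(r$steal_outcome[1], "no_target")

  # per-player punishment levels (within-set design): harsh stealer pays -30
  r <- resolve_group(c("steal", "steal", "cooperate", "cooperate"),
                     c(FALSE, FALSE), cfg3,
                     punishment_levels = c("harsh", "lenient", "n/a", "n/a"))
  expect_equal(r$delta, c(-30, -15, 0, 0))

  expect_error(resolve_group(rep("cooperate", 3), logical(0), cfg1),
               "expected 4 actions")
  expect_error(resolve_group(c("steal", rep("cooperate", 3)), logical(0),
                             cfg1), "steal success flags")
})

test_that("engine matches the exhaustive rule-table oracle on all profiles and configs", {
  profiles <- all_action_profiles()
  for (study in 1:4) {
    cfg <- study_config(study)$config
    pun <- c("harsh", "lenient", "lenient", "harsh")
    for (i in seq_len(nrow(profiles))) {
      actions <- unlist(profiles[i, ], use.names = FALSE)
      n_steal <- sum(actions == "steal")
      flag_grid <- if (n_steal == 0) {
        list(logical(0))
      } else {
        asplit(as.matrix(expand.grid(
          rep(list(c(FALSE, TRUE)), n_steal))), 1)
      }
      for (flags in flag_grid) {
        flags <- as.logical(flags)
        got <- resolve_group(actions, flags, cfg, punishment_levels = pun)
        want <- oracle_resolve(actions, flags, cfg, punishment_levels = pun)
        expect_identical(got$delta, want$delta)
        expect_identical(got$steal_outcome, want$steal_outcome)
      }
    }
  }
})

test_that("perturbation is a discretized mean-zero Gaussian, absent in studies 3-4", {
  expect_equal(apply_perturbation(100, cfg3)$perturbation, 0L)
  set.seed(303)
  shocks <- apply_perturbation(rep(0L, 1e5), cfg1)$perturbation
  expect_true(all(shocks == round(shocks)))
  expect_lt(abs(mean(shocks)), 0.03)
  # rounding inflates the continuous sd 3 by about 1/216 relative
  expect_gt(sd(shocks), 2.9)
  expect_lt(sd(shocks), 3.1)
})

test_that("payout conversion applies the below-round penalty with a floor at zero", {
  expect_equal(settle_payout(120, 2, TRUE, cfg1), 1.40)
  expect_equal(settle_payout(100, 4, TRUE, cfg1), 0)
  expect_equal(settle_payout(0, 0, TRUE, cfg1), 0)
  # no-threshold condition ignores the below count entirely
  expect_equal(settle_payout(80, 5, FALSE, cfg1), 1.60)
  expect_error(settle_payout(100, -1, TRUE, cfg1), ">= 0")
})

test_that("payout is monotone in points, anti-monotone in below rounds, never negative", {
  pts <- seq(-50, 300, by = 25)
  for (b in 0:6) {
    pay <- settle_payout(pts, rep(b, length(pts)), TRUE, cfg1)
    expect_true(all(diff(pay) >= 0))
    expect_true(all(pay >= 0))
  }
  for (p in pts) {
    pay <- settle_payout(rep(p, 7), 0:6, TRUE, cfg1)
    expect_true(all(diff(pay) <= 0))
    # and with the threshold off, independent of the count
    expect_equal(length(unique(settle_payout(rep(p, 7), 0:6, FALSE, cfg1))),
                 1L)
  }
})

test_that("sessions are reproducible and structurally sound", {
  players <- assign_conditions(1, 1)
  pol <- policy_preset("paper_like")
  log1 <- run_session(cfg1, players, pol, seed = 314)
  log2 <- run_session(cfg1, players, pol, seed = 314)
  expect_identical(log1, log2)

  # each player appears exactly once per round, in a 4/4 split
  for (r in unique(log1$round_index)) {
    rows <- log1[log1$round_index == r, ]
    expect_setequal(rows$player_id, players$player_id)
    expect_equal(unname(table(rows$group_id)), c(4L, 4L), ignore_attr = TRUE)
  }

  # points accounting holds row-wise
  expect_equal(log1$points_after,
               log1$points_before + log1$delta_points + log1$perturbation)
  # every real round's deltas replay through resolve_group
  for (r in 1:3) {
    rows <- log1[log1$round_index == r, ]
    for (g in c("A", "B")) {
      grp <- rows[rows$group_id == g, ]
      stealers <- grp$action == "steal"
      flags <- grp$steal_outcome[stealers] == "success"
      redo <- resolve_group(grp$action, flags, cfg1,
                            punishment_levels = grp$punishment_level)
      expect_equal(redo$delta, grp$delta_points)
    }
  }
})

test_that("forced work-alone sessions only move points by the perturbation", {
  players <- assign_conditions(1, 1)
  log <- run_session(cfg1, players, forced_policy("work_alone"), seed = 9)
  expect_true(all(log$delta_points == 0))
  expect_true(all(log$action == "work_alone"))
  real <- log[log$round_index >= 1, ]
  expect_true(any(real$perturbation != 0))
  mock <- log[log$round_index <= 0, ]
  expect_true(all(mock$perturbation == 0))
})

test_that("round structure follows the study rules and mock points reset", {
  cfg4 <- study_config(4)$config
  players <- assign_conditions(4, 2)  # unequal, threshold
  log <- run_session(cfg4, players, forced_policy("work_alone"), seed = 21)
  expect_equal(attr(log, "n_real_rounds"), 12L)
  expect_equal(sort(unique(log$round_index)), c(-3:0, 1:12))

  # real-round allocation is an independent draw: with no perturbation and
  # all-work-alone, payout depends only on the post-reset allocation
  r1 <- log[log$round_index == 1, ]
  expect_equal(sort(r1$points_before), rep(c(180, 190, 220, 230), each = 2))

  set.seed(606)
  draws <- replicate(1e5, draw_n_real_rounds(cfg1))
  freqs <- tabulate(draws, 16)[8:16] / 1e5
  expect_true(all(abs(freqs - 1 / 9) < 0.01))
  expect_true(all(draw_n_real_rounds(study_config(4)$config) == 12L))
})

test_that("below-round counting uses end-of-round points, strictly below", {
  # forced work-alone, study 1: points stay at 100 except for perturbation;
  # a round ending exactly at the threshold is not 'below'
  players <- assign_conditions(1, 1)
  log <- run_session(cfg1, players, forced_policy("work_alone"), seed = 4)
  pay <- attr(log, "payouts")
  real <- log[log$round_index >= 1, ]
  for (pid in players$player_id) {
    rows <- real[real$player_id == pid, ]
    expect_equal(pay$below_round_count[pay$player_id == pid],
                 sum(rows$points_after < 100))
  }
})
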