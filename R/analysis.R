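#' Prepare a session log for decision-level modelling
#'
#' Adds the derived analysis columns used throughout: `below` (points at the
#' moment of decision, i.e. `points_before`, strictly below the threshold),
#' `steal` / `coop` indicators (attempts, not successes), `thr`, `harsh` and
#' `unequal` 0/1 condition indicators, and z-scored `round_z` and `trust_z`.
#'
#' @param dataset A (real-rounds) session log, e.g. from
#'   [apply_exclusions()].
#' @param threshold_level Threshold in points (from the study's
#'   [game_config()]).
#' @return The augmented data frame.
#' @export
prepare_decision_frame <- function(dataset, threshold_level) {
  dataset$below <- as.numeric(dataset$points_before < threshold_level)
  dataset$steal <- as.numeric(dataset$action == "steal")
  dataset$coop <- as.numeric(dataset$action == "cooperate")
  dataset$thr <- as.numeric(dataset$threshold_active)
  dataset$harsh <- as.numeric(dataset$punishment_level == "harsh")
  dataset$unequal <- as.numeric(dataset$inequality_condition == "unequal")
  dataset$round_z <- as.numeric(scale(dataset$round_index))
  dataset$trust_z <- as.numeric(scale(dataset$trust_rating))
  dataset
}

#' Cross-tabulate steal attempts by below-threshold status
#'
#' Builds the 2 x 2 table of steal attempts against whether the player's
#' points level at decision time was below the threshold, optionally within
#' strata, and reports stealing rates, their standard errors, and the
#' cross-product odds ratio. Strata with an empty margin get `or = NA` and
#' `degenerate = TRUE`.
#'
#' @param dataset Output of [prepare_decision_frame()].
#' @param by Optional character vector of stratifying columns.
#' @return Data frame with one row per (stratum x) below-status, columns
#'   `n_steal`, `n_not`, `rate`, `se`, plus per-stratum `or` and
#'   `degenerate`.
#' @export
tabulate_steal_by_threshold <- function(dataset, by = NULL) {
  strata <- if (is.null(by)) {
    list(`all` = dataset)
  } else {
    split(dataset, dataset[by], drop = TRUE, sep = "/")
  }
  rows <- list()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    tab <- sapply(c(below = 1, above = 0), function(v) {
      c(n_steal = sum(d$steal == 1 & d$below == v),
        n_not = sum(d$steal == 0 & d$below == v))
    })
    or <- (tab["n_steal", "below"] * tab["n_not", "above"]) /
      (tab["n_not", "below"] * tab["n_steal", "above"])
    degenerate <- !is.finite(or)
    for (side in c("below", "above")) {
      ns <- tab["n_steal", side]; nn <- tab["n_not", side]
      ntot <- ns + nn
      rate <- if (ntot > 0) ns / ntot else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = nm, status = side, n_steal = ns, n_not = nn,
        rate = rate,
        se = if (ntot > 0) sqrt(rate * (1 - rate) / ntot) else NA_real_,
        or = if (degenerate) NA_real_ else or,
        degenerate = degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decompose a two-way interaction into simple effects
#'
#' Refits the model within each stratum of factor B, giving factor A's
#' effect per stratum, alongside the interaction fit on the full frame —
#' the decomposition pattern used for the threshold-by-points-level and
#' punishment-by-threshold analyses.
#'
#' @param dataset Model frame (see [prepare_decision_frame()]).
#' @param outcome Name of the 0/1 outcome column.
#' @param factor_a,factor_b Names of 0/1 indicator columns.
#' @param covariates Extra fixed-term column names (default `"round_z"`).
#' @param groups Random-intercept factors.
#' @param family Model family.
#' @return List with `interaction` (full-frame [fit_bayes_glmm()] including
#'   the `factor_a:factor_b` term) and `strata` (named list of per-stratum
#'   fits of factor A's effect).
#' @export
simple_effects <- function(dataset, outcome, factor_a, factor_b,
                           covariates = "round_z",
                           groups = c("player_id", "set_id"),
                           family = "binomial") {
  rhs_full <- paste(c(sprintf("%s * %s", factor_a, factor_b), covariates),
                    collapse = " + ")
  full <- fit_bayes_glmm(
    stats::as.formula(paste(outcome, "~", rhs_full)),
    dataset, groups = groups, family = family
  )
  strata <- list()
  for (v in c(0, 1)) {
    d <- dataset[dataset[[factor_b]] == v, , drop = FALSE]
    if (nrow(d) == 0L) {
      stop("empty stratum: ", factor_b, " = ", v, call. = FALSE)
    }
    if (length(unique(d[[outcome]])) < 2L) {
      stop("no outcome variation in stratum ", factor_b, " = ", v,
           call. = FALSE)
    }
    rhs <- paste(c(factor_a, covariates), collapse = " + ")
    strata[[paste0(factor_b, "=", v)]] <- fit_bayes_glmm(
      stats::as.formula(paste(outcome, "~", rhs)),
      d, groups = groups, family = family
    )
  }
  list(interaction = full, strata = strata)
}

#' Aggregate a session log to the set-round level
#'
#' For each set and real round: the mean of the eight trust ratings, the
#' number of steal attempts, and the number of players with end-of-round
#' points below the threshold; plus one-round-lagged copies of the two
#' predictor counts (missing for each set's first real round), for models
#' that relate this round's trust to last round's desperation and stealing.
#'
#' @param dataset Real-rounds session log.
#' @param threshold_level Threshold in points.
#' @return Data frame: `set_id`, `round_index`, `mean_trust`, `n_stealers`,
#'   `n_below`, `lag_n_stealers`, `lag_n_below`.
#' @export
build_set_level <- function(dataset, threshold_level) {
  d <- dataset[dataset$round_index >= 1L, , drop = FALSE]
  key <- interaction(d$set_id, d$round_index, drop = TRUE)
  agg <- data.frame(
    set_id = tapply(d$set_id, key, `[`, 1),
    round_index = tapply(d$round_index, key, `[`, 1),
    mean_trust = as.numeric(tapply(d$trust_rating, key, mean)),
    n_stealers = as.numeric(tapply(d$action == "steal", key, sum)),
    n_below = as.numeric(tapply(d$points_after < threshold_level, key, sum))
  )
  agg <- agg[order(agg$set_id, agg$round_index), , drop = FALSE]
  lag1 <- function(x) c(NA, x[-length(x)])
  agg$lag_n_stealers <- ave(agg$n_stealers, agg$set_id, FUN = lag1)
  agg$lag_n_below <- ave(agg$n_below, agg$set_id, FUN = lag1)
  rownames(agg) <- NULL
  agg
}

#' Lagged set-level mediation of desperation on trust through stealing
#'
#' Fits standardized Gaussian set-level models with set random intercepts
#' and a round control on the lag-complete rows of a [build_set_level()]
#' frame:
#' * path a: stealers last round ~ players below threshold last round;
#' * path b + direct: this round's mean trust ~ stealers last round +
#'   players below last round;
#' * total: this round's mean trust ~ players below last round.
#'
#' The indirect effect is `a * b`. The proportion mediated is reported two
#' ways: `indirect / total` and `indirect / (indirect + direct)`; the two
#' differ whenever the single-predictor total does not equal the sum of the
#' decomposed paths. Uncertainty comes from a set-resampling bootstrap.
#'
#' @param set_frame Output of [build_set_level()].
#' @param n_bootstrap Bootstrap draws resampling whole sets (default 1000).
#' @return A list of class `"micsoc_mediation"`: `a`, `b`, `direct`,
#'   `total`, `indirect`, `proportion_total`, `proportion_paths`,
#'   `ci` (matrix of percentile intervals), `n_sets`, `n_rows`, and the
#'   three component fits.
#' @export
mediation_analysis <- function(set_frame, n_bootstrap = 1000L) {
  d <- set_frame[stats::complete.cases(
    set_frame[c("mean_trust", "lag_n_stealers", "lag_n_below")]
  ), , drop = FALSE]
  n_sets <- length(unique(d$set_id))
  if (n_sets < 2L) stop("mediation needs at least 2 sets", call. = FALSE)
  if (length(unique(d$round_index)) < 2L) {
    stop("mediation needs at least 2 usable lagged rounds", call. = FALSE)
  }

  fit_paths <- function(dd) {
    dd <- standardize(dd, c("mean_trust", "lag_n_stealers", "lag_n_below",
                            "round_index"))
    fa <- fit_bayes_glmm(lag_n_stealers ~ lag_n_below + round_index, dd,
                         groups = "set_id", family = "gaussian")
    fb <- fit_bayes_glmm(mean_trust ~ lag_n_stealers + lag_n_below +
                           round_index, dd,
                         groups = "set_id", family = "gaussian")
    ft <- fit_bayes_glmm(mean_trust ~ lag_n_below + round_index, dd,
                         groups = "set_id", family = "gaussian")
    a <- fa$estimate[fa$term == "lag_n_below"]
    b <- fb$estimate[fb$term == "lag_n_stealers"]
    direct <- fb$estimate[fb$term == "lag_n_below"]
    total <- ft$estimate[ft$term == "lag_n_below"]
    c(a = a, b = b, direct = direct, total = total, indirect = a * b,
      proportion_total = a * b / total,
      proportion_paths = a * b / (a * b + direct))
  }

  est <- fit_paths(d)
  boot <- NULL
  if (n_bootstrap > 0) {
    sets <- unique(d$set_id)
    boot <- matrix(NA_real_, n_bootstrap, length(est),
                   dimnames = list(NULL, names(est)))
    for (i in seq_len(n_bootstrap)) {
      pick <- sample(sets, length(sets), replace = TRUE)
      dd <- do.call(rbind, lapply(seq_along(pick), function(k) {
        rows <- d[d$set_id == pick[k], , drop = FALSE]
        rows$set_id <- k  # resampled copies count as distinct sets
        rows
      }))
      boot[i, ] <- tryCatch(fit_paths(dd), error = function(e) rep(NA, 7))
    }
  }
  ci <- if (!is.null(boot)) {
    t(apply(boot, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
  } else {
    NULL
  }
  # proportions are meaningful only when paths share sign with the total
  shared_sign <- sign(est["indirect"]) == sign(est["total"])
  structure(list(
    a = unname(est["a"]), b = unname(est["b"]),
    direct = unname(est["direct"]), total = unname(est["total"]),
    indirect = unname(est["indirect"]),
    proportion_total = unname(est["proportion_total"]),
    proportion_paths = unname(est["proportion_paths"]),
    proportion_valid = unname(shared_sign),
    ci = ci, n_sets = n_sets, n_rows = nrow(d)
  ), class = "micsoc_mediation")
}

#' @export
print.micsoc_mediation <- function(x, ...) {
  cat("<micsoc_mediation> lagged set-level mediation\n")
  cat(sprintf("  a (below -> stealers)        = %.3f\n", x$a))
  cat(sprintf("  b (stealers -> next trust)   = %.3f\n", x$b))
  cat(sprintf("  indirect (a*b)               = %.3f\n", x$indirect))
  cat(sprintf("  direct                       = %.3f\n", x$direct))
  cat(sprintf("  total                        = %.3f\n", x$total))
  cat(sprintf("  proportion mediated          = %.1f%% (of total) / %.1f%% (of paths)%s\n",
              100 * x$proportion_total, 100 * x$proportion_paths,
              if (x$proportion_valid) "" else "  [sign-discordant: flagged]"))
  if (!is.null(x$ci)) {
    cat(sprintf("  indirect 95%% bootstrap CI    = [%.3f, %.3f] (%d sets)\n",
                x$ci["indirect", 1], x$ci["indirect", 2], x$n_sets))
  }
  invisible(x)
}

#' Restrict a dataset to the first k real rounds
#'
#' Used for the early-rounds reanalysis of the inequality study, where the
#' starting-allocation difference between conditions is still consequential.
#'
#' @param dataset Session log (real rounds indexed from 1).
#' @param k Number of rounds to keep (default 4).
#' @return Rows with `1 <= round_index <= k`.
#' @export
first_k_rounds <- function(dataset, k = 4L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  dataset[dataset$round_index >= 1L & dataset$round_index <= k, ,
          drop = FALSE]
}
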