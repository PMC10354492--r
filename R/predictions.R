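# Registered pre-specified prediction recipes for each study design, and the
# driver that executes them on a simulated (or imported) dataset.

# Internal: one suite row from a fitted model, extracting a single term.
suite_row <- function(prediction, fit, term, rounds = "all") {
  r <- fit[fit$term == term, , drop = FALSE]
  if (nrow(r) != 1L) {
    stop("term '", term, "' not found in fit for ", prediction,
         call. = FALSE)
  }
  data.frame(
    prediction = prediction, rounds = rounds, term = term,
    estimate = r$estimate, sd = r$sd, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
    or = r$or, bf = r$bf, bf_display = r$bf_display, category = r$category,
    n_obs = attr(fit, "n_obs"), stringsAsFactors = FALSE
  )
}

# Internal: z-score the continuous covariates over the analysis subset.
rescore <- function(d) {
  d$round_z <- as.numeric(scale(d$round_index))
  if (stats::sd(d$trust_rating) > 0) {
    d$trust_z <- as.numeric(scale(d$trust_rating))
  }
  d
}

#' Run the registered prediction suite for one study
#'
#' Executes the pre-specified decision-level and set-level models for the
#' given study on a (real-rounds, post-exclusion) dataset and returns one
#' row per prediction: standardized estimate, odds ratio where applicable,
#' 95% credible interval, Savage-Dickey Bayes factor and evidence category.
#'
#' * Study 1: P1.1 below-threshold effect on stealing; P1.2 set-level
#'   lagged effect of desperation on trust (with mediation through stealing
#'   attached as attribute `mediation`); P1.3 trust effect on cooperating
#'   vs working alone among non-stealers.
#' * Study 2: P2.1 threshold-condition x below-level interaction (with
#'   simple effects per condition); P2.2 set-level lagged stealers effect
#'   on trust; P2.3 as P1.3.
#' * Study 3: P3.1 punishment x threshold interaction among below-level
#'   players; P3.7 replication of the threshold x below interaction with
#'   simple effects; P3.trust as P1.3.
#' * Study 4: P4.1-P4.3 inequality effects on stealing / trust /
#'   cooperation within threshold sets; P4.4-P4.6 inequality x threshold
#'   interactions; each on all rounds and again on the first four rounds.
#'
#' All models control for (z-scored) round; continuous variables are
#' z-scored over each model's analysis subset; decision-level models carry
#' player and set random intercepts, set-level models a set intercept.
#'
#' @param study Integer 1:4 (must match the dataset's design).
#' @param dataset Session log after [apply_exclusions()].
#' @param n_bootstrap Bootstrap draws for the study-1 mediation (default
#'   200; 0 disables).
#' @return Data frame of suite rows (class `"micsoc_suite"`); for study 1,
#'   attribute `mediation` holds the [mediation_analysis()] result.
#' @export
run_prediction_suite <- function(study, dataset, n_bootstrap = 200L) {
  study <- as.integer(study)
  config <- study_config(study)$config
  d <- prepare_decision_frame(dataset[dataset$round_index >= 1L, ,
                                      drop = FALSE],
                              config$threshold_level)
  if (study %in% c(1L, 2L) && any(d$inequality_condition != "n/a")) {
    stop("dataset does not look like a study ", study, " design",
         call. = FALSE)
  }
  groups_ind <- c("player_id", "set_id")
  rows <- list()
  med <- NULL

  fit_trust_coop <- function(dd, label, rounds = "all") {
    nd <- rescore(dd[dd$steal == 0, , drop = FALSE])
    f <- fit_bayes_glmm(coop ~ trust_z + round_z, nd, groups = groups_ind)
    suite_row(label, f, "trust_z", rounds)
  }

  if (study == 1L) {
    f11 <- fit_bayes_glmm(steal ~ below + round_z, rescore(d),
                          groups = groups_ind)
    rows$p11 <- suite_row("P1.1", f11, "below")

    sl <- build_set_level(d, config$threshold_level)
    slz <- sl[stats::complete.cases(sl[c("lag_n_below", "mean_trust")]), ]
    slz <- standardize(slz, c("mean_trust", "lag_n_below", "round_index"))
    f12 <- fit_bayes_glmm(mean_trust ~ lag_n_below + round_index, slz,
                          groups = "set_id", family = "gaussian")
    rows$p12 <- suite_row("P1.2", f12, "lag_n_below")
    med <- mediation_analysis(sl, n_bootstrap = n_bootstrap)

    rows$p13 <- fit_trust_coop(d, "P1.3")
  } else if (study == 2L) {
    f21 <- fit_bayes_glmm(steal ~ below * thr + round_z, rescore(d),
                          groups = groups_ind)
    rows$p21 <- suite_row("P2.1", f21, "below:thr")
    for (v in c(1, 0)) {
      dd <- rescore(d[d$thr == v, , drop = FALSE])
      fs <- fit_bayes_glmm(steal ~ below + round_z, dd, groups = groups_ind)
      rows[[paste0("p21s", v)]] <- suite_row(
        if (v == 1) "P2.1.simple_threshold" else "P2.1.simple_nothreshold",
        fs, "below"
      )
    }

    sl <- build_set_level(d, config$threshold_level)
    slz <- sl[stats::complete.cases(sl[c("lag_n_stealers", "mean_trust")]), ]
    slz <- standardize(slz, c("mean_trust", "lag_n_stealers", "round_index"))
    f22 <- fit_bayes_glmm(mean_trust ~ lag_n_stealers + round_index, slz,
                          groups = "set_id", family = "gaussian")
    rows$p22 <- suite_row("P2.2", f22, "lag_n_stealers")

    rows$p23 <- fit_trust_coop(d, "P2.3")
  } else if (study == 3L) {
    dbelow <- rescore(d[d$below == 1, , drop = FALSE])
    f31 <- fit_bayes_glmm(steal ~ harsh * thr + round_z, dbelow,
                          groups = groups_ind)
    rows$p31 <- suite_row("P3.1", f31, "harsh:thr")
    rows$p31h <- suite_row("P3.1.harsh_overall",
                           fit_bayes_glmm(steal ~ harsh + round_z, dbelow,
                                          groups = groups_ind),
                           "harsh")

    f37 <- fit_bayes_glmm(steal ~ below * thr + round_z, rescore(d),
                          groups = groups_ind)
    rows$p37 <- suite_row("P3.7", f37, "below:thr")
    for (v in c(1, 0)) {
      dd <- rescore(d[d$thr == v, , drop = FALSE])
      fs <- fit_bayes_glmm(steal ~ below + round_z, dd, groups = groups_ind)
      rows[[paste0("p37s", v)]] <- suite_row(
        if (v == 1) "P3.7.simple_threshold" else "P3.7.simple_nothreshold",
        fs, "below"
      )
    }
    rows$p3t <- fit_trust_coop(d, "P3.trust")
  } else if (study == 4L) {
    for (rlab in c("all", "first4")) {
      dr <- if (rlab == "all") d else first_k_rounds(d, 4L)
      dthr <- rescore(dr[dr$thr == 1, , drop = FALSE])
      rows[[paste0("p41", rlab)]] <- suite_row(
        "P4.1", fit_bayes_glmm(steal ~ unequal + round_z, dthr,
                               groups = groups_ind), "unequal", rlab)
      rows[[paste0("p42", rlab)]] <- suite_row(
        "P4.2", fit_bayes_glmm(trust_z ~ unequal + round_z, dthr,
                               groups = groups_ind, family = "gaussian"),
        "unequal", rlab)
      rows[[paste0("p43", rlab)]] <- suite_row(
        "P4.3", fit_bayes_glmm(coop ~ unequal + round_z, dthr,
                               groups = groups_ind), "unequal", rlab)
      drz <- rescore(dr)
      rows[[paste0("p44", rlab)]] <- suite_row(
        "P4.4", fit_bayes_glmm(steal ~ unequal * thr + round_z, drz,
                               groups = groups_ind), "unequal:thr", rlab)
      rows[[paste0("p45", rlab)]] <- suite_row(
        "P4.5", fit_bayes_glmm(trust_z ~ unequal * thr + round_z, drz,
                               groups = groups_ind, family = "gaussian"),
        "unequal:thr", rlab)
      rows[[paste0("p46", rlab)]] <- suite_row(
        "P4.6", fit_bayes_glmm(coop ~ unequal * thr + round_z, drz,
                               groups = groups_ind), "unequal:thr", rlab)
    }
    # replication of the threshold x below-level interaction, all rounds
    frep <- fit_bayes_glmm(steal ~ below * thr + round_z, rescore(d),
                           groups = groups_ind)
    rows$p4rep <- suite_row("P4.repl_below_x_threshold", frep, "below:thr")
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("micsoc_suite", "data.frame")
  if (!is.null(med)) attr(out, "mediation") <- med
  attr(out, "study") <- study
  out
}
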