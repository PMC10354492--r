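#!/usr/bin/env Rscript
# Run the registered prediction suite for each simulated study: the
# desperation effect on stealing, its interaction with threshold presence,
# punishment sensitivity, trust-cooperation coupling, and the inequality
# contrasts (all rounds and first four rounds for study 4). Requires
# 01_simulate.R to have produced scratch/sims/.

suppressPackageStartupMessages(library(micsoc))

dir.create("results", showWarnings = FALSE)
all_rows <- list()
for (study in 1:4) {
  sim <- read_session_csv(sprintf("scratch/sims/sim_study%d.csv", study))
  dat <- apply_exclusions(sim)
  suite <- run_prediction_suite(study, dat, n_bootstrap = 0)
  write_results_json(suite, sprintf("results/predictions_study%d.json",
                                    study))
  cat(sprintf("\n== study %d ==\n", study))
  print(as.data.frame(suite)[, c("prediction", "rounds", "estimate", "or",
                                 "bf_display", "category")], row.names = FALSE)
  suite$study <- study
  all_rows[[study]] <- as.data.frame(suite)
}
combined <- do.call(rbind, all_rows)
write.csv(combined, "results/predictions_all.csv", row.names = FALSE)
cat("\nwrote results/predictions_study{1..4}.json and results/predictions_all.csv\n")
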