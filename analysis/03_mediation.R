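#!/usr/bin/env Rscript
# Set-level lagged mediation for the study-1 society: does the number of
# desperate (below-threshold) players depress next-round trust *through*
# the amount of stealing they trigger? Requires 01_simulate.R.

suppressPackageStartupMessages(library(micsoc))

dir.create("results", showWarnings = FALSE)
set.seed(20260925)
sim <- read_session_csv("scratch/sims/sim_study1.csv")
dat <- apply_exclusions(sim)
sl <- build_set_level(dat, study_config(1)$config$threshold_level)
med <- mediation_analysis(sl, n_bootstrap = 1000)
print(med)

out <- data.frame(
  quantity = c("a_below_to_stealers", "b_stealers_to_trust", "direct",
               "total", "indirect", "proportion_of_total",
               "proportion_of_paths"),
  estimate = c(med$a, med$b, med$direct, med$total, med$indirect,
               med$proportion_total, med$proportion_paths),
  ci_lo = med$ci[c("a", "b", "direct", "total", "indirect",
                   "proportion_total", "proportion_paths"), 1],
  ci_hi = med$ci[c("a", "b", "direct", "total", "indirect",
                   "proportion_total", "proportion_paths"), 2]
)
write.csv(out, "results/mediation_study1.csv", row.names = FALSE)
cat("wrote results/mediation_study1.csv\n")
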