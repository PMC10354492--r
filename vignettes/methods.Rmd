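---
title: "Simulating and analysing desperation-threshold microsocieties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing desperation-threshold microsocieties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micsoc)
```

# The game

Eight players form a *set*. Each round the set is partitioned uniformly at
random into two four-player interaction groups, each player rates on a
1–10 scale how much they trust the others to cooperate, and then chooses
one of three actions:

* **work alone** — never gains or loses points;
* **cooperate** — gains `cooperate_gain` (+5) if the group contains at
  least two cooperators *and* nobody attempted to steal; loses
  `|stolen_loss|` (−5), once per round, if at least one steal attempt in
  the group succeeded;
* **steal** — needs at least one cooperator as a target; the attempt then
  succeeds or is caught with equal probability, paying `steal_gain` or the
  player's punishment-level penalty. With no cooperator present, the
  attempt fizzles with no risk.

Every admissible configuration must make stealing a negative-expectation
gamble (`0.5·gain + 0.5·penalty < 0`); `validate_config()` enforces this.
Stealing is attractive only through its variance — which is exactly what a
*desperation threshold* exploits. In threshold conditions, each real round
a player ends with points strictly below the threshold level adds a fixed
cash penalty at payout, large enough that a handful of below-threshold
rounds wipes out the game bonus (the payout is floored at zero).

Sessions run a few practice ("mock") rounds, reset points to a fresh
starting allocation, then play 8–16 real rounds (uniform; players are not
told the length) or a fixed 12 in the inequality design. In the first two
designs each real round additionally shocks every player's points with a
discretized Gaussian (sd 3) so that players wander across the threshold
even from a degenerate start.

Four study designs are encoded in `study_config()`:

| design | threshold | punishment | starting points | rounds |
|---|---|---|---|---|
| 1 | all sets | single (−40) | 100 (at threshold) | 8–16 |
| 2 | between sets | single (−40) | 100 | 8–16 |
| 3 | within sets | within sets (−15/−30) | iid {180, 190, 200} | 8–16 |
| 4 | between sets | single (−15) | 205, or 2×{180, 190, 220, 230} | 12 |

Study 4's *unequal* allocation is an exact stratification (two players per
value), so every unequal set starts with exactly four players below the
200-point threshold while holding the set mean at 205, identical to the
*equal* condition; the study-3 allocation is genuinely i.i.d. The two
rules are deliberately implemented differently because the designs differ
in kind: one manipulates the cross-sectional distribution, the other only
shifts its location.

# Synthetic agents

The generator's purpose is to produce session data with the statistical
structure the analysis chain assumes, with known ground truth, so that the
chain can be audited by parameter recovery rather than taken on faith.

The steal decision is a logistic model on the log-odds scale:

$$\mathrm{logit}\,P(\text{steal}) = \beta_0 + \beta_{below}\,[x < L] +
\beta_{int}\,[x < L][\text{threshold}] + \beta_{punish}\,[\text{harsh}] +
\beta_{round}\,t + u_i, \qquad u_i \sim N(0, \sigma_{id}^2).$$

Conditional on not stealing, the player cooperates with probability
$\mathrm{logit}^{-1}(\gamma_0 + \gamma_{trust}\,\tau_i)$, where latent
trust $\tau_i \in [0,1]$ follows an exponential moving average of the
observed cooperativeness of the player's *own group* (the outcome page
shows only one's own group):
$\tau \leftarrow (1-\lambda)\tau + \lambda\,(1 - s/3)$ with $s$ the steal
attempts by the three others. The 1–10 trust rating is a rounded affine
readout of $\tau$ plus Gaussian noise; in the designs that also elicit a
steal-likelihood rating, the second rating's noise is negatively
correlated with the first's, with an analytic inflation factor
compensating the variance the integer rounding adds, so the two ratings
correlate at the calibration target (default magnitude 0.44).

Three presets fix the study conditions:

* `null_agent` — $\beta_0 = -2.2$ (a realistic ~10% base attempt rate),
  $\sigma_{id} = 0.5$, every structural effect zero. Used for type-I /
  null calibration.
* `paper_like` — $\beta_{below} = 0.3$ (a loss-response present in every
  condition), $\beta_{int} = 0.9$ (so the below-effect odds ratio is
  ~1.35 without a threshold and ~3.3 with one, magnitudes typical of
  incentivised economic-game experiments on desperation and risk-taking),
  $\beta_{punish} = -0.3$, $\beta_{round} = -0.03$,
  $\sigma_{id} = 0.8$, $\gamma_{trust} = 4$ on the latent scale.
* `cn_threshold` — the near-deterministic strategy the
  desperation-threshold theory predicts: steal with high probability when
  the threshold is in force and points are below it, otherwise cooperate
  iff trust clears a cutoff.

These defaults were chosen once, from the magnitudes a behavioural
economist would call realistic for an incentivised online game, and are
not adjusted against test outcomes. Initial latent trust is 0.65: players
typically arrive mildly trusting, matching opening ratings around 6–7 on
the 10-point scale.

What the generator deliberately does **not** emulate: human trust
dynamics have no known functional form (the EMA is this package's
modelling choice); real participants in no-threshold conditions did not
know a threshold existed, whereas the generative family conditions on
`threshold_active` so one parameter family spans all conditions; there is
no learning or optimal-control behaviour, no comprehension failures, and
dropout is a simple i.i.d. per-round hazard (off by default). Passing
tests therefore certify the *pipeline* — engine rules, estimator
calibration, directionality under a known data-generating process — not
any claim about human behaviour.

# The analysis chain

All models are generalized linear mixed models with random intercepts,
fitted in a standardized Bayesian style: independent $N(0, 1)$ priors
on fixed coefficients, 0/1 indicators left unscaled (so logistic
coefficients exponentiate to odds ratios), continuous outcomes and
predictors z-scored over the analysis subset (so Gaussian coefficients are
standardized $\beta$), and a z-scored round covariate in every model.
Decision-level models carry player and set intercepts; set-level models a
set intercept — the minimal grouping the set/player design implies. The
below-threshold indicator in decision models uses the points level *at the
moment of deciding* (`points_before`); the payout penalty counts
end-of-round points. The intercept gets a diffuse $N(0, 10^2)$ prior
rather than $N(0,1)$: the shrinkage prior is meant for effects, and
shrinking a baseline log-odds of −2.5 towards zero would bias every rate.

## Laplace fitting

For fixed variance parameters the joint penalized posterior of
coefficients and random intercepts is maximized by Newton iterations on a
sparse system (`Matrix`); random-effect (and residual) standard deviations
maximize the Laplace approximation to the marginal likelihood, with the
coefficient block of the inverse observed information at the mode giving
the Gaussian posterior approximation. Numerical choices: Newton tolerance
$10^{-8}$ on the gradient with step-halving; outer optimization of log-sd
parameters by Brent (one parameter) or Nelder–Mead (several), warm-started
between evaluations; log-sd bounded in $[-6, 3]$. Degenerate inputs —
zero-variance outcomes or predictors, apparent complete separation when
the prior is too diffuse to regularize it — raise errors naming the term,
never silent drops. With no data at all the posterior is returned equal to
the prior (every Bayes factor 1), the Savage–Dickey identity's degenerate
case.

Analyses of this kind are conventionally run with MCMC samplers (brms and
friends); this package uses a Laplace approximation instead, so agreement
with sampler-based fits of the same models is expected to be approximate,
never asserted as exact. An independent mixed-model implementation (lme4)
is used in the test suite as a cross-check in the diffuse-prior limit.

## Bayes factors and evidence labels

Savage–Dickey density ratios, $BF = \phi(0; 0, \tau) / \phi(0; \mu,
\sigma)$, with display capped at "> 1000". Labels follow the conventional
1/3/10/30/100 bands (anecdotal / moderate / strong / very strong /
extreme) and their reciprocals for the null. The test suite audits the
categorizer against a curated collection of published BF–label pairings
from this experimental literature; exactly one of them (a BF of 2.50
called "moderate") is inconsistent with the bands, and the categorizer
follows the bands, not that label.

## Mediation

The set-level mediation uses one-round-lagged predictors: path *a*
regresses last round's stealer count on last round's below-threshold
count; path *b* and the direct effect come from regressing this round's
mean trust on both lagged counts; the total effect from the
single-predictor model. All three are standardized Gaussian set-intercept
models with a round control on the lag-complete rows. The indirect effect
is $a \cdot b$. The proportion mediated is reported both as
indirect/total and indirect/(indirect + direct): with partial pooling and
unbalanced panels the decomposition $total = direct + indirect$ holds only
approximately, so the two versions differ slightly and are flagged when
the indirect path and total disagree in sign. Uncertainty comes from a
bootstrap that resamples whole sets (default 1000 draws), respecting the
cluster structure.

# Calibration evidence

The test suite audits the chain at these problem sizes, chosen to make
Monte-Carlo error small relative to the tolerances while keeping a full
run in minutes:

* engine payoffs against an independently enumerated rule table over all
  $3^4$ action profiles × steal-flag combinations × four study configs;
* Savage–Dickey against numerically integrated conjugate normal–normal
  Bayes factors (< 1% relative error);
* parameter recovery of $\beta_{below} \in \{0, 0.7, 1.2\}$ at 60 sets ×
  12 rounds × 50 replicates: absolute bias below 0.15, CI coverage at
  least 85%. The inequality design supplies the recovery substrate because
  its stratified allocation varies below-threshold status exogenously;
  in designs where desperation only arises endogenously (through being
  caught or robbed), below-status correlates with the player intercept and
  a small positive bias at the null is expected and observed;
* null calibration on `null_agent` data (50 replicates): median BF < 1 for
  the below effect and the threshold interaction, interval coverage of 0
  within 7 points of nominal;
* qualitative replication with `paper_like` agents (20 replicates each):
  below-threshold OR > 1; threshold-stratum OR above the
  no-threshold-stratum OR; and, under fully cooperative
  threshold-strategy play, the unequal condition's four initially
  desperate players per set regaining the threshold within four rounds
  (the +5 cooperative gain closes the worst 20-point gap in exactly four).

# Known limitations

* The trust model is a measurement convenience; nothing here estimates
  how human trust actually updates.
* The fitter's posterior is a Gaussian (Laplace) approximation; for very
  sparse strata (few steal events) credible intervals can be optimistic,
  which is why degenerate strata error out rather than fit.
* Victim selection for successful theft is unspecified in the game's
  source description; here every cooperator in the group loses the small
  amount once per round when any attempt succeeds. A one-random-victim
  variant would change only the variance of cooperator losses.
* Points may go negative (no floor is stated for the game itself); the
  economics are handled entirely by the payout floor.
* The per-session substream derivation (`session_seed()`) is an explicit
  affine hash; it guarantees reproducibility, not cryptographic
  independence, which at these simulation sizes is immaterial.
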