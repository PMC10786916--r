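---
title: "The cooperation-and-punishment model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cooperation-and-punishment model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopunish)
```

## The measurement problem and the model

Observed punishment in a Prisoner's Dilemma with a costly punishment
option mixes qualitatively different processes. The
cooperation-and-punishment model is a multinomial processing tree (MPT)
model that decomposes the eight observable outcome categories per
condition — partner behaviour (two trees) × participant decision ×
punished-or-not — into five latent probabilities:

* `C` — the participant's propensity to cooperate. Both players decide
  simultaneously, so `C` is assumed identical in both trees: the
  participant cannot condition the decision on the partner's move, which
  is revealed only afterwards.
* `p_moral` — punishment specifically provoked when the participant's
  cooperation meets the partner's defection.
* `p_hypocritical` — punishment after mutual defection.
* `p_antisocial` — punishment of a cooperating partner by a defecting
  participant.
* `b` — an unspecific punishment bias that can fire in any cell when the
  outcome-specific process does not. Mutual cooperation offers no specific
  reason to punish, so that cell identifies `b` alone; in the other three
  cells the punish probability is `P + (1 - P) * b`.

`category_probabilities()` returns the eight branch products;
`write_eqn()` exports the structure in an EQN-style text format for
interchange with general MPT tooling.

Punishment is binary in the model: any investment of 1–3 points counts as
"punished". The graded amounts (and the corresponding 10/20/30-point
fines) exist only in the trial-level simulator, where they drive the
payoff ledger. Whether punishment *magnitude* carries additional signal is
an open question the model does not address.

## Estimation

Data are pooled over participants into aggregate category counts per
condition — the standard aggregate MPT approach matching group-level
parameter estimates and a group-level fit statistic. The likelihood is
product-multinomial: each tree is a multinomial over its four categories
conditional on that tree's trial total. Conventions: `0 * log 0 = 0`; a
positive count on a zero-probability cell yields a log-likelihood of
`-Inf` (a boundary misfit that the optimizer moves away from, not an
exception).

`cp_fit()` maximizes the likelihood over the free parameters of the
sharing map. Numerical choices:

* **Transform.** Optimization runs unconstrained on the log-odds scale
  with an analytic gradient; estimates are mapped back through the
  logistic.
* **Multistart.** 5 starts by default: one informed start from the
  closed-form estimator (below) plus 4 uniform random draws on
  [0.05, 0.95], seeded via the `seed` argument. The objective tolerance is
  `rel.tol = 1e-12`. With these settings the best objective is stable to
  below 1e-6 across reruns with different seeds (tested).
* **Closed form.** For an unrestricted condition the likelihood
  factorizes: `C` is the overall cooperation rate; `b` is the punish rate
  of the mutual-cooperation cell; each specific punishment parameter is
  `(r - b) / (1 - b)` for the cell's punish rate `r`, clipped to [0, 1].
  This serves as the informed start and as an independent oracle in the
  tests — the optimizer must reproduce it to 1e-6 whenever the unclipped
  values are interior.
* **Goodness of fit.** `G^2 = 2 (lnL_saturated - lnL_model)`, clamped at
  zero against numerical noise; the saturated term uses observed
  tree-conditional relative frequencies with the same `0 log 0`
  convention. Degrees of freedom: three free category probabilities per
  tree minus the number of free parameter indices (two-condition base
  model: `12 - 10 = 2`).
* **Boundaries.** Estimates at 0/1 are legal; they are reported at the
  boundary with a flag and df is left unchanged. Empty trees contribute
  nothing and trigger a warning, never an error.
* **Standard errors.** Square roots of the diagonal of the inverse
  observed information (the Hessian of the negative log-likelihood at the
  optimum, probability scale, differentiated from the analytic gradient).
  When an estimate is on the boundary or the information matrix is
  singular, a parametric bootstrap (200 refits by default) replaces it;
  `se_method` records which route produced the numbers. On large interior
  datasets the two routes agree within 10% relative (tested).

Equality restrictions (`cp_restrict()`, `cp_test_restriction()`) merge two
free-parameter indices — one parameter across the two conditions, or a
cross-parameter pair such as moral punishment in the cooperating-majority
condition against antisocial punishment in the defecting-majority
condition, which is a substantively meaningful contrast in this design and
therefore a first-class restriction type. The test statistic is
`Delta G^2 = G^2_restricted - G^2_base` on 1 df, clamped at zero (nesting
guarantees non-negativity up to optimizer noise; a deficit larger than
1e-8 triggers a warning about base-fit convergence instead of being
silently absorbed).

## Effect sizes, power and sensitivity

Cohen's `w = sqrt(Delta G^2 / N)`. **`N` is the total number of decisions
(participants × 25 analyzed trials), not the participant count.** This is
the convention under which every reported effect size in the motivating
experiments reproduces from its `Delta G^2`, and it matches the
noncentrality convention `lambda = N * w^2` of standard chi-square power
software. `chisq_power()` evaluates the noncentral chi-square survival
function at the central `1 - alpha` quantile; `sensitivity_w()` inverts it
by root bracketing to a power tolerance of 1e-10, so the round trip
`chisq_power(sensitivity_w(p)) == p` holds to 1e-8. The sensitivity
analysis defaults to `df = 1`, the df of every restriction test in the
battery. At the full design size (`N = 13600`, power 0.95, alpha 0.05)
the minimal detectable effect is `w ≈ 0.031`, i.e. 0.03 at reporting
precision.

Reporting precision throughout (`print`, markdown reports): `G^2` to 2
decimals, `p` to 3 decimals with `< 0.001` below that, `w` to 2 decimals.
JSON serializations always keep full precision.

## The synthetic-data generator

`simulate_experiment()` emulates the experimental design trial by trial:

* **Base-rate manipulation.** Each participant's partner schedule
  contains exactly `round(rate × trials)` cooperation trials (15 or 10 of
  25), shuffled per participant. The source design says partners cooperate
  in "60% of the trials" without fixing per-participant exactness; the
  exact schedule is the default because it matches the design totals
  deterministically, and a Bernoulli-per-trial policy is available via
  `schedule = "bernoulli"` (non-integer `rate × trials` designs require
  it). Only the 25 analyzed trials are generated; training trials are
  not simulated.
* **Behaviour.** The participant cooperates with probability `C`
  independently of the scheduled partner move; punishment follows the
  realized cell's tree (specific process first, else the bias), making
  the generator the exact sampling counterpart of
  `category_probabilities()` — simulated cell frequencies converge on the
  branch probabilities (tested at 1e5 decisions within 3 binomial SEs).
* **Graded punishment.** A punishing participant invests 1, 2 or 3
  points uniformly; the model is agnostic to the amount, and uniform
  mirrors the partners' randomly determined 10/20/30-point fines. In the
  two-sided-punishment variant (`exp1` preset) partners always fine the
  participant's unilateral defection by a uniform 10/20/30 points; in the
  unilateral variant (`exp2`) they never punish.
* **Ledger.** Payoffs follow the PD matrix (+10/+10, 0/0, +20/−10);
  each trial's delta is the game payoff minus own investment minus fines
  received, accumulated from a 150-point endowment. Balances may go
  negative; no bankruptcy rule exists in the design.
* **Presets.** `experiment_design("exp1")` encodes 278/266 participants
  (cooperating-/defecting-majority) with partner punishment;
  `"exp2"` encodes 250/245 without.
* **Default generating parameters.** `default_true_parameters()` sets
  `C` to the observed behavioral cooperation rates (0.70/0.56 with
  partner punishment, closer to the 0.6/0.4 base rates without), and
  punishment parameters reproducing the qualitative fitted pattern (moral
  ≈ 0.4–0.5 and dominant, hypocritical ≈ 0.2, antisocial ≤ 0.15 and
  larger under the cooperating majority, bias ≈ 0.05). The exact fitted
  punishment estimates are published only graphically, so these values
  are fixed plausible choices, not reproductions.

What the generator deliberately does **not** emulate: learning or
trial-order effects (decisions are i.i.d. given the parameters — the MPT
model is static), partner-identity effects, punishment-amount
heterogeneity, and participant exclusions (it produces clean data).
Passing recovery and calibration tests therefore show that the estimation
machinery is correct for data generated by the model itself; they cannot
certify the model's substantive adequacy for real participants, where
sequential dependencies or individual heterogeneity may bias aggregate
estimates.

## Monte-Carlo problem sizes

The test suite and the acceptance script use: 200 replications of 500
participants × 25 trials for parameter recovery (mean absolute error
below 0.02 per parameter); 500 replications at the full 544-participant
design for null calibration (mean `G^2` ≈ 2, restriction-test type-I
error ≈ 0.05, with counts drawn directly from the tree multinomials via
`simulate_counts()` for speed); 4000 participants × 25 trials (1e5
decisions) for generator/model consistency. Bulk loops use the informed
start plus one random start rather than the 5-start default — the
likelihood factorizes and is well-behaved, and single fits retain the full
multistart.

## Known limitations

* Aggregate fitting assumes homogeneous parameters across participants;
  hierarchical (participant-level) extensions are out of scope.
* Fits to the original experiments' raw data are not bundled: the
  published group-level `G^2` values depend on the archived dataset,
  which this package does not ship. `read_trials()` with a column
  mapping supports re-analyzing such exports.
* Standard errors are SE-based only; no profile or Bayesian intervals.
* Boundary estimates keep their nominal df; the mixture asymptotics of
  boundary likelihood-ratio tests are not implemented.
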