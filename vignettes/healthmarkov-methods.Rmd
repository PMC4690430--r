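---
title: "Latent Markov health models and morbidity scenarios: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent Markov health models and morbidity scenarios: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthmarkov)
```

## The model

`healthmarkov` implements a latent Markov (hidden Markov) model of health
in older adults, built for panels that combine survey-based health
indicators observed only at multi-year waves with administratively
registered health care costs observed annually. A discrete latent health
state $\eta_{i,t}$ with $M$ states (by default three living states —
good, moderate, poor — plus an absorbing death state) drives everything
that is observed:

* **Indicator emissions.** Each of $J = 7$ categorical indicators
  (self-perceived health, a mobility score, a categorized dressing
  performance test, the GALI activity-limitation item, a chronic-disease
  count category, CES-D depression and MMSE cognition cut-offs) has a
  separate multinomial distribution per living state,
  $P(y^j_{i,t} = k \mid \eta_{i,t} = m)$, parameterized as multinomial
  logits without covariates. Category 1 is always the best outcome.
* **Cost emissions.** Annual costs per service (hospital care, formal
  home care, institutional long-term care) follow a two-part model per
  living state: a logit for any use, times a Gamma GLM with log link for
  the positive amount, with covariates sex, partner status, age,
  education and calendar-year dummies. One dispersion parameter is
  estimated per service, shared across states.
* **Structure.** First-order annual transitions between states, one
  multinomial logit per living origin with covariates sex, partner, age
  and education (no calendar year); death is absorbing. The initial state
  follows a multinomial logit on age and sex at first observation.

The marginal likelihood of an individual's record sequence sums the
products of initial, transition and emission probabilities over all
latent paths. Years without survey data contribute only their observed
cost densities; fully unobserved years contribute a factor one. Death is
treated as exactly observed through vital status: the death-year record
has emission probability one for the death state and zero for living
states, and living emissions are impossible from death.

## Estimation

The likelihood is maximized by expectation–maximization:

* **E step.** Scaled forward–backward recursions (implemented in C++)
  produce smoothed state probabilities $\gamma$, pairwise joint
  probabilities $\xi$, and the exact log-likelihood. A brute-force
  path-enumeration oracle (`loglik_brute_force`) validates the recursion
  to $10^{-10}$ relative accuracy on randomized small instances.
* **M step.** Posterior-weighted fits, each run to full inner
  convergence so the observed-data log-likelihood is monotone:
  Newton–Raphson weighted multinomial logits for the initial-state and
  transition models (warm-started at the previous iteration), closed-form
  weighted category frequencies for indicator intercepts, weighted
  logistic and Gamma GLM fits for the cost models, and a univariate
  maximum-likelihood update of the Gamma dispersion given the fitted
  means. When a state receives too little posterior weight for the full
  cost design (17 columns with calendar dummies), the fit falls back to
  the base covariates and finally to an intercept — relevant only for
  very small panels.
* **Initialization.** Each record's mean standardized indicator severity
  is partitioned by k-means into the living states, ordered by severity;
  one M step on the implied hard posteriors gives the starting values.
  This start is deterministic and, on this model class, reliably in the
  right basin, so the default is a single start; additional restarts
  (jittered partitions) are available via `n_restarts`.
* **Conventions.** Convergence when the relative log-likelihood change
  falls below $10^{-7}$ (default cap 500 iterations). Age enters all
  logits linearly per decade centered at 75; education is an ordinal
  score 1–3 centered at 2; the first panel year is the reference
  calendar-year dummy. The mixture is identified after estimation by
  `label_states`, which orders living states by mean standardized
  severity (ties broken by death probability at the reference profile),
  not by constraints during estimation.

Home-care and institutional LTC costs are observed only in a short late
registry window, so they stay out of the joint likelihood; their two-part
models are estimated *ex post* by posterior-probability-weighted fits on
the window years (`fit_expost_cost_model`), with inestimable calendar
dummies pinned to the reference level.

Model size is chosen by comparing candidate state counts via AIC/BIC
(`select_num_states`); parameter counts grow quadratically with the
number of living states through the transition block.

## The synthetic panel generator

No public version of the original survey–registry linkage exists, so the
package ships a seeded generator that reproduces its statistical
structure: entry ages uniform on 55–85 in 1995, a refreshment cohort
with entry ages 55–64 in 2002, indicator waves every third year from
1995, hospital costs registered annually 1995–2007, home-care and LTC
costs only 2004–2007, and death as the only source of attrition. The
default ground truth (`make_default_truth`):

* anchors the living transition rows at the reference profile (men aged
  75, with partner, middle education) to the baseline transition matrix
  used by the scenario machinery — good (0.87, 0.07, 0.04, 0.02),
  moderate (~0, 0.87, 0.10, 0.03), poor (~0, 0.04, 0.81, 0.15) — with
  the structurally tiny recovery probabilities set to 0.002 since
  multinomial logits need positive mass;
* lets the death logit rise ≈0.7–0.85 per decade of age (a Gompertz-like
  gradient) and gives women a −0.5 logit mortality advantage, so the
  implied period life expectancy at 65 (about 15.4 years for men and
  18.4 for women) sits near published Dutch values from the mid-2000s;
  an exact match is impossible while keeping the transition-row anchor;
* gives each indicator state-specific target severities (solved exactly
  for linear-in-category logit slopes) that reproduce the qualitative
  state profiles: good health near the best outcome on everything;
  moderate health combining a high chronic-disease probability with mild
  disability and little depression or cognitive impairment; poor health
  severe on disability, depression and cognition, with self-perceived
  health only slightly worse than moderate;
* uses two-part cost models whose expected costs increase from good to
  poor for every service at ages 65–85, with LTC use rising steeply with
  age. Amounts are abstract cost units of realistic magnitude; no claim
  is made about real euro levels.

The seed perturbs intercepts and severity targets slightly, preserving
all orderings, so different seeds give distinct but equally shaped
truths, and all output is bit-reproducible given the seed.

What the generator does *not* emulate: informative non-mortality
dropout (attrition in the source cohort was predominantly mortality),
the irregular empirical wave calendar (a strict three-year cycle is
used), linkage errors, cohort trends in covariates, and covariate
effects on indicator emissions (absent from the model by design).
Passing tests therefore demonstrate internal statistical correctness and
recoverability under the model's own assumptions, not robustness to
violations of them.

## Scenario machinery

Scenarios start from a given remaining life expectancy (LE) at 65 in
2050 — 21.1/24.6 years for men/women in the standard variant, 24.1/27.6
in the optimistic variant — and differ in *how* the transition model is
bent to get there. All operators rescale selected entries of a
row-stochastic transition row by a compounded multiplier
$(1-x)^{\,\text{year}-2010}$ and reallocate the freed mass:

* **Expansion of morbidity** (`1o`, `1++`): the death entry of every
  living row is scaled; survivors stay in their current state (freed
  mass to the diagonal).
* **Compression of morbidity** (`2o`, `2+`, `2++`): for good and
  moderate origins, transitions to strictly worse living states and to
  death are scaled, freed mass to the diagonal; the poor-origin row is
  untouched. The allocation of the freed mass to the own state is the
  one genuinely open choice here; it is the minimal reading of "raising
  the probability of remaining in good or moderate health".
* **Dynamic equilibrium** (`3o`, `3+`, `3++`): for good/moderate
  origins, transitions to poor health and death are scaled with the
  freed mass moved to the moderate entry; a second rate scales the
  poor-origin death probability so expected poor-state years can be held
  at their baseline value.

`+` variants also ramp the initial profile of new 65-year-olds linearly
in calendar year ("gradually" is not otherwise specified): the good
share to 100% in 2050 under compression, the moderate share to 45%
under dynamic equilibrium, with the remaining mass spread
proportionally over the other living states. Ramp endpoints follow the
stated percentages (100%, 45%) rather than rounded tabulations
elsewhere (0.99, 0.44).

**Life tables.** Remaining LE at 65 uses the period convention by
default — the scenario adjustment frozen at the stated calendar year
while the synthetic cohort ages — matching the demographic forecasts the
targets come from; a cohort convention (calendar advancing with age) is
available and is what makes a lone projected cohort's aggregate
expenditures equal its lifetime costs exactly. Occupancy is accumulated
from age 65 to an age cap of 110, with a configurable half-year
correction crediting the death year with half a person-year attributed
to the start-of-year state. Covariates other than age and sex are held
at representative levels (partner = 1, education = 2).

**Calibration.** For expansion and compression, a single rate is found
by bracketing and bisection on $x \in [0, 0.5]$ to $10^{-6}$ in $x$ (LE
is strictly increasing in $x$, so the root is unique); achieved LE must
be within 0.005 years of the target. Dynamic scenarios use a nested
solve: an inner bisection finds the poor-death rate holding poor-state
years at baseline for each candidate $x$, and the outer bisection moves
$x$ to the LE target. Where the inner bracket is infeasible (possible at
the outer bisection's endpoints), the inner solution is clamped to its
boundary and feasibility is verified at the final solution. Calibration
is per sex, since the targets are sex-specific. A target below the
baseline LE or above what $x \le 0.5$ can reach raises an error stating
the achievable range.

## Projection and outcomes

The population projection is a deterministic expected-value calculation:
2010 stock counts by age (65–95) and sex are allocated to states by the
model's age/sex-specific initial-state shares, advanced annually through
the scenario-adjusted transition rows, and topped up each year with a
new cohort of 65-year-olds carrying the scenario's (possibly ramped)
initial profile. Ages are capped at 110 (survivors are moved to deaths).
The bundled default inputs are flat synthetic counts — 100 persons per
age/sex cell in 2010 and 100 entrants per sex per year — stand-ins for
real demographic series, which are config inputs. A seeded
individual-level microsimulation (`microsimulate_population`, with
cell-wise multinomial transitions and two-part cost draws, death years
carrying half weight) exists as a Monte-Carlo cross-check of the
deterministic projection, not as the projection engine.

Outcomes are reported from three perspectives: state-decomposed
remaining LE and lifetime costs at 65 (undiscounted, accruing to the
start-of-year state with the life table's half-year death convention),
population pyramids, and aggregate expenditure series 2010–2050 with
geometric-mean annual growth rates
$((\text{end}/\text{start})^{1/40}-1)\times 100$. Costs in projections
are evaluated at the cost models' reference calendar level; no
discounting or price inflation is applied.

## Problem sizes and numerical checks

The test suite exercises, among others: forward–backward vs. brute-force
path enumeration on 130 randomized instances ($10^{-10}$ relative);
EM ascent ($10^{-8}$) and stationarity at convergence; parameter
recovery on ten seeded panels of 2,000 individuals over 13 years
(transition rows at the reference profile within ±0.02, emission
probabilities within ±0.03, required in at least 8 of 10 seeds);
calibration of all eight scenarios for both sexes to within 0.005 years
of their LE targets while dynamic scenarios hold poor-state years within
0.005 of baseline; exact (to $10^{-9}$ relative) population accounting
and cohort/aggregate expenditure consistency; and agreement between the
deterministic projection and a 50,000-individual microsimulation within
three Monte-Carlo standard errors. These sizes are the package's chosen
trade-off between statistical resolution and run time.

## Known limitations

* Individuals are assumed administratively observed every year until
  death; gaps in the annual record are rejected rather than bridged.
* Covariates other than age advance are frozen along projections and
  life tables; no partner-status or education dynamics.
* The projection has no migration, no ages below 65, and no uncertainty
  intervals; it is an expectation, not a stochastic forecast.
* Cost levels are abstract units: real-price attachment, discounting and
  demographic input series are out of scope.
* The identifiability of the mixture rests on the post-hoc severity
  ordering; models whose states do not separate on indicator severity
  would need a different labeling rule.
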