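---
title: "Multi-state cost-effectiveness modelling of ICU skin-antiseptic strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state cost-effectiveness modelling of ICU skin-antiseptic strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhsmcea)
```

## The problem

Catheter-related bloodstream infections (CRBSI) are rare but expensive and
dangerous events in intensive care. When several skin-antiseptic
strategies (chlorhexidine-alcohol vs povidone iodine-alcohol, with a
one-step or four-step application) are compared in a trial, the economic
question is not only *which strategy causes fewer infections* but *what a
prevented infection costs*. `nhsmcea` implements the full analysis
pipeline for this question: a discrete-time, non-homogeneous eight-state
model of the ICU stay fitted to daily individual-patient trajectories, a
cohort simulator, a per-state cost engine, pairwise incremental
cost-effectiveness (ICER / dominance) comparison, and patient-level
bootstrap uncertainty with Efron's BCa intervals.

## The model

A patient's day in the ICU is classified into one of eight health
states: catheterized care without incident (state 1), a new catheter
inserted (2), CRBSI without or with a new catheter (3, 4), contact
dermatitis (5), a switch to a neutral semipermeable dressing after
dermatitis (6), and two absorbing states, discharge alive (7) and death
in the ICU (8). The chain is followed on integer ICU days, day 0 being
inclusion, with half-open day intervals; daily resolution matches the
per-patient-per-day structure of the cost inputs.

Transitions are governed by a *schedule* of daily row-stochastic
matrices $P_t$, $t = 0, \dots, H-1$, with $P_t[i,j]$ the probability of
being in state $j$ at day $t+1$ given state $i$ at day $t$. The
time-inhomogeneity is indexed by calendar ICU day rather than sojourn
time: with daily panel observations, calendar-day matrices are exactly
estimable by counting, whereas a sojourn-clock formulation would require
assumptions the data cannot check. This is the one genuinely open design
choice in the formulation; we implement the calendar-day reading and
regard a sojourn-clock variant as out of scope.

Estimation (`fit_multistate()`) is nonparametric: row $i$ of $P_t$ is
the row-normalized count of observed $i \to j$ transitions from day $t$
to $t+1$, after the panel is expanded to a daily grid (last observation
carried forward between visits, absorbing states carried to the
horizon, administratively censored subjects leaving the risk set).
Sparse state-days borrow counts from the nearest adjacent days until a
minimum at-risk threshold (default 5) is reached; rows never observed
fall back to the identity, which keeps every chain well defined.
Entries outside the allowed-transition mask are zeroed. The mask itself
encodes the model structure: all transient states may persist or
absorb, CRBSI is entered from the catheterized states 1–2, the neutral
dressing state 6 is entered only from the dermatitis state 5 and may
emit back to 5 or resolve to 1, and absorbing states only self-loop.

From a fitted schedule the package computes the functionals the
analysis reports:

* **occupancy (prevalence) curves** $\pi_{t+1} = \pi_t P_t$;
* **expected total length of stay** per state,
  $\sum_{t=1}^{H} \pi_t[s]$ — day 0 is the initial observation and is
  not credited, so stays sum exactly to the horizon, and ICU life
  expectancy is $H - \mathrm{LOS}(\text{death})$;
* **expected visits** per state,
  $\pi_0[s] + \sum_t \sum_{i \ne s} \pi_t[i] P_t[i,s]$;
* **first-passage probability** into the CRBSI states by the horizon,
  computed on an augmented chain with shadow-absorbed targets and
  scaled per 1000 patients — the model analogue of the trial's
  effectiveness endpoint.

## Costing

Each arm carries a per-state cost vector (Euro 2016): daily care costs
for states 1–6, a full one-time CRBSI episode premium on states 3–4
(direct treatment €715.01 plus 11.77 additional ICU days at €1,125.41
per day, about €13,961 in all), and zero for the absorbing states. The
published per-state table is shipped as the canonical default because
the non-CRBSI state costs cannot be decomposed from the listed unit
costs (the new-catheter premium in the printed table, ~€603, is not the
listed €117.02 catheter-change cost; the composition involves an
unpublished weighting of catheter-handling scenarios). A reconstruction
mode that rebuilds states 3–4 additively from the ledger is provided
for sensitivity analysis. All arithmetic is kept in full precision;
cent-level inconsistencies in published figures are absorbed by a €0.05
comparison band.

The default costing mode prices occupancy daily:
$\sum_{t=0}^{H-1} \sum_s \pi_t[s]\, c[s]$, i.e. each day a patient
*starts* in a state is charged that state's cost. (Length of stay, by
contrast, credits occupancy at days $1, \dots, H$; the two conventions
differ only in which end of the day they look at, and the cost
convention is the one that makes a one-day stay in state 1 cost exactly
the state-1 daily cost.) Because the CRBSI states carry the whole
episode premium, daily pricing equals per-episode pricing only when
CRBSI sojourns last one day — the default in the generator — so a
`per_entry_event` mode is also shipped that charges states 3–5 once per
expected entry.

## Comparison

`compare_strategies()` orients effectiveness so that *fewer* CRBSI
patients per 1000 is better. A comparator is *dominant* when it is no
more costly and no less effective (at least one strictly), *dominated*
in the reverse case, and otherwise sits in a trade-off quadrant where
the ICER $\Delta C / \Delta E$ (euro per CRBSI patient avoided) is
reported as a magnitude together with the quadrant ("less costly, less
effective", etc.). Published tables mix sign conventions for
$\Delta E$; the package always stores both signed deltas and the
quadrant label. A zero effectiveness difference inside a trade-off is
flagged undefined rather than divided. Statistical comparability is
reported by 95% confidence-interval overlap, the convention of the
underlying analysis — conservative relative to a formal test of the
difference, and deliberately not replaced by one.

## Uncertainty

The resampling unit is the patient: whole trajectories are drawn with
replacement, the only choice consistent with subject-grouped panel
data. Every replicate re-runs the full estimation. Intervals use
Efron's BCa construction with bias-correction
$z_0 = \Phi^{-1}(\#\{\hat\theta^*_b < \hat\theta\}/B)$ and
leave-one-patient-out jackknife acceleration; endpoints are
nearest-rank quantiles of the sorted replicates, so results are
bit-reproducible for a fixed seed. Default $B = 1000$. For rare-event
statistics (two CRBSI cases in ~600 patients) the intervals are
strongly asymmetric with a lower bound at zero, mirroring the shape of
published rare-event intervals.

## The synthetic cohort

The trial database is not public, so the package ships a generator that
emulates its statistical structure; all tests and examples run on it.
Per arm, a patient-day in a transient state faces competing hazards
(discharge, death, CRBSI, catheter change, dermatitis, dressing
switch), resolved by a single multinomial draw so the configured
hazards are exactly the one-day exit probabilities. Defaults encode the
study conditions: arms of 588 / 580 / 587 / 594 patients, expected
CRBSI patient counts 2 / 4 / 15 / 13, CRBSI risk ending at day 60,
100-day death/discharge fractions 29.06%/70.03% and 25.56%/73.73% for
the CHG arms, and mean catheters per patient 2.23 / 2.17 / 2.30 / 2.28.
The corresponding fractions for the PVI arms are unpublished; the
defaults take the midpoint of the CHG arms (27.31% / 71.88%) and are an
assumption of the package, not a reported value. Dermatitis is likewise
unreported and set to a small daily hazard (5e-4) with a fast (0.5/day)
dressing switch. One arm-size ambiguity in the source material (two
sections swap the CHG-T1/PVI-T1 sizes) is resolved by following the
abstract; sizes are configuration, not constants.

Calibration solves the daily hazards by one-dimensional root-finding
(`uniroot`, tolerance 1e-10) against the *exact chain functionals*: the
total exit hazard and its split reproduce the 100-day absorbing
fractions through $1-(1-h)^{H}$; the CRBSI hazard is solved so the
chain's first-passage probability equals the target count over $n$; the
catheter-change hazard so expected entries into the new-catheter states
plus the initial catheter equal the target mean. Solving against the
chain rather than a single-risk closed form matters at the margins: the
closed form ignores the exposure lost to dermatitis and CRBSI sojourn
days and would miss the tightest calibration checks. CRBSI sojourns
longer than one day are represented by a geometric stay with the
configured mean, the first-order-Markov approximation of a fixed
sojourn.

What the generator does *not* emulate: covariate-dependent hazards
(age, severity scores), within-day event ordering, catheter-level
structure, and — importantly — the shape of the length-of-stay
distribution beyond its 100-day absorbing fractions. Real ICU stays
are more right-skewed than the generator's geometric stays, so
synthetic mean costs per patient run some 5–15% above the published
point estimates even though infection rates and mortality match.
Passing tests therefore demonstrate the correctness of the machinery
(estimation, simulation, costing, comparison, bootstrap) under the
study conditions, not numerical reproduction of results that depend on
the unpublished patient-level data.

## Numerical conventions and degenerate inputs

* Schedule rows must sum to 1 within 1e-12; absorbing rows are unit
  self-vectors; masked entries are exactly zero.
* Empty or never-visited estimator rows fall back to identity.
* A CRBSI recorded within two days after ICU discharge is attributed to
  the stay (recoded to the last transient day, discharge following);
  later post-discharge infections are not attributed and are dropped
  from the trajectory with a warning. Records beyond day 100 are
  censored.
* Bootstrap bias-correction counts of 0 or $B$ are clamped to
  $1/(B+1)$, $B/(B+1)$ with a warning; identical replicates yield the
  degenerate interval at the point estimate.
* ICER with $\Delta E = 0$ in a trade-off: undefined, flagged.
* All randomness flows through explicit integer seeds; per-arm seeds
  are derived from the master seed so arms are independent streams.

## Problem sizes used in the shipped checks

The package's own test suite exercises: parameter recovery on a
simulated cohort of 50,000 patients (daily matrices recovered within
0.02 absolute where at least 500 patients are at risk); matrix-product
occupancy versus a 100,000-path Monte-Carlo cohort (within 3 binomial
standard errors cell-wise); BCa coverage of a normal mean over 10,000
simulated datasets at $B = 1000$ (93–97%); and calibration of all four
default arms over 200 replicate cohorts (targets within 3 standard
errors). These sizes were chosen so each check has enough resolution to
detect the faults it guards against while the whole suite stays
routinely runnable.

## A worked example

```{r example, eval = FALSE}
cfg <- default_arm_profiles(seed = 1)
panel <- generate_panel(cfg)
panel <- apply_censoring_rules(panel)

fit <- fit_multistate(panel, arm = "CHG-T1")
summary(fit)

ct <- build_cost_table()
report <- run_pipeline(analysis_config(generator = cfg, seed = 1))
report
```

## Known limitations

* Calendar-day inhomogeneity only; no sojourn-time clocks, parametric
  intensities or covariate effects.
* The alive-patient analysis removes deceased subjects post hoc and
  re-estimates, the literal reading of the source analysis; it is not a
  death-hazard-zeroed chain.
* Costs are undiscounted (horizon under one year), single-currency,
  and confined to the shipped ledger's perspective.
* CI-overlap significance is conservative; no acceptability curves or
  net-benefit framework.
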