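---
title: "A Markov cost-utility model of internet-based versus face-to-face CBT for student anxiety"
author: "cbtcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of internet-based versus face-to-face CBT for student anxiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbtcea)
```

## The decision problem

University students with mild anxiety symptoms can be offered a low-intensity
course of cognitive behavioral therapy either face to face (f-CBT) or as a
guided internet programme (i-CBT). The two delivery modes differ in three
ways that matter economically: students are more willing to *accept* an
internet offer, slightly less likely to *adhere* to it, and the internet
course consumes only a fraction of a psychotherapist's time plus a platform
overhead. `cbtcea` implements a cohort state-transition model that turns
those differences into discounted costs, quality-adjusted life-years
(QALYs), and a cost-effectiveness verdict from a societal perspective, with
full deterministic and probabilistic uncertainty analysis.

## Model structure

The model tracks a cohort that enters all-mild through five health states
-- well, mild, moderate, severe, dead -- over a 5-year horizon in monthly
cycles (60 cycles; short cycles keep discretization error small relative to
the clinical event rates).

1. **Programme phase** (`phase_cycles`, default 3 months, matching a
   9--12-week low-intensity course). The cohort remains in the mild state
   apart from background mortality. Acceptance and adherence are not
   states: they define two strata. The *effective* stratum (accepted and
   adhered, probability $p_\text{accept} \times p_\text{adhere}$) receives
   the programme's recovery and deterioration probabilities; everyone else
   receives the no-intervention rates. For i-CBT the f-CBT acceptance,
   adherence, recovery and deterioration are multiplied by relative
   differences (1.19, 0.99, 1.00, 1.00 at base case), capped at 1 where
   the product is a probability.
2. **Redistribution**. At programme end the surviving cohort splits into
   well / mild / moderate / severe according to the stratum mixture. The
   deterioration mass has no published moderate:severe decomposition; the
   default `proportional` rule splits it like the background
   mild-to-moderate versus mild-to-severe probabilities (0.5214 : 0.4786),
   with `all_moderate` as the conservative alternative. The redistributed
   cohort occupies the cycle after the phase as its own row: the programme
   outcome is valued before background dynamics resume. One consequence,
   frozen in a test, is that a uniform monthly mortality $m$ yields a dead
   fraction of $1-(1-m)^{H-1}$ at the horizon, not $1-(1-m)^{H}$: the
   redistribution month carries no background transitions.
3. **Background Markov dynamics**. From then on the monthly transition
   matrix applies. Off-diagonal morbidity entries are taken verbatim from
   the configured monthly probabilities; the death column is the age-specific
   all-cause monthly mortality, multiplied by the anxiety mortality rate
   ratio (1.66) in the symptomatic states (`mortality_rr_states`); the
   diagonal absorbs the remainder. Mortality is added by reducing the stay
   probability rather than rescaling morbidity -- at $2.5\times10^{-5}$
   per month the competing-risk distortion is negligible.

Students not recovered at programme end are assumed to step up to
high-intensity face-to-face CBT. This escalation is a one-time cost (a
14-session, 60-minute course) charged at phase end, not a second
effectiveness layer: the post-programme transition probabilities are taken
to already embody the outcomes of subsequent care. The default recipients
are accepters not in the well state (`escalation_recipients =
"accepters_not_well"`); charging all non-well survivors is available as a
switch.

### Cycle-length conversion

Published transition probabilities often come on a coarser clock than the
model cycle. `matrix_root(P, k)` converts them by eigendecomposition,
taking the principal $k$-th root of each eigenvalue of $P$. Not every
stochastic matrix has a stochastic root: non-diagonalizable matrices and
negative real eigenvalues raise an explicit error, tiny negative entries
from floating-point noise (above $-10^{-8}$) are clipped and rows
renormalized, and the self-inverse property $(\sqrt[k]{P})^k = P$ is
enforced by property tests on random diagonalizable stochastic matrices.

## Valuation

All costs are in US dollars and all value flows are discounted monthly at
an annual 3 per cent, $d(t) = 1.03^{-t/12}$.

* **QALYs.** A cycle in state $s$ credits $u_{\text{age}} \times u_s / 12$
  QALYs, with the remission utility for the well state. The age-utility
  anchor (0.92) scales the QALY *level* of both arms equally and cancels
  from the incremental comparison; absolute QALY levels are therefore
  sensitive to whether such an anchor is applied, while every incremental
  and threshold result is not.
* **Course costs.** A course is priced as wage $\times$ session duration
  $\times$ number of sessions: US\$208 for low-intensity f-CBT, US\$19
  platform + 22 per cent of therapist time = US\$64.76 for i-CBT, US\$728
  for the high-intensity course. Accepters are charged the full
  low-intensity course (sessions are provisioned on acceptance), spread in
  equal instalments over the phase cycles and discounted per cycle;
  `course_cost_nonadherent = "half"` prorates dropouts instead.
* **Outpatient psychiatric care.** A monthly reimbursement cost (US\$220)
  applies to the states in `outpatient_states`. The default is the mild
  state. This is the one genuinely calibrated structural choice: the
  reimbursement estimate stems from university health-service records of
  students under ongoing outpatient management -- a predominantly mild,
  chronically symptomatic population -- and attaching it to mild occupancy
  is also the only assignment that reproduces the published base-case cost
  totals within tolerance (moderate+severe undershoots them by ~40 per
  cent, all symptomatic states overshoots by ~34 per cent). Moderate and
  severe occupancy meanwhile accrue the hospitalization expectation and
  productivity losses below. Both broader and narrower assignments remain
  one switch away.
* **Hospitalization.** An expected-cost term: severe occupancy $\times$
  monthly hospitalization probability (0.0114) $\times$ cost per episode
  (US\$1,278). The cohort engine uses the expectation; the
  microsimulation samples Bernoulli events, so their means agree by
  construction.
* **Indirect cost.** Friction-cost productivity loss: the employed
  fraction (participation $\times$ (1 - unemployment) = 0.3167) of
  moderate+severe occupancy loses the student wage (US\$10/h) for the
  monthly allowable working hours (56). The friction period is the time
  spent moderate-to-severe itself.

`compare_strategies()` classifies dominance, computes the ICER
$\Delta C / \Delta E$ only in the trade-off case, and always reports the
incremental net monetary benefit $\mathrm{INMB} = \lambda \Delta E -
\Delta C$ at the willingness-to-pay threshold $\lambda$ (US\$46,070, a
GDP-per-capita anchor).

## Uncertainty analysis

Every input carries a distribution family and range. Beta inputs are fitted
by method of moments with $\sigma = (\text{high}-\text{low})/3.92$ (the
range read as a 95 per cent interval); the fitted mean is exact by
construction and infeasible fits fall back to triangular sampling with a
warning. Triangular inputs use the base value as mode. Fixed inputs
(session durations, the age-utility anchor, the discount rate, the horizon
and the threshold) do not vary.

* **One-way analysis** evaluates the incremental results across each
  declared range, flags non-monotone responses rather than hiding them, and
  locates sign changes of the incremental QALY by bisection to an interval
  below $10^{-5}$. Because acceptance and adherence enter the state
  dynamics only through their product, the QALY thresholds on the two
  relative differences are structural: each sits at the reciprocal of the
  other ratio's base value (1/0.99 = 1.0101 and 1/1.19 = 0.8403).
  Cost-only inputs can never move the QALY difference; the suite asserts
  this to $10^{-15}$.
* **Two-way analysis** classifies a grid of two inputs by net monetary
  benefit at the threshold and extracts the decision frontier by per-row
  bisection.
* **Probabilistic analysis** redraws every input independently 10,000
  times (each draw shared by both arms), re-validates each transition row
  and proportionally rescales any draw whose outgoing probabilities reach
  1 (logged; unreachable within the declared ranges), and reports means
  with normal-approximation standard errors of the mean plus the
  acceptability curve $\mathrm{CEAC}(\lambda) = \Pr(\lambda \Delta E -
  \Delta C > 0)$ on a grid from 0 to US\$138,210 in 2,000-dollar steps
  with the exact GDP anchors included. Ties favour the comparator.
  Independence across inputs mirrors the per-row independent uncertainty
  specification; no joint Dirichlet row model is imposed.

## Validation by microsimulation

`simulate_individuals()` is a first-order Monte Carlo re-implementation of
the identical decision process: each student samples acceptance, adherence,
a phase outcome, monthly categorical transitions and Bernoulli
hospitalization events, and accrues the same discounted tallies. It shares
no code path with the cohort recursion beyond the parameter definitions,
so agreement is informative. The suite requires cohort--microsimulation
agreement within three standard errors for costs, QALYs and state
occupancy at cycles 3, 12 and 60, at $n = 20{,}000$ routinely and
$n = 200{,}000$ in the acceptance checks. Randomness is consumed from a
single seeded stream in fixed-width per-individual blocks, so enlarging
$n$ extends the population without replaying earlier individuals.

A scenario generator (`generate_random_scenario()`) fuzzes the engine
invariants -- row-stochasticity, occupancy conservation, non-decreasing
death, non-negative values -- across random parameter sets and structural
configurations.

## What the synthetic machinery does and does not show

The microsimulation validates that the cohort engine solves *its own*
stated process correctly; neither component can validate the clinical
inputs themselves, which come from heterogeneous published sources rather
than a single trial. Passing tests therefore demonstrate internal
consistency and faithful arithmetic, not real-world effectiveness of
internet-delivered CBT. Known structural limitations, each deliberate:
parameter draws are independent (no correlation between, say, acceptance
and adherence); there is no treatment re-entry and no waiting-time penalty
for the face-to-face arm; mortality does not age over the 5-year horizon;
escalation affects costs, not transition probabilities; and the absolute
QALY level depends on the age-utility anchoring convention discussed
above, while all incremental quantities, thresholds and probabilistic
conclusions are invariant to it.

## Worked example

```{r example, eval = FALSE}
inputs <- default_model_inputs()
fit <- cea_model(inputs)
summary(fit)

find_threshold(inputs, "rr_accept_icbt", "delta_qaly_zero")  # 1.0101
find_threshold(inputs, "rr_adhere_icbt", "delta_qaly_zero")  # 0.8403

psa <- run_psa(inputs, n_draws = 10000, seed = 1)
psa
plot(psa, "ceac")
```
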