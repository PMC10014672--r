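---
title: "Methods: a Markov cohort cost-utility pipeline for chemoembolization strategies"
author: "tacecua"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility pipeline for chemoembolization strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacecua)
```

This vignette documents the model behind `tacecua`, the assumptions baked
into its defaults, the estimator and numerical choices, and what the
package's own tests do and do not demonstrate about real data.

## The decision problem and the model

Two first-line chemoembolization strategies for unresectable hepatocellular
carcinoma are compared: conventional lipiodol-based TACE (C-TACE) and
drug-eluting microsphere TACE (DEM-TACE). The comparison is a cost-utility
analysis from a healthcare-payer perspective: incremental direct health
cost per quality-adjusted life year (QALY), with a willingness-to-pay
(WTP) threshold of €25,000/QALY as the default decision rule.

Disease progression is represented by a three-state illness-death Markov
cohort model with 1-year cycles:

* **stable disease** — the starting state of every patient;
* **disease recurrence** — entered from stable; no return to stable;
* **death** — absorbing, reachable from both alive states.

Liver transplant is deliberately *not* a fourth state. It enters the model
in two places only: the utility attached to each alive state is a mixture
over the transplanted and non-transplanted fractions of the arm
(`effective_utility()`: $(1-p_{tx})u_{\text{state}} + p_{tx}u_{tx}$), and
the transplant proportion is an arm-level input. This keeps the state space
identifiable from recurrence/death follow-up data while still letting
transplant shift both QALYs and (through the configured cost moments)
costs.

The cohort vector $v_k$ over (stable, recurrence, death) starts at
$(1,0,0)$ and evolves as $v_{k+1} = v_k P$ with a row-stochastic annual
transition matrix $P$ (death row fixed at $(0,0,1)$, recurrence→stable
structurally zero). Cycle-$k$ payoffs use **start-of-cycle** state
membership, discounted by $(1+r)^{-k}$; the one-off procedure cost enters
at cycle 0. An optional half-cycle correction averages start- and
end-of-cycle occupancy instead. The lifetime horizon is operationalized as
40 cycles or an alive fraction below $10^{-9}$, whichever comes first — at
the hazards relevant here the cohort is numerically extinct well before 40
years, so the cap is not binding in practice.

Because follow-up costs in this population are heavily skewed (median 0
with four-digit means in the stable state), every analysis is run twice:
once with **median-based** and once with **mean-based** state costs. The
two scenarios bracket the plausible economic impact; neither is privileged.

## Synthetic cohorts: what the generator emulates

`generate_cohort()` simulates an already-matched two-arm study of
`n_per_arm = 101` patients per arm (propensity matching itself is out of
scope; the generator emits balanced arms by construction). The event
process is a latent-time competing-risks construction with constant
hazards: stable→recurrence ($h_{sr}$) and stable→death ($h_{sd}$) compete;
on recurrence, a residual recurrence→death time with hazard $h_{rd}$
follows. With the default Weibull shape of 1 all sojourns are exponential
and the process is Markov; a shape ≠ 1 is accepted as an extension.

Administrative censoring mimics a study that accrued patients over 8 years
and closed follow-up 13.5 years after accrual started: each patient gets a
uniform accrual offset in $[0, 8)$ years, hence a censoring time uniform on
$(5.5, 13.5]$ years. No loss to follow-up beyond administrative censoring
is simulated — the source study followed patients through clinical charts
until death or study end, and no censoring-fraction information exists to
calibrate anything richer.

**Hazard calibration.** The published anchors are observed event
*fractions*, not rates: recurrence in 61.4% / 48.5% and death in 76.2% /
57.4% of the C-TACE / DEM-TACE arms. Two targets cannot identify three
hazards, so the post-recurrence hazard is fixed at $h_{rd} = 0.40$/year
(median post-recurrence survival ≈ 1.7 years, clinically plausible for
intermediate-stage HCC after failed locoregional control), and
`calibrate_hazards()` solves the remaining two rates so that the expected
observed fractions under the censoring distribution — computed from the
closed-form illness-death solution `idm_transition_probs()` integrated
over the censoring law — hit the targets exactly. The shipped defaults are
the solutions: $h_{sr} = 0.1556$, $h_{sd} = 0.0614$ (C-TACE) and
$h_{sr} = 0.0871$, $h_{sd} = 0.0327$ (DEM-TACE). These were fixed once,
from the calibration alone.

**Costs.** Stable-state cost is a two-part distribution: a point mass at
zero with probability 0.6 (any value above 0.5 forces a zero median, as
printed; 0.6 leaves a clear margin at $n = 101$) and otherwise a
log-normal whose parameters are moment-matched
(`two_part_cost_params()`) so the *overall* mean ± SD equal the published
2463 ± 6626 € (C-TACE) and 2158 ± 5067 € (DEM-TACE). Recurrence cost is a
plain log-normal matched to 12,406 ± 17,361 € and 11,972 ± 17,156 €, drawn
only for patients with an observed recurrence. A log-normal matched on
mean/SD cannot simultaneously match the published recurrence-cost medians
(it implies medians of ≈ 7,200 € rather than ≈ 4,400 €); mean/SD were
preferred because the PSA's normal cost distributions are parameterized
from them. The one-off procedure cost is not published; 3,500 € per arm is
used — a plausible Italian DRG-level tariff, equal across arms because the
source reports procedural costs did not differ.

**Seeding.** One master seed; per-arm, per-variable sub-stream seeds are
derived from it deterministically, so cohorts are byte-identical under a
fixed seed and each variable's stream is insensitive to the others.

What the generator does *not* emulate: covariate structure (no BCLC stage,
tumor burden, liver function), informative censoring, cost–survival
correlation within patient, transplant-dependent costs/hazards, or
re-treatment sessions. Tests passing on these cohorts therefore certify
the *estimators and the decision arithmetic*, not robustness to real-data
complications such as confounding or dependent censoring.

## Estimation: from patient records to an annual matrix

`kaplan_meier()` (a thin wrapper over `survival::survfit`) provides the
marginal product-limit curves; at tied event/censoring times events
precede censorings, the standard counting-process convention.

`aalen_johansen()` implements the product-integral estimator for the
illness-death model directly: at each observed transition time $t$,
the increment matrix $I + d\hat A(t)$ holds the Nelson–Aalen increments
(observed transitions divided by the at-risk count in the source state),
and $\hat P(0, t)$ is the ordered product of these factors. Each factor is
row-stochastic by construction, so conservation holds to floating-point
precision at every $t$. Patients censored at an event time are kept in the
risk set at that time; a patient whose recurrence and death coincide
passes through the recurrence state instantaneously. Under no censoring
the estimator collapses to empirical state-occupancy fractions, and with
recurrence impossible its stable-state entry is algebraically the
Kaplan–Meier estimator — both identities are asserted at $10^{-12}$ in the
test suite, alongside a cross-check against `survival::survfit`'s
multi-state (Aalen–Johansen) implementation on censored data.

`annual_matrix()` turns the fit into the per-cycle matrix the Markov
engine consumes:

* **Stable row**: the conditional product of the estimated increments
  restricted to calendar interval $(k, k+1]$. Everyone starts in stable,
  so risk sets are large and the estimate is precise.
* **Recurrence row**: estimated on the **time-since-recurrence clock** — a
  product-limit over all observed recurrence sojourns, evaluated at one
  year. The calendar-conditional alternative (the recurrence row of the
  interval product) conditions on occupancy of the recurrence state at the
  interval start; in the first cycle almost nobody has entered recurrence
  yet, the risk set is nearly empty, and the variance of that entry
  diverges logarithmically — at $n = 20{,}000$ simulated patients it
  missed the true annual exit probability by over 3 percentage points.
  Pooling sojourns identifies the homogeneous annual exit probability the
  Markov model actually needs, recovers known hazards to well under 1
  percentage point at the same $n$, and leaves the small worked examples
  (where entries coincide) unchanged.

The base case uses the single cycle-0 matrix (time-homogeneous model,
matching a decision model specified by one matrix per arm); a time-varying
mode returns one matrix per cycle, carrying the last informative matrix
forward with a warning once follow-up is exhausted — extrapolation beyond
observed follow-up has no empirical support and carrying forward is the
least-structured choice.

## Cost-utility arithmetic

`icur()` reports $\Delta C / \Delta E$ only in the trade-off quadrants.
Strict dominance cases are labelled (`"dominant"`, `"dominated"`) rather
than reported as signed ratios — a negative ICUR is ambiguous between
"cheaper and better" and "costlier and worse" — plus `"undefined"`
(equal QALYs, unequal costs) and `"equivalent"`. The label set is what the
PSA needs to count decisions consistently. `net_monetary_benefit()`
provides the threshold-based form; for a positive QALY gain, positive
incremental NMB and ICUR < WTP are the same decision, which is
property-tested.

## Probabilistic sensitivity analysis

`run_psa()` draws **all parameters simultaneously** each simulation and
re-runs the Markov model per draw for both arms (the stricter
interpretation; perturbing final outputs directly would ignore the
nonlinear map from inputs to outcomes):

* **Costs** — Normal(mean, SE), resampled until non-negative. SEs default
  to SD$/\sqrt{101}$ from the published cost moments: the uncertain
  quantity is the *mean* state cost entering the model, so the sampling
  distribution of the mean is the defensible scale.
* **Utilities** — Beta with method-of-moments shapes
  ($\alpha = \mu(\mu(1-\mu)/se^2 - 1)$). Utility SEs are published
  nowhere; the default is 10% of the mean, config-overridable and flagged
  as an assumption.
* **Transition rows** — Dirichlet with concentration
  $\text{ESS} \times \text{base row}$, ESS defaulting to the arm size
  (101): the concentration should reflect the amount of data behind the
  estimated matrix. Structural zeros are excluded from sampling so
  impossible transitions never acquire mass; degenerate rows and
  $\text{ESS} = \infty$ return the base row exactly, which makes the
  all-SEs-zero PSA reproduce the deterministic base case to $10^{-9}$ (a
  wired-in consistency test).

Transplant proportions are held fixed in the PSA: they are structural
weights estimated from near-complete follow-up, and no uncertainty
specification for them is available.

Outputs are the incremental cloud on the cost-effectiveness plane, the
quadrant counts, the fraction of draws with positive incremental NMB at
the WTP, and the acceptability curve on a 0–100,000 € grid in 1,000 €
steps (the curve is reported as computed; monotonicity is not assumed).
With 10,000 draws the Monte-Carlo SE of a CE fraction is at most 0.5
percentage points.

## Defaults, units and numerical choices

| Parameter | Default | Units | Why |
|---|---|---|---|
| `discount_rate` | 0 | fraction/year | mirrors an undiscounted source analysis; 3–3.5% is one config line away |
| `horizon_cycles` | 40 | 1-year cycles | non-binding lifetime cap (cohort extinct earlier) |
| `half_cycle` | off | — | start-of-cycle convention as base case; correction optional |
| `wtp` | 25,000 | €/QALY | common EU benchmark used in the source figures |
| utilities (stable/recurrence/transplant) | 0.72 / 0.50 / 0.82 | utility/year | placeholders in the published range for palliative HCC, labelled as such in the config |
| `p_transplant` | 0.139 / 0.228 | proportion | observed per-arm transplant shares |
| `ess` | 101 | patients | Dirichlet concentration = data behind the matrix |
| `n_sims` | 10,000 | draws | CE-fraction MC error ≤ 0.5 pp |

Numerical details: transition matrices are validated row-stochastic at
$10^{-12}$ after stripping floating-point drift from long products (row
sums are exactly 1 in exact arithmetic); the Markov engine rejects
matrices off the simplex at $10^{-8}$; beta moment-matching reports the
feasibility bound ($se^2 < \mu(1-\mu)$) when violated; empty annual risk
sets carry the previous matrix forward with a warning rather than emitting
NaNs. All tabular output is CSV (comma-delimited, UTF-8, 6 significant
digits); "Euro 2020" is a label — no inflation adjustment is performed.

## Problem sizes used in the test suite

Distributional checks run at 10,000 patients or draws; the
hazard-recovery check runs at 20,000 patients per arm (estimates within 1
percentage point of the closed-form illness-death solution); the
enumeration oracle runs exhaustively on dozens of censoring-free cohorts
of ≤ 20 subjects; the full-size PSA check runs 10,000 draws twice under
one seed. These sizes make Monte-Carlo noise small relative to the stated
tolerances while keeping the whole suite under a minute.

## Known limitations

* The published QALY totals (0.523 / 0.371 in the results table; a
  conflicting 0.452 / 0.318 appears in the accompanying text) and cost
  totals depend on utility, cost and transition inputs from an
  unavailable supplement, so they are **not** reproduction targets; the
  package reproduces the *arithmetic relations* among the published
  numbers (ICUR and cost/QALY ratios to within rounding of their printed
  inputs) and otherwise computes its own results from synthetic data.
* The time-homogeneous base case assumes constant annual transition
  probabilities; the time-varying mode relaxes this within follow-up but
  extrapolates by carry-forward.
* The recurrence row pools sojourns across entry times (semi-Markov
  homogeneity); a calendar-time-inhomogeneous recurrence process would
  violate this silently.
* Costs and event times are drawn independently within patient; real
  follow-up costs correlate with survival duration and terminal care.
* Two arms only; no efficiency frontier for ≥ 3 comparators, no
  value-of-information analysis, no tornado diagrams.
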