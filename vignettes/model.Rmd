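---
title: "A one-year decision-tree model of structured suicide risk assessment in SMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-year decision-tree model of structured suicide risk assessment in SMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxmiscea)
```

## The model

Patients with severe mental illness (SMI) present to secondary mental
health care and are assessed for suicide risk, either with the OxMIS
prediction tool or by unstructured clinical judgment. Assessment assigns
each patient to high-risk management (HRM; four additional clinical
reviews plus a multidisciplinary psychosocial assessment, £1,615) or
low-risk management (LRM; no additional cost). Over the following year a
patient either dies by suicide or remains in care. The model is a
four-path decision tree per strategy:

| quantity | base case | meaning |
|---|---|---|
| `p_high_oxmis` | 0.25 | HRM assignment under OxMIS = 1 − specificity (0.75) |
| `p_high_clinical` | 0.50 | HRM assignment under clinical judgment |
| `p_suicide_high` | 0.017 | annual risk in the OxMIS high-risk stratum, pre-treatment |
| `p_suicide_overall` | 0.008 | 12-month suicide incidence in SMI |
| `hrm_risk_reduction` | 0.10 | relative risk reduction conferred by HRM |
| `cost_oxmis` / `cost_clinical_assessment` | £57 / £253 | assessment costs |
| `cost_hrm` / `cost_lrm` | £1,615 / £0 | management costs |
| `cost_suicide` | £260 | direct emergency/health cost of a suicide |
| `utility_smi` | 0.77 | annual utility living with SMI |
| `utility_decrement_hrm` | 0.05 | treatment disutility in the HRM branch |

Expected per-patient cost is
`assessment + p_hrm·cost_hrm + (1 − p_hrm)·cost_lrm + p_suicide·cost_suicide`,
and expected QALYs weight each branch by
`(1 − p_die)·u + p_die·u/2`: decedents accrue half the branch utility,
the convention that suicide occurs at the six-month midpoint of the
one-year horizon. Death by other causes is excluded (it would be equal in
both arms), the suicide cost is charged once at the event, and there is no
discounting on a one-year horizon. Non-fatal self-harm costs are out of
scope.

```{r base-case}
params <- load_parameters()
oxmis <- evaluate_strategy(make_oxmis_strategy(params))
clinical <- evaluate_strategy(make_clinical_strategy(params))
incremental(oxmis, clinical)
```

## Design choices where the model was open

**The OxMIS low-risk branch risk is derived, not assumed.** Only the
high-stratum risk (0.017) and the population incidence (0.008) are given;
we close the model by solving
`p_high·p_high_risk + (1 − p_high)·p_low = incidence`, giving
`p_low = 0.005` at base case. This preserves the 0.8% cohort incidence
exactly, and `derive_p_suicide_low()` refuses parameter combinations where
the solution leaves `[0, p_suicide_high]`.

**Clinical flagging is uninformative for risk.** Both clinical branches
start at the population incidence before the HRM treatment effect,
consistent with the evidence that unstructured clinical ratings
discriminate poorly; the HRM branch then receives the 10% relative
reduction. This convention reproduces the published clinical-arm mean of
£1,062.

**Decedents keep their branch utility.** The HRM treatment decrement
applies to a decedent's half-year in the HRM branch. This is the simplest
reading of "QALYs halved at the midpoint", and the microsimulation uses
the identical rule so the two routes agree in expectation. Under these
conventions the base-case QALY gain is ≈ 0.0125 (rounding to the published
0.01) and the ICER ≈ −£48k/QALY. The originally reported mean ICER
(−£58,109) implies a QALY gain of ≈ 0.0103, which cannot be reproduced
from the printed inputs under any branch-risk/utility convention we could
identify; the dominance classification (cheaper, more effective) is the
robust, reproducible statement, and it holds here.

**Sequential scenario reconstruction.** For clinical assessment followed
by OxMIS, both assessment costs are charged (£310) and OxMIS updates the
probability that a clinical high-risk call is a true positive from 0.5 to
0.69 via the likelihood ratio (`posttest_probability()` works on the odds
scale and is exactly invertible). How that post-test probability maps to
HRM entry is not specified; we set `p_hrm = 1 − 0.69 = 0.31`, the unique
simple mapping that reproduces the published £250 per-person saving of
this scenario. This is a *reconstruction*, flagged as such, and the
post-test probability (or a sensitivity/specificity pair) is overridable.

**HRM cost is the printed aggregate.** £1,615 is used as given; its stated
components (4 × £343 + £253 = £1,625) do not sum to it, and we do not
resolve the £10 discrepancy.

## Sensitivity analysis calibration

Six parameters are varied, as in the original analysis: the OxMIS
assessment cost, HRM cost, suicide cost, HRM utility decrement, the OxMIS
high-risk assignment probability, and the high-stratum suicide risk. The
source's per-parameter standard deviations are not recoverable, so the
probabilistic sensitivity analysis defaults to **sd = 20% of each mean**
(overridable per parameter), with beta distributions for quantities on
[0, 1] and gamma for costs, moment-matched in closed form
(`moment_match()`). Joint draws that violate a model invariant — e.g. a
drawn high-stratum risk below the overall incidence, or an infeasible
derived low-branch risk — are rejected and resampled (capped at 10^6
attempts), and the rejection count is reported. Because the dispersions
are assumptions, the published probabilistic proportions (99.96%
cost-saving; 61% dominant; 35% cheaper-but-less-effective; 2.4% inferior)
are calibration context, not quantities this package claims to reproduce;
the package's own checks are structural (quadrant proportions partition
the draws, degenerate distributions collapse onto the base case, fixed
seeds reproduce results bit-for-bit).

```{r psa}
psa <- psa_run(params, n = 2000, seed = 1)
psa
```

One-way analysis defaults to ±25% of base case per parameter (the
original ranges are likewise unpublished), re-evaluating both arms at each
end and sorting by ICER span. Under these ranges the HRM utility
decrement, not the OxMIS flag probability, has the widest ICER span: the
QALY gain (≈ 0.0125) sits in the ICER's denominator and responds strongly
to the decrement, which enters the clinical arm with twice the weight
(50% vs 25% HRM assignment). The original report named the OxMIS flag
probability as most influential, which suggests its (unpublished) range
for the decrement was relatively narrow; with uniform relative ranges
that ordering does not emerge, though the *least* influential parameter
(the suicide cost) agrees. We deliberately do not tune the ranges to
recover the published ordering.

```{r tornado}
one_way_sa(params)[, c("parameter", "icer_at_low", "icer_at_high", "span")]
```

## The microsimulation: generator and oracle

`simulate_cohort()` draws each patient's HRM flag
(Bernoulli `p_hrm`) and suicide outcome (Bernoulli branch risk after the
treatment effect) and accrues the exact per-patient payoffs of the tree,
including the midpoint QALY rule. It emulates assessment-to-outcome
trajectories *as the cohort model defines them*: it does not add
individual heterogeneity in risk or utility, within-year event timing, or
non-fatal self-harm, so agreement between simulation and tree validates
the engine's arithmetic and conventions, not the model's fidelity to real
patients. At the default n = 200,000 the 3-standard-error band is about
±£1.5 on mean cost, tight enough to detect payoff or probability wiring
errors; tests check both arms and the sequential arm at that size, which
runs in well under a second per arm.

```{r microsim}
spec <- make_oxmis_strategy(params)
s <- summarize_cohort(simulate_cohort(spec, n = 200000, seed = 7))
c(simulated = s$expected_cost, analytic = evaluate_strategy(spec)$expected_cost)
```

A second, fully independent check enumerates the four root-to-leaf paths
with flat arithmetic in the test suite and requires agreement with the
tree engine to 10^-12 on randomized valid parameter sets.

## Numerical notes and limitations

* All computations are closed-form expectations; no optimisation or
  iteration is involved. Agreement tolerances are 10^-12 (analytic
  routes) and 3 Monte Carlo standard errors (simulation routes).
* The ICER is reported as `NA` when the QALY difference is exactly zero,
  and always carries its cost-effectiveness-plane quadrant, since a bare
  negative ICER conflates dominant and dominated positions.
* Probabilities are treated as annual risks on the one-year horizon; the
  model deliberately refuses `time_horizon_years != 1` rather than
  silently extrapolating — multi-year (Markov) dynamics, discounting and
  competing mortality are out of scope.
* The willingness-to-pay threshold defaults to £20,000/QALY (the
  conventional lower NICE bound) and is configurable; results reported
  here do not depend on it except through the NMB and CEAC.
* Costs are used exactly as printed in their source years; no inflation
  indexing is performed.
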