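# oxmiscea

Decision-tree cost-effectiveness model for structured suicide risk
assessment in severe mental illness (SMI).

People with schizophrenia-spectrum disorders or bipolar disorder have a
substantially elevated suicide risk, and risk assessment linked to
preventative management is a core part of secondary mental health care.
This package implements a one-year decision-analytic model, from the NHS
perspective, comparing two ways of triaging patients into high-risk
management (HRM) versus low-risk management (LRM):

* **OxMIS arm** — assessment with the Oxford Mental Illness and Suicide
  tool (£57 per assessment); 25% of patients are flagged high-risk (one
  minus the tool's 75% specificity) and enter HRM (£1,615) at an annual
  suicide risk of 1.7% before treatment effect;
* **clinical arm** — unstructured psychosocial assessment (£253); 50% of
  patients are judged high-risk, and clinical flagging is treated as
  uninformative for risk, so both branches carry the population 12-month
  incidence of 0.8%.

HRM confers a conservative 10% relative reduction in suicide risk. The
OxMIS low-risk branch risk is solved from the mixture constraint
`p_high × p_high_risk + (1 − p_high) × p_low = incidence`
(0.25 × 0.017 + 0.75 × p_low = 0.008 ⇒ p_low = 0.005), so the cohort
reproduces the overall incidence. Survivors accrue the branch utility
(0.77 with SMI, minus a 0.05 HRM treatment decrement) for the year;
decedents accrue half of it (suicide at the six-month midpoint), and a
suicide costs £260 in immediate emergency and health services. For two
strategies the package reports the incremental cost ΔC, incremental QALYs
ΔE, the ICER ΔC/ΔE with its cost-effectiveness-plane quadrant, and the net
monetary benefit λ·ΔE − ΔC at a willingness-to-pay λ (default
£20,000/QALY).

It also provides:

* a **sequential scenario** (clinical assessment followed by OxMIS) in
  which OxMIS updates the probability that a clinical high-risk call is a
  true positive from 0.5 to 0.69 by likelihood-ratio updating
  (post-test odds = pre-test odds × LR+), with HRM entry reconstructed as
  `1 − posttest`;
* **one-way (tornado) and probabilistic sensitivity analysis** — beta
  distributions for probabilities and the utility decrement, gamma for
  costs, moment-matched to a mean and standard deviation — with
  cost-effectiveness plane points and acceptability curves (CEAC);
* a **patient-level microsimulation** that pushes individual patients
  through the same tree and cross-validates the analytic expectations.

## Worked example

```r
library(oxmiscea)

params <- load_parameters()                 # packaged base case
oxmis    <- evaluate_strategy(make_oxmis_strategy(params))
clinical <- evaluate_strategy(make_clinical_strategy(params))
oxmis
#> Strategy 'oxmis': expected cost £462.72, expected QALYs 0.75468, annual suicide probability 0.00758
clinical
#> Strategy 'clinical': expected cost £1062.48, expected QALYs 0.74216, annual suicide probability 0.00760

incremental(oxmis, clinical)
#> Incremental analysis: oxmis vs clinical
#>   delta cost:  £-599.76
#>   delta QALYs: 0.01252
#>   ICER: £-47922 per QALY (quadrant SE)
#>   classification: intervention dominant
#>   NMB at £20000/QALY: £850.06
```

The rounded headline values are £463 per patient assessed with OxMIS
versus £1,062 with clinical judgment alone — a saving of £599 per person
with a 0.01 QALY gain, so OxMIS *dominates* (cheaper and more effective;
the negative ICER is a saving per QALY gained, reported with its SE
quadrant). The sequential scenario saves £250 per person:

```r
run_scenario(posttest = 0.69)$headline$saving_per_patient
#> [1] 250
```

Sensitivity and microsimulation:

```r
run_psa(n = 10000, seed = 1)        # Monte Carlo PSA + CEAC
run_tornado()                       # one-way analysis, sorted by ICER span
run_microsim(n = 200000, seed = 1)  # simulated vs analytic means
```

A thin command-line wrapper with the same subcommands (`base-case`,
`scenario`, `psa`, `tornado`, `microsim`) is installed at
`system.file("cli", "oxmiscea.R", package = "oxmiscea")`.

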