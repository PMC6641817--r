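---
title: "A decision-tree cohort model of preterm neonatal mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cohort model of preterm neonatal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretermcascade)
```

## The model

`pretermcascade` implements a deterministic (nonstochastic) decision-tree
cohort model of neonatal mortality among preterm births, with three ordered
levels of care — home, clinic, hospital — and six mutually exclusive
cause-of-death channels ("subconditions"): respiratory distress syndrome
(RDS), intraventricular hemorrhage (IVH), necrotizing enterocolitis (NEC),
sepsis, birth asphyxia, and low birth weight with no other condition
(`LBW_only`). Each subcondition carries a prevalence among preterm births
and a case-fatality rate (CFR) in the absence of any intervention.
Prevalences partition the cohort: every neonate is in exactly one channel,
and strata case counts always sum to the number of preterm births.

The expected deaths in a stratum (subcondition × setting of care) are

```
deaths = n_cases × untreated_cfr × residual(coverage, efficacy)
```

where the residual factor collects the interventions that reach the
stratum. Coverage follows the *penetration–utilization–efficacy* cascade:

* **penetration** — the probability the intervention is available at the
  setting;
* **utilization** — the probability it is used appropriately when
  available;
* **efficacy** — the relative reduction in mortality when received,
  treated as setting-independent (diagnostics are the exception: their
  "efficacy" is the probability the condition is correctly identified, and
  it does vary by setting).

Treatments that presuppose a diagnosis (surfactant, oxygen, CPAP, positive
pressure ventilation, empirical sepsis antibiotics, warmers) reach only the
diagnosed fraction of a stratum. Diagnosis at a setting is itself a
cascade: `penetration × utilization × diagnostic efficacy` of the
corresponding gate. Universal newborn-care profiles (drying and
stimulation, cord care, breastfeeding, kangaroo mother care) are ungated.

### How interventions combine

Ungated interventions combine as independent multiplicative reductions of
residual risk: each contributes a factor `1 − coverage × efficacy`. Gated
interventions hang off a single diagnosis event per case, so their receipt
probabilities are correlated through that shared node. The engine therefore
mixes over the diagnosis branch rather than multiplying through:

```
residual = Π_ungated (1 − cov_i e_i) × Π_gates [ (1 − d_g) + d_g Π_i∈g (1 − pen_i util_i e_i) ]
```

with `d_g` the diagnosis probability of gate `g` at the stratum's setting.
This is the exact expectation of the individual-level tree (diagnose once,
then each treatment's availability and use are independent Bernoulli
events), and it is what makes the deterministic engine agree with the
microsimulation oracle to Monte Carlo precision. The simpler "flat"
product `Π (1 − d·pen·util·e)` understates deaths whenever two or more
treatments share a gate, because it implicitly re-diagnoses the case for
each treatment.

### Antenatal prophylaxis

Antenatal corticosteroids are given to mothers in whom imminent preterm
birth is recognised. Recognition happens where the mother is seen, so
antenatal-timing profiles are weighted by the antenatal-care location mix
(30/65/5 home/clinic/hospital in the bundled set) rather than the delivery
mix; the cascade is `Σ_a mix_a × d_preterm_labor(a) × pen(a) × util(a)`,
applied uniformly to every delivery stratum of the targeted subconditions.
The parameter `anc_weighting = "delivery"` switches to delivery-mix
weighting for sensitivity analysis. When a scenario enables preterm-labor
referral, mothers diagnosed at their antenatal setting deliver at the
destination instead, and receive the drug at the destination's
penetration/utilization — this is what gives the "diagnosis + transfer +
corticosteroids" scenarios their synergy.

### Referral transfer

Two referral mechanisms exist, both acting only on *diagnosed* cases and
both off (probability 0) at current care, since no baseline referral rates
are published — a documented assumption:

1. **preterm-labor transfer** relocates the delivery itself, so every
   subcondition stratum is affected;
2. **subcondition-gate transfer** moves the diagnosed fraction of one
   stratum (e.g. recognised sepsis) from its setting of care to the
   destination (hospital by default).

Transferred cases use destination-setting penetration and utilization for
all subsequent treatments, and they count as already diagnosed for the gate
that triggered the referral. The engine splits each affected stratum into
undiagnosed stayers, diagnosed stayers, and diagnosed movers, which keeps
the arithmetic exactly equal to the individual-level tree. Case counts are
conserved at every stage.

## Parameters

The bundled parameter set (`baseline_parameters()`,
`inst/extdata/baseline_ssa_2015.yaml`) describes sub-Saharan Africa in
2015: 3,988,000 preterm births, delivery mix 50/35/15, antenatal-care mix
30/65/5, the six subcondition prevalence/CFR pairs, per-setting diagnostic
cascades for seven gates, and per-setting penetration/utilization plus
per-target efficacy for eleven interventions. All proportions are stored on
the 0–1 scale internally; config files declare `units: percent` or
`units: proportion` explicitly. Two entries are modelling assumptions
rather than published cells, and are flagged as such in the fixture:

* the **birth-asphyxia recognition gate** reuses the RDS
  clinical-recognition profile (no separate asphyxia diagnostic row is
  published, but the asphyxia scenarios require one);
* **baseline transfer probabilities are zero** (see above).

One further structural choice: kangaroo mother care applies only to the
`LBW_only` stratum — thermal care helps stable small neonates, not those
dying of RDS or sepsis — and likewise warmers and the low-birth-weight
efficacy of breastfeeding.

## Scenarios

A scenario is data, not code: a named set of levers (intervention profiles
and diagnostic gates, each with the settings they apply in, plus optional
referral gates and a delivery-mix override), stored in
`inst/extdata/scenarios_ssa_2015.yaml` and loaded by `scenario_library()`.
Every scenario is evaluated at two improvement levels:

* **incremental change** — penetration and utilization +20 percentage
  points, capped at 98%. The additive reading is the default because
  several profiles (cord care) have zero baseline coverage, and a relative
  ×1.2 reading could never move them; `incremental_mode = "relative"`
  preserves the alternative for sensitivity checks.
* **universal coverage** — penetration and utilization set to 98% in the
  scenario's settings; settings the scenario does not list (e.g.
  surfactant outside hospitals) stay at baseline.

Efficacies are never changed. Referral probabilities, when a scenario
enables transfer, take the same boosted level (0.20 incremental, 0.98
universal) since no separate referral figures are published. Scenario
transforms are pure: the input parameter set is never mutated, and the
universal transform is idempotent.

The library's gate mappings follow the scenario wording: scenarios phrased
as "increased diagnosis …" raise the named gate (and usually referral);
treatment-only scenarios (surfactant alone, oxygen/CPAP alone, antibiotics
alone) leave recognition at current care. The one exception is the
corticosteroid scenario, which raises the hospital preterm-labor gate with
the drug, because the drug is unusable without the recognition step and the
scenario's published effect size is only attainable with it.

Each scenario group is scored on its own subcondition set — direct
complications (RDS, IVH, NEC) in one group, sepsis/asphyxia/low birth
weight in the other — against the shared current-care baseline:

```{r scenarios, eval = FALSE}
params <- baseline_parameters()
suite <- run_scenario_suite(params)
build_report(suite)
```

Reporting rounds death counts to the nearest 100 (half-up on ties) and
prints percent reductions to one decimal; percents are computed from
unrounded totals so they are stable under the rounding.

## The synthetic generator and the microsimulation oracle

`random_parameter_set()` draws fully valid random parameterizations of the
model's fixed structure: every penetration, utilization, efficacy, CFR,
prevalence, and location-mix value is sampled from configurable intervals,
prevalences and mixes are renormalised to sum to one, and sampled values
are rounded to six decimals so YAML round-trips are bit-exact. The
generator holds the model's *structure* fixed (six subconditions, seven
gates, eleven interventions with their gating and timing), because the
gating map is part of the model, not of the data.

`microsim_oracle()` is the package's independent correctness check: it
simulates individual neonates through the same tree — antenatal location,
preterm-labor recognition, referral, prophylaxis receipt, delivery
location, subcondition, recognition, referral, per-intervention
availability and use, death — with every stage a separate Bernoulli or
categorical draw. It shares none of the engine's expected-value
arithmetic. Uniform variates are consumed in a fixed stage order, so two
runs under one seed are coupled by common random numbers; this makes
stochastic monotonicity checks feasible at moderate cohort sizes. The
headline property, exercised in the test suite, is agreement between
engine and oracle within 3 binomial standard errors at 2,000,000 simulated
neonates across random parameter sets and scenario transforms at both
improvement levels.

What the synthetic machinery does *not* emulate: correlated subconditions
(real neonates can have RDS and sepsis at once), gestational-age structure,
time dynamics, adverse effects of over-treatment, or uncertainty in the
parameters themselves. Passing tests therefore demonstrate that the
cascade arithmetic is an exact expectation of the stated tree under the
stated parameters — not that the tree or the parameters are an accurate
description of any real health system.

## Numerical choices

* All arithmetic is double-precision and deterministic; identical inputs
  give bit-identical results. No iteration, no tolerances inside the
  engine itself.
* Location mixes must sum to 1 within 1e-9; mortality-total consistency is
  checked at 1e-6 relative.
* Rounding to the nearest 100 is half-up (`floor(x/100 + 0.5) × 100`),
  applied only in reporting; all comparisons between scenarios use
  unrounded expectations.
* Degenerate inputs are handled by construction: zero prevalence yields
  empty strata, zero coverage yields the untreated CFR, full coverage with
  full efficacy yields zero deaths, and a baseline of zero deaths makes
  percent-prevented an explicit error rather than NaN.
* Test problem sizes: property tests use 100–200 random parameter sets for
  validation/monotonicity and 2,000,000 simulated neonates per oracle
  comparison — large enough that 3 standard errors is a fraction of a
  percent of the cohort, small enough that the whole suite runs in a few
  minutes on one CPU.

## Known limitations

The printed current-care parameterization does not, under this cascade
structure, reproduce every published headline number; the baseline for the
direct-complication group and the oxygen/CPAP and corticosteroid scenario
effects land close (within a few percent), while the sepsis/asphyxia/LBW
baseline computes materially higher than the published figure. The
per-stratum trace (`run_cohort(p, trace = TRUE)`) exposes every diagnosis
probability, coverage, and residual factor precisely so such gaps can be
localized to a structural choice (gating, referral level, combination
rule, incremental reading) rather than guessed at. The model also shares
the structural simplifications of its class: single-condition neonates, a
single aggregate region, gold-standard efficacy wherever an intervention
is delivered, and no uncertainty quantification.
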