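---
title: "Modelling quality and cost in postnatal care redesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling quality and cost in postnatal care redesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pram)
```

## The decision problem

Routine postnatal care — the universal maternity service for mothers and
babies in the days after birth, delivered first in hospital and then in the
community — is under sustained pressure to cut costs while improving
quality. Redesign proposals typically reallocate resources along the
pathway (shorter in-patient stays, more community contacts) and between
groups of mothers with different levels of need, but the quality and
financial consequences of a whole *package* of changes are rarely assessed
together. This package implements a decision-support model combining
multicriteria decision analysis (MCDA) with the programme budgeting and
marginal analysis (PBMA) perspective: candidate service options are scored
against explicit, weighted quality criteria and costed along the same
pathway description, so the trade-offs a redesign implies are explicit and
debatable rather than implicit.

The model works at the service-planning level, not at the point of care.
Demand is split into four broad acuity categories of mother-and-baby dyads
(`0a`, `0b`, `1` and the merged `2&3`; categories 2 and 3 are combined
because very few dyads fall in 3). The category list is user-extensible.
One caveat inherited from the source material: the published definitions
of `0a` and `0b` carry identical wording (almost certainly a typesetting
slip), and rather than invent a distinction the default fixture reproduces
the wording as published.

## The quality model

A service option is described by *design parameters* — controllable levers
such as length of stay in hours, regular ward staff-hours per case,
dedicated feeding/parenting support hours, and counts and durations of
community contacts. Each parameter $i$ has a *maximum beneficial value*
$z_i > 0$: the level beyond which no further quality benefit accrues. An
*impact matrix* $q(i, j)$ encodes the judged contribution of parameter $i$
to quality domain $j$; the five domains are the Institute of Medicine set
(safe, effective, timely, equitable, person-centred) interpreted for
postnatal care. Domain scores are linear in the attainment ratios and
normalised so that full provision scores 100:

$$ s_j \;=\; \frac{100\,\sum_{i=1}^{n} q(i,j)\; x_i / z_i}{\sum_{i=1}^{n} q(i,j)} $$

with $x_i$ the option's value of parameter $i$. The aggregate quality
score is the weighted sum $\sum_j w_j s_j$ over domains, with weights on
the unit simplex. The default weight set (safe 0.50, effective 0.30,
timely 0.05, equitable 0.05, person-centred 0.10) reflects a stakeholder
consensus in which safety and effectiveness dominate but every domain
retains non-zero representation.

Three numerical choices deserve note.

* **Capping.** $z_i$ is a *maximum beneficial* value, so the attainment
  ratio is capped: $r_i = \min(x_i/z_i, 1)$. Without the cap,
  over-provision of one lever would buy unbounded quality credit, which
  contradicts the saturation interpretation of $z_i$. Whether the original
  spreadsheet tool capped is not documented, so the linear uncapped model
  remains available behind `cap = FALSE` for exploration; all defaults
  cap.
* **Negative impacts.** The evidence base includes harms (early discharge
  can harm safety unless skilled community care backs it up). Negative
  $q(i,j)$ entries are accepted provided each domain's column sum stays
  positive (the normalising denominator); validation then warns, because
  with mixed signs the 0–100 bounds no longer hold. The shipped fixture
  matrix is non-negative and encodes the discharge/community interplay
  qualitatively instead: ward staffing and home visits carry the largest
  safety impacts, so cutting the hospital side without strengthening the
  community side lowers the safety score.
* **Tolerances.** Equality assertions on weights and mixes use an
  absolute tolerance of 1e-9; scores are validated against brute-force
  summation to 1e-12 in the test suite.

A service-level aggregate across categories, where requested, is the
demand-weighted mean of per-category aggregates (weights proportional to
annual births). That is reporting convenience, not part of the scoring
model, which is strictly per category.

## The cost model

Hospital cost per case is split into a *staff* component (regular ward
staff-hours by grade at hourly rates, plus dedicated feeding/parenting
hours priced at a configurable grade, default maternity care assistant —
the role's pay band is not documented) and a *bed/infrastructure*
component (stay in bed-days times a bed-day rate). The split matters
because the evidence suggests quality tracks staff-hours input more than
bare length of stay, so a redesign can shorten stays (releasing bed cost)
while protecting staff contact. Community cost sums each contact's staff
time — duration plus travel for home visits, no travel for clinic and
phone contacts — at the grade's rate, plus a per-contact clinic overhead.
Phone contacts are costed as pure staff time; whether the original tool
costed them at all is not documented, and duration-times-rate is the
conservative choice. Mileage, discounting and capital planning are out of
scope. Currency is abstract; annual figures are per-case figures times
annual births, so cost is exactly linear in demand and exactly additive
across its three components (both are asserted as test invariants).

## The acuity transition sub-model

Acuity falls during the postnatal stay, so the case mix discharged into
the community is lighter than the admission mix, and the more so the
longer the stay. The original sub-model was fitted by regression on a
workforce-planning dataset that is not available, so the functional form
here is an implementation choice, chosen for interpretability and a free
closed form: each category's mass transfers to the adjacent lower-acuity
category at a constant per-hour rate (the lowest category absorbs), i.e.
the linear system $\dot p = Ap$ with a bidiagonal generator, solved with
the matrix exponential. The form guarantees the properties the
description demands — the output stays on the simplex, zero stay is the
identity, the high-acuity share declines monotonically with stay — and
the implementation is verified against an independent 0.1 h-step
mass-transfer simulation to 1e-3. All rates are user-configurable
(`transition.csv`), and the sub-model is optional: when transition
parameters are passed to `annual_cost()`, community demand is
redistributed to the discharge mix (using the demand-weighted mean stay,
since the sub-model operates at whole-service level) while hospital costs
always follow admission demand; by default it is not applied.

## Option comparison and the equity plane

`compare_options()` recomputes everything for both options at call time —
there is no cached state to drift — and reports per-category domain
deltas, aggregate deltas, per-case and annual cost deltas, and an
equity-impact-plane quadrant per category: `win_win` when quality rises
and cost falls, `win_lose`, `lose_win`, `lose_lose`, and `neutral` when
either delta is exactly zero (the plane's boundary behaviour is not
defined in the source material; mapping ties to a quadrant would
overstate the evidence). The cost axis is annual by default, with
per-case deltas reported alongside.

## Sensitivity analysis

Weighting is the most contentious input, so the first-line sensitivity
analysis perturbs one domain weight at a time by ±0.1 and ±0.2 (defaults;
any set and deltas can be given), renormalising the remaining weights
proportionally so the vector still sums to 1, and fully recomputes the
comparison at each weighting. A category's verdict is flagged *robust*
when the sign of its aggregate quality delta is unchanged across the
baseline and every retained perturbation. Because the aggregate is a
convex combination of domain deltas, same-signed domain deltas make
robustness a theorem rather than an observation; the test suite asserts
exactly that property. Perturbations that would push a weight outside
[0, 1] are skipped with a warning rather than failing the sweep.
One-way design-parameter sweeps (`parameter_sweep()`) modify the
underlying pathway description — scaling contact counts or staff-hours
proportionally where the parameter aggregates several fields — and
recompute every row from scratch. Probabilistic (Monte Carlo) uncertainty
propagation is deliberately excluded; deterministic sweeps are the
documented extension point.

## The fixture generator and what it does (not) show

`generate_fixture()` writes a complete illustrative bundle. The site data
behind the original application were never published, so Option A's
baselines are drawn, under the supplied seed, from ranges a UK service
planner would recognise: annual births 1500–2500 / 1000–2000 / 800–1500 /
150–400 across the four categories (a mid-size trust of roughly 5000
births a year); stays of 18–30 / 24–42 / 42–60 / 60–96 hours (most
mothers out within 48 h, longer for higher acuity); midwife plus
maternity-care-assistant ward hours rising with acuity; 1–5 home visits
of 40 minutes plus 20 minutes travel; one 10-minute phone contact per
pathway. Unit costs are round NHS-scale figures: midwife 45/h, maternity
care assistant 25/h, bed-day 400, clinic overhead 10. Option B is then
*derived* from A by exactly the four-item redesign package — 20% shorter
stays in every category, 10% less regular ward staffing with dedicated
feeding/parenting hours increased (+0.5 h/case), one extra home visit for
every category and two for `2&3`, and a new 30-minute feeding and
parenting clinic contact for every category, supplementing rather than
replacing a visit. The impact matrix magnitudes are synthetic and
documented as such; the acuity decay rates (0, 0.01, 0.02, 0.03 per hour,
lowest to highest) are likewise illustrative.

What passing tests on this fixture demonstrate is therefore the
*machinery* — normalisation, additivity, determinism, the redesign
derivation, the convexity of robustness — not any empirical claim about a
real service. Real applications replace the impact matrix, weights, unit
costs and pathway tables with locally elicited and audited values; the
bundle files are plain CSV precisely so workshop participants can inspect
and challenge every number.

## Worked example

```{r example}
dir <- tempfile()
bundle <- generate_fixture(dir, seed = 1)
bundle
cmp <- compare_options("A", "B", bundle)
summary(cmp)
suppressWarnings(weight_sweep("A", "B", bundle))
```

(The suppressed warning is the sweep skipping the person-centred −0.2
perturbation, which would take that weight below zero.) Problem sizes
throughout the package's tests are deliberately small — four categories,
six parameters, five domains — matching the scale at which this class of
deliberative model is actually used; nothing in the implementation is
specific to those sizes.

## Known limitations

* The acuity sub-model's exponential form is an interpretable stand-in
  for a site-fitted regression; its rates must be locally calibrated
  before any quantitative use.
* Scores are relative, not utilities: 100 is "every lever at its judged
  saturation point", an ideal-world anchor, so cross-site score
  comparisons are only meaningful under a shared impact matrix and `z`
  values.
* With capping on, the model is piecewise linear; one-way sweeps that
  cross `z_i` show a kink, which is intended behaviour.
* No Monte Carlo uncertainty propagation, no multi-option Pareto search,
  no elicitation support: the package assesses options it is given.
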