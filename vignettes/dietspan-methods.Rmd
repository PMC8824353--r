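---
title: "dietspan: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietspan: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietspan)
```

## The model

`dietspan` estimates how a sustained change of diet alters remaining life
expectancy (LE). The machinery is a period life table whose age-specific
mortality rates are multiplied by the hazard ratio (HR) associated with the
diet change:

1. **Baseline LE.** For a sex/region stratum, single-year all-cause mortality
   rates \(m_a\) give annual death probabilities
   \(q_a = m_a / (1 + 0.5\,m_a)\) (deaths uniform within the year), a
   survivorship curve, and remaining LE at any age — conditional on survival
   to that age.
2. **The diet change as a hazard multiplier.** Each of 14 food groups is an
   independent multiplicative protective or risk factor. A group's
   dose–response curve gives \(\mathrm{HR}(d)\) as a function of intake
   \(d\) (g/day); changing intake from \(d_0\) to \(d_1\) contributes
   \(\mathrm{HR}(d_1)/\mathrm{HR}(d_0)\), and the combined multiplier is the
   product over groups.
3. **Time to full effect.** Risk reversal is not instantaneous. The combined
   multiplier is ramped in linearly over \(T\) years (default 10): at time
   \(t\) after the change the applied multiplier is
   \(1 + \min(t/T, 1)\,(\mathrm{HR}_{\text{full}} - 1)\).
4. **Gain.** LE under the modified rates minus LE under the unmodified rates,
   both evaluated at the change age.

### Life-table conventions

The published description of this class of models says only "standard
lifetable methodology", so the numeric conventions are pinned here:

* \(q = m/(1+0.5m)\), capped at 1 (the actuarial \(a_x = 0.5\) assumption);
* each lived year credits \(l\,(1 - 0.5q)\) person-years — survivors a full
  year, decedents half a year;
* closure at age 110 with an open terminal interval contributing \(l/m\)
  person-years (exponential tail at the terminal rate). For a constant
  hazard this closure makes the discrete table agree with the geometric
  closed form \((1 - 0.5q)/q\) to floating precision, which the tests
  exploit;
* 5-year (or any grouped) rates expand to single years piecewise-constantly
  — the minimal assumption; no graduation or smoothing is applied, so
  band-averaging the expanded rates is the identity;
* all arithmetic is double precision; only the human-readable report rounds
  (to 0.1 years).

Because exact reproduction of any published baseline LE additionally depends
on the source's own life-table conventions (terminal age, \(a_x\), grouping),
matching a specific published table is a calibration task, not a package
guarantee.

### Dose–response curves

Curves are tabulated points \((d_i, \mathrm{HR}_i)\) with 95% confidence
bands. Between points the HR is linear in dose; beyond the first/last point
it is flat. The plateau rule reflects how "optimized" intakes are defined in
this literature — at the dose where the mortality benefit plateaus — so no
extra benefit or harm is extrapolated past the tabulated range. Curves are
used only through ratios, which makes the meta-analysis' choice of reference
category irrelevant and gives two invariances the tests check: ratio
symmetry (\(\mathrm{HR}_{a\to b}\,\mathrm{HR}_{b\to a} = 1\)) and invariance
to redundant collinear points.

White meat and added plant oils are modelled as *neutral* (HR ≡ 1 at all
doses), following meta-analytic evidence of no net mortality effect; neutral
groups contribute nothing to gains, uncertainty or evidence weights.

### Ramp choices

Two details are underdetermined by the published phrase "linear increase in
effect":

* **What is ramped.** The *combined* multiplier is ramped on the HR scale,
  \(1 + f(t)(\mathrm{HR}_{\text{full}}-1)\), matching the "20% of maximum
  after 2 years" reading (linear in effect size, not log-HR). Ramping each
  group separately and then multiplying is mathematically different
  (products of ramps are not a ramp of the product) and was rejected as less
  transparent.
* **When in the year the ramp is sampled.** Discrete model years sample the
  continuous ramp at the year midpoint (\(t = a - a_0 + 0.5\)), minimising
  discretisation bias and making results bit-reproducible. With \(T=10\) the
  multiplier in the first year after a change to
  \(\mathrm{HR}_{\text{full}} = 0.8\) is therefore \(0.99\), not \(1\).

### Uncertainty interval (95% UI)

For each of 200 replicates (fixed seed), one uniform deviate per non-neutral
food group places that group's whole curve between its lower and upper band
by pointwise linear blending \(lo + u\,(hi - lo)\) — group-level, not
point-level, perturbation, preserving each curve's shape. The replicate
gains' 2.5th and 97.5th percentiles (type-7 linear interpolation between
order statistics, pinned for reproducibility) form the interval. Draws are
independent across groups and replicates; no correlation structure is
asserted because none is published. Per-group intervals draw only the focal
group, central curves elsewhere — the forest-plot semantics. The RNG
(R's Mersenne-Twister via `set.seed`), the default seed (20220208) and the
draw order (total-diet block first, then per-group blocks re-seeded at
`seed + group index`) are part of the public contract; intervals are
byte-reproducible.

### Sensitivity family

Meta-analytic HRs may be over- or under-adjusted. The transform
\(\mathrm{HR}_a = \mathrm{HR}_0 + (1-\mathrm{HR}_0)(1-m)\) for protective
ratios — with harmful ratios handled through the reciprocal so that
\(\mathrm{HR}_a(h)\,\mathrm{HR}_a(1/h) = 1\) — attenuates effects toward the
null for \(m<1\) and amplifies them for \(m>1\); \(m=1\) is the identity.
It is applied to each group's *change*-HR (the ratio for the intake change),
the quantity the published definition describes. The reported sensitivity
interval evaluates \(m = 0.5\) and \(m = 1.5\) and orders the two results,
so it brackets correctly for net-harmful changes too.

### Energy gate

Diets below 4,000 or above 16,000 kJ/day are refused ("estimates not
reported") rather than estimated; the bounds themselves pass, because the
published rule says "below"/"above". The gate is applied to both the
baseline and the target diet — both are inputs to the calculator. Energy
content is \(\sum_g \text{intake}_g \times \text{density}_g\). The shipped
density table uses typical as-consumed food-composition values, with two
entries (refined grains, fish) solved so that the preset totals reproduce
the published 8,085 / 7,850 / 7,615 kJ/day; it stands in for a full
food-composition database and is documented as such.

### Evidence quality

Each group carries a NutriGrade score (0–10; categories very low < 4 ≤ low
< 6 ≤ moderate < 8 ≤ high, boundaries belonging to the upper class). The
overall score for a scenario is the mean of the group scores weighted by
each group's absolute LE contribution *in that scenario* — the published
description does not say which stratum's contributions weight its overall
figure, so the package computes and reports the score per scenario and
leaves the choice of stratum to the user. Neutral groups carry zero weight;
added oils have no published score and are excluded (`NA`).

## The synthetic world

No mortality extract or meta-analytic HR table ships with the package; both
are *inputs*. To make the package testable offline, `make_schedule()` and
`make_curveset()` generate stand-ins:

* **Mortality**: Gompertz–Makeham, \(m_x = c + a e^{bx}\), defaults
  \(c = 5\times10^{-4}\), \(a = 3\times10^{-5}\), \(b = 0.095\), closure
  110. These give LE(20) ≈ 58.5 years, inside the 58–63 range typical of
  contemporary high-income adult schedules — chosen once so synthetic
  results sit in a realistic regime.
* **Curves**: two-point piecewise-linear curves from (0 g, HR 1) to a
  plateau at the optimized intake (protective groups) or the typical intake
  (harmful groups), with symmetric bands widening linearly from zero. The
  plateau HRs (0.78–0.88 protective, 1.04–1.12 harmful) are plausible for
  this literature but are **synthetic placeholders, not transcribed
  estimates**; their combined TW→OD multiplier (≈ 0.31) yields decade-scale
  gains at age 20, the regime published models report.

What a green test does and does not establish: the synthetic world exercises
every code path (protective and harmful arms, neutral groups, ramps, draws,
the gate) and the oracle equivalences below, but agreement with any
*published* gain requires the real external inputs; no such agreement is
claimed. Real data lack the smoothness of Gompertz–Makeham (infant
mortality, accident humps) and real CI bands are asymmetric on the log
scale; neither feature affects the engine's code paths, only its outputs.

### The cohort oracle

`cohort_oracle()` simulates individual lifetimes year by year from the same
\(q_a\), with half-year credit in the death year and an exponential tail at
closure, and returns mean ± SE. Agreement of the analytic life table with
this brute-force simulation within 3 SE at n = 200,000 — on baseline and
hazard-modified schedules — is the package's strongest correctness check,
because the two implementations share no code beyond the rate vector.

## Numerical and degenerate-input choices

* Rates of 0 are legal except at the terminal age (LE would diverge);
  certain death (\(q\) capped at 1) yields LE = 0.5 via the half-year
  credit.
* Identical baseline and target diets give a gain of exactly 0 (the
  multiplier is exactly 1; no floating residue).
* Per-group gains change one group against the *baseline* (not
  leave-one-out from the target): the forest-plot convention. Life-table
  gains are not additive across hazard factors; the total is always
  computed jointly, and on the default fixture the per-group sum deviates
  from the joint total by well under 10%.
* Degenerate CI bands collapse the uncertainty interval onto the central
  gain exactly.
* `m` outside [0.5, 1.5] is an error (the published domain), not clamped.

## Known limitations

* Morbidity, quality of life and energy-restriction effects are out of
  scope, as in the source methodology; only all-cause mortality moves.
* HRs are age-constant; adherence is all-or-nothing apart from the linear
  ramp.
* Mortality-rate uncertainty is not propagated (the UI covers HR
  uncertainty only).
* The GBD-style reader covers the common results-tool export layout, not
  every variant.

## A worked run

```{r example, eval = FALSE}
schedule <- make_schedule()                 # synthetic mortality
curves   <- make_curveset()                 # synthetic dose-response set
scenario <- diet_change_scenario(preset_diet("TW"), preset_diet("OD"),
                                 change_age = 20, region = "synthetic")
estimate_gains(scenario, schedule, curves,
               config = uncertainty_config(n_draws = 200, seed = 20220208))
```
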