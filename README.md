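# dietspan

Estimates how a sustained change of diet alters remaining life expectancy
(LE) by age, sex and region. The intended users are quantitative
epidemiologists and health-policy modellers who want a transparent,
reproducible engine behind "what would eating more legumes buy me in life
years?" questions — per food group, with uncertainty, and with an explicit
statement of the evidence quality behind the answer.

## The model

For a stratum with single-year all-cause mortality rates *m<sub>a</sub>*,
remaining LE at age *a₀* comes from a standard period life table
(*q<sub>a</sub> = m<sub>a</sub>/(1 + 0.5 m<sub>a</sub>)*, half-year credit
in the death year, open terminal interval *l/m* at age 110). A diet change
at *a₀* multiplies every rate from *a₀* on by a combined hazard ratio

> HR<sub>full</sub> = ∏<sub>g</sub> HR<sub>g</sub>(d₁,g) / HR<sub>g</sub>(d₀,g)

over 14 food groups, where each group's HR(d) is a tabulated dose–response
curve (linear between points, flat beyond them). The multiplier is phased
in linearly over *T* years (default 10): at *t* years after the change the
applied multiplier is 1 + min(*t/T*, 1)·(HR<sub>full</sub> − 1), sampled at
year midpoints. The gain is LE(modified) − LE(baseline).

Around the central estimate the package computes

* a **95% uncertainty interval**: 200 seeded replicates, one uniform draw
  per food group placing its curve between its 95% confidence bands;
  interval = 2.5/97.5 percentiles of the replicate gains;
* a **sensitivity interval**: every change-HR pushed toward (*m* = 0.5) or
  away from (*m* = 1.5) the null via
  HR<sub>a</sub> = HR₀ + (1 − HR₀)(1 − *m*), harmful ratios through the
  reciprocal;
* an **energy gate**: diets below 4,000 or above 16,000 kJ/day are refused
  rather than estimated;
* a **NutriGrade score**: evidence quality per group, averaged with weights
  equal to each group's absolute LE contribution.

Three diet presets ship: `TW` (typical Western), `OD` (optimized — intakes
at the mortality plateau) and `FA` (feasibility approach — the per-group
TW/OD midpoint). Mortality schedules and hazard-ratio tables are *inputs*
(CSV readers are provided, including a tolerant reader for burden-of-disease
results-tool exports); the package generates clearly-labelled synthetic
stand-ins so everything runs and is testable offline.

## Worked example

```r
library(dietspan)

schedule <- make_schedule()      # synthetic Gompertz-Makeham mortality
curves   <- make_curveset()      # synthetic dose-response curve set
scenario <- diet_change_scenario(preset_diet("TW"), preset_diet("OD"),
                                 change_age = 20, region = "synthetic")
estimate_gains(scenario, schedule, curves,
               config = uncertainty_config(n_draws = 200, seed = 20220208))
```

prints

```
Diet change 'TW' -> 'OD' at age 20 (female, synthetic)
  LE baseline: 58.5 y   LE after change: 71.2 y
  Gain: 12.7 y (95% UI 11.1 to 14.9; sensitivity 6.1 to 19.9)
  Evidence quality (NutriGrade): 6.7 (moderate)
```

A 20-year-old in the synthetic stratum who switches from the typical
Western to the optimized diet gains 12.7 life years centrally; 11.1–14.9
years when the hazard ratios vary within their confidence bands; 6.1 years
even if every effect is attenuated halfway to the null (m = 0.5); and the
evidence behind the dominant contributors is of moderate quality. The
returned object also carries the per-group forest table (gain and interval
for changing each food group alone). These numbers describe the synthetic
default world — with your own mortality and hazard-ratio inputs they
describe your stratum.

Command-line interface over the same functions:

```sh
Rscript inst/cli/dietspan.R gain --age 60 --draws 200 --out reports/
Rscript inst/cli/dietspan.R sweep-age --ages 20,40,60,80 --T 30
Rscript inst/cli/dietspan.R make-fixtures --out fixtures/
```

Exit codes: 0 success, 2 validation/energy-gate refusal, 1 unexpected error.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline end to end — builds the synthetic mortality schedule
and curve set, estimates the TW→OD gain at age 20 with its uncertainty and
sensitivity intervals and evidence grade, and cross-checks the analytic
life table against a 200,000-lifetime cohort simulation — then writes the
result file.

## Documentation

The methods vignette (`vignettes/dietspan-methods.Rmd`) documents every
modelling convention: life-table closure, the ramp's midpoint sampling, the
draw granularity and RNG contract, the sensitivity transform, the energy
gate calibration, what the synthetic world does and does not emulate, and
known limitations.
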