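---
title: "Modelling the health and economic burden of smoking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and economic burden of smoking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobaccosim)
```

## The model

`tobaccosim` is a first-order Monte Carlo microsimulation of
smoking-attributable disease burden, paired with a closed-form tax-policy
layer. Individuals enter at age 35+ with a fixed smoking status (never,
current, former) and are followed in annual cycles until death or age 100.
Each cycle:

1. **Incidence.** For each of fifteen tobacco-related conditions (four acute
   cardiovascular/respiratory event types, COPD, and ten cancers), an
   incident event or diagnosis is drawn with probability
   `baseline incidence x RR(status)`, the baseline being the never-smoker
   rate by sex and single year of age, capped at 1 (capping is counted and
   logged). Never-smokers have RR = 1 by definition.
2. **Mortality.** Death is competed in a fixed order: event-year case
   fatality and chronic-state excess mortality per condition (in catalogue
   order, folded into one per-condition draw), then background mortality
   from the life table. The first fatal draw sets the cause of death. The
   terminal age forces death (background cause).
3. **Accrual.** Survivors accrue one life-year; a death year accrues a
   half-year (half-cycle correction). QALYs weight the year by the product
   of the utilities of concurrent conditions (bounded in (0, 1], the model's
   choice where the combination rule is genuinely open). YLD accrues
   per condition as `disability weight x credit`, so DALY = YLL + YLD holds
   per condition by construction. Costs accrue as first-year/event costs
   (in full, even in a death year — treatment happened) plus annual
   follow-up or COPD-tier costs (credit-weighted).

Death age is recorded as the age at last birthday, so life-years equal
`death age - entry age + 0.5` and the life table's residual life expectancy
`e(x)` — the YLL assigned to a death at age x — uses the same half-year
convention. A constant-hazard table with q = 0.5 therefore has e = 1/q - 0.5
= 1.5 years, not the curtate 1.0; mixing conventions would bias YLL against
lived years.

**Natural histories.** Acute conditions can recur; ischemic heart disease
and stroke survivors enter follow-up states with an annual cost, disutility
and (configurable) excess mortality. COPD is incident once and progresses
mild → moderate → severe with default annual probabilities 0.05/0.05 — the
cost catalogue prices three tiers but publishes no progression rates, so
these are modelling defaults, not estimates. Cancers use the first-year
cost and case fatality in the diagnosis year; survivors carry the
"second year onwards" cost, disutility and an excess mortality for five
years and are then considered cured. Relative risks apply to incidence by
default; whether the source risk ratios price incidence or mortality is
ambiguous (they are published as mortality RRs), so `sim$rr_applies =
"mortality"` exposes the alternative rather than guessing.

## Attribution

Attributable burden is "current country minus a hypothetical country in
which smokers never existed": the same cohort is simulated twice — once at
observed prevalence, once with everyone a never-smoker — and per-capita
annual rates are differenced and scaled to the national population.

Two design choices make this workable at desk scale:

* **Steady-state reading.** A lifetime cohort run is converted to annual
  cross-sectional rates by dividing total occurrences by person-years at
  each attained age. A single pair of runs then yields annual national
  figures.
* **Common random numbers.** Cohort composition is deterministic
  (largest-remainder allocation over strata, entry ages cycling within
  bands, status blocks never/former/current), and the engine draws a fixed
  uniform layout per individual slot and cycle regardless of parameters.
  Individuals identical across arms produce identical histories, so the
  entire difference comes from individuals whose status differs. Negative
  attributable cells can still arise from sampling noise; they are reported
  as-is with a warning, never clipped.

This single-stream fixed-layout design replaces per-individual RNG streams:
it delivers the same determinism and variance-reduction guarantees with a
fraction of the bookkeeping.

The engine does not model secondhand smoke or perinatal outcomes; a fixed
uplift (13.6% for men, 12% for women, applied over each sex's direct
estimates of deaths, YLL, YLD and costs alike) stands in for them.

## Costing

* **Direct**: unit costs per event/diagnosis year and follow-up year, in
  naira (March 2020), converted to USD only at report time (306.92 ₦/USD).
* **Premature-death productivity**: the human-capital value of a statistical
  life — survival-weighted, discounted future wages from the year after
  death to retirement (60), with wage growth g = 1.21%/yr and discount
  r = 5%/yr. Survival comes from the background life table: counterfactual
  earnings should not embed smoking mortality.
* **Disability productivity**: attributable YLD at working ages times the
  wage, i.e. productivity falls in proportion to quality of life.
* **Informal caregivers**: attributable condition-years times hours of care
  per day times 365 times an hourly opportunity cost. Hours come from a
  per-condition table; conditions without a value fall back to a linear map
  from the disability weight (default 8 h/day per unit weight — a labelled
  placeholder, as the underlying econometric coefficients are unpublished).
  The hourly cost defaults to annual expenditure-per-worker divided by
  250 working days x 8 hours; the source names the proxy but no hourly
  conversion.

The four components add exactly; derived indicators (share of GDP, of
health expenditure, share recovered by tobacco taxes) are always re-derived
from raw quantities, never stored.

## The tax-policy layer

A price rise `dP` changes prevalence by
`PrevB * (alpha*eps_d + (1-alpha)*eps_cp) * dP * Ip`, with own-price
elasticity -0.496, cross-price (licit→illicit) elasticity 0.17, and Ip the
share of the consumption change expressed as prevalence (0.5 in years 1–5,
0.75 in years 6–10). Revenue changes by `(1 + eps_d*dP)*(1 + dP/tax_share)
- 1` under full pass-through. Two parameters are calibrated rather than
published: the licit market share `alpha = 0.94` (chosen so the
illicit-retention ratio reproduces the published 92% of gains retained) and
the tax share of price `tax_share = 0.299` (chosen so the revenue formula
links the published ~168% tax increase to the published ~101% revenue
gain). `dP / tax_share` is read as the proportional tax-rate increase —
the only reading that reconciles those two published figures; the
multiplicative alternative is exposed as `reading = "product"`.

`run_scenario()` projects ten-year effects. Quitters produced by the
prevalence formula become former smokers immediately (ex-smoker RRs are the
only published quit-state parameters). Because non-quitters cancel exactly
under common random numbers, the implementation simulates only the quitter
block, once as current and once as former smokers, and scales the
per-quitter annual rate difference by the national quitter count for each
year's Ip. This is an exact algebraic refactoring of "simulate both arms",
and it makes scenario outputs exactly linear in `dP` — the published
scenario table follows the same proportionality. The prevalence reduction
is applied once per arm at the year-appropriate Ip (no compounding across
years), revenue gains are held constant across the horizon, and health
outcomes are not discounted. Scenario totals exclude the secondhand uplift:
the policy moves active smokers only.

## Synthetic data

The packaged `nigeria_fixture()` embeds the published population,
prevalence, cost and economic parameters verbatim. Everything else —
epidemiological rates, relative risks, utilities, the life table, wages,
caregiver hours — is a **synthetic stand-in**, because the underlying
country calibration (GBD/IARC rates, RR and utility appendices) is not
redistributed. Choices made once, on realism grounds:

* Background mortality is a Gompertz hazard calibrated to a residual life
  expectancy at 35 of 36 years (men) and 39 (women), in the range of
  national life tables.
* Baseline incidence rises exponentially with age (5.5%/yr); current-smoker
  RRs sit near published cohort-study magnitudes (COPD 13, lung cancer 21,
  cardiovascular 2–3); ex-smoker RRs sit halfway between 1 and the
  current-smoker value.
* Wages proxy annual household expenditure per worker (₦380,000, mild
  inverted-U age profile, female ratio 0.8).

Consequently a green simulation test establishes *model correctness*
(oracle equivalence, parameter recovery, invariances), not agreement with
the published national burden, whose magnitudes depend on the withheld
calibration. The published headline numbers are treated as accounting and
format targets only. `generate_bundle()` draws randomized bundles within
stated ranges for property-style testing; all generated values satisfy the
validator's invariants by construction.

## Numerical and degenerate-input choices

* Probabilities are capped at 1 with a counted warning; probabilities are
  validated to [0, 1] at load time, with named-field error messages.
* `rr(former) > rr(current)` and non-monotone life-table `qx` are warnings,
  not errors (documented leniency); strictly increasing residual life
  expectancy is an error.
* Empty rate cells (no person-years at an attained age) yield rate 0 rather
  than NaN.
* The open-ended ≥65 population band is spread uniformly over entry ages
  65–84 (`sim$entry_age_max`); band-to-single-age expansion is uniform.
* Ties in the mortality competition are impossible by construction (fixed
  condition order, background last).

## Limitations

No smoking initiation/cessation dynamics within a lifetime; no
second-order (parameter-uncertainty) simulation; no explicit secondhand or
perinatal modelling beyond the uplift; no subnational or equity
breakdowns; non-medical patient costs are out of scope. Burden magnitudes
from the packaged fixture are illustrative until users supply calibrated
epidemiological inputs through the documented bundle format.
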