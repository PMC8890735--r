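# tobaccosim

Individual-level microsimulation of the health and economic burden of
cigarette smoking, with a closed-form tax-policy layer. Built for health
economists and tobacco-control analysts who need annual
smoking-attributable deaths, events, DALYs and costs for an adult (35+)
population, and projections of what a cigarette price increase through
taxes would avert.

## The model in brief

A first-order Monte Carlo engine follows hypothetical cohorts in annual
cycles from entry to death. For each of 15 tobacco-related conditions
(ischemic and non-ischemic cardiovascular disease, stroke, COPD,
pneumonia/influenza, and ten cancer sites), the per-cycle event risk is

    P(event) = baseline incidence(sex, age) x RR(smoking status)

with RR = 1 for never-smokers. Mortality competes in a fixed order
(event-year case fatality, chronic-state excess mortality, background life
table), and each cycle accrues life-years (half-year credit in the death
year), utility-weighted QALYs, per-condition YLD (disability weight =
1 − utility), and treatment costs.

Attributable burden is the difference between the observed-prevalence
population and a counterfactual in which smokers never existed, read as
steady-state annual rates and scaled to national population strata, plus a
secondhand-smoke uplift (13.6% men, 12% women). DALY = YLL + YLD,
undiscounted and not age-weighted. Indirect costs cover premature-death
productivity loss (human-capital VSL: survival-weighted wages discounted
at `(1+g)/(1+r)` per year to retirement at 60), disability productivity
loss (YLD x wage), and informal caregiver time (hours/day x 365 x
opportunity cost).

The policy layer evaluates price rises ΔP through

    Prev = PrevB + (α·εd + (1−α)·εcp) · ΔP · Ip · PrevB
    Δ%R  = (1 + εd·ΔP)(1 + ΔP/%Ptax) − 1

with εd = −0.496, εcp = 0.17, Ip = 0.5 (years 1–5) / 0.75 (years 6–10),
and an illicit-trade adjustment that retains (α·εd + (1−α)·εcp)/εd ≈ 92%
of gains at α = 0.94.

The packaged `nigeria_fixture()` embeds the published population,
prevalence, unit-cost and economic inputs verbatim; epidemiological rates,
relative risks, utilities, the life table and wages are clearly-flagged
synthetic stand-ins (the national calibration data are not
redistributable), so simulated burden magnitudes are illustrative.

## Worked example

```r
library(tobaccosim)
p <- nigeria_fixture()

run <- smoking_burden(p, n = 20000, seed = 42)
run
#> <burden_run> n=20000 per arm, seed=42
#>   attributable deaths/yr: 46100 | DALYs/yr: 920827
#>   direct cost: 328326 naira mn | total burden: 553313 naira mn
run$daly
#>      sex      yll       yld     daly
#> 1   male 435598.7 133614.10 569212.8
#> 2 female 186225.8  58596.99 244822.7
#> 3  total 621824.5 192211.09 814035.6

sc <- run_scenario(p, policy_scenario(0.50), n = 20000, seed = 42)
sc
#> <scenario_outcomes> price +50%, 10-year horizon
#>   deaths prevented                      27239
#>   ...
#>   tax collection increase              366458 (naira mn)
#>   total economic benefit               716737 (naira mn)
```

Reading the numbers: the burden run differences two common-random-number
cohort arms (observed prevalence vs all never-smokers) and scales to the
~43.6 m national population 35+, giving annual attributable deaths, DALYs
(YLL + YLD by sex) and direct costs in ₦ million, including the
secondhand uplift row. The scenario projects a 50% price rise over ten
years: averted deaths/events/DALYs and avoided costs come from simulating
the formula-implied quitters under both statuses; the tax line is
`10 x ₦36,300 mn x Δ%R` (≈ +101% at ΔP = 0.5); the total is the exact sum
of the four monetary components. The closed-form layer is available
directly: `revenue_change(-0.496, 0.5, 0.299)`, `illicit_retention(0.94,
-0.496, 0.17)`, `post_policy_prevalence(...)`, `vsl(...)`.

Parameter bundles (YAML config + CSV tables) round-trip through
`write_parameters()` / `load_parameters()` with full validation;
`generate_bundle(synthetic_spec(seed))` draws randomized, internally
consistent bundles for testing. A CLI lives at `inst/cli/tobaccosim`
(`burden` and `policy` subcommands).

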