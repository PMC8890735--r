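Package: tobaccosim
Title: Microsimulation of the Health and Economic Burden of Tobacco Smoking
Version: 1.0.0
Authors@R:
    person("Tobi", "Adeyemi", email = "tobi.adeyemi@example.org",
           role = c("aut", "cre"))
Description: An individual-level, annual-cycle Monte Carlo model of the
    disease burden attributable to cigarette smoking, with a closed-form
    tax-policy layer. The engine follows hypothetical cohorts over their
    lifetimes, applying smoking-status relative risks to baseline disease
    incidence for fifteen tobacco-related conditions, and accrues events,
    deaths, life-years, QALYs, DALYs (YLL + YLD) and direct medical costs.
    Attributable burden is the difference between the observed-prevalence
    population and a never-smoker counterfactual, scaled to national
    population strata, with a secondhand-smoke uplift. Costing covers direct
    treatment costs and indirect costs: premature-death productivity loss
    (human-capital value of a statistical life), disability productivity
    loss, and informal caregiver time. The policy layer evaluates cigarette
    price increases through taxes via price-elasticity formulas (prevalence
    change, tax-revenue change, illicit-trade retention) and projects
    ten-year averted deaths, events, DALYs and costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
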