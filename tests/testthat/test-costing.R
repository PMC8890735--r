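# Costing layer: VSL closed forms, disability and caregiver valuation,
# breakdown additivity and derived shares.

flat_wages <- function(w = 100, upto = 60)
  do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, age = 35:upto, wage = w, stringsAsFactors = FALSE)))

no_mort_lt <- function()
  do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, age = 35:100, qx = 0, stringsAsFactors = FALSE)))

test_that("VSL closed-form limits", {
  w <- flat_wages(100)
  lt <- no_mort_lt()
  # death at or after retirement: nothing to lose
  expect_equal(vsl("male", 60, w, lt), 0)
  expect_equal(vsl("male", 70, w, lt), 0)
  # one remaining working year, g = r: discount factor 1
  expect_equal(vsl("male", 59, w, lt, g = 0.05, r = 0.05), 100)
  # one remaining working year at published g and r
  expect_equal(vsl("male", 59, w, lt, g = 0.0121, r = 0.05),
               100 * 1.0121 / 1.05, tolerance = 1e-10)
  expect_equal(round(vsl("male", 59, w, lt, g = 0.0121, r = 0.05), 2),
               96.39)
  # g = r with survival 1: plain sum of remaining working-age wages
  expect_equal(vsl("female", 50, w, lt, g = 0.05, r = 0.05), 100 * 10)
})

test_that("VSL is non-increasing in age at death and respects survival", {
  p <- nigeria_fixture()
  v <- vapply(35:65, function(a)
    vsl("male", a, p$wages, p$life_table, p$econ$g, p$econ$r,
        p$econ$retirement_age), 0)
  expect_true(all(diff(v) <= 1e-9))
  # mortality inside the survival term can only reduce the value
  v_nomort <- vsl("male", 40, p$wages, no_mort_lt(), p$econ$g, p$econ$r)
  expect_lt(vsl("male", 40, p$wages, p$life_table, p$econ$g, p$econ$r),
            v_nomort)
  expect_error(vsl("male", 40, transform(p$wages, wage = -1),
                   p$life_table), "negative")
})

test_that("disability productivity loss is QALY-loss times wage below retirement", {
  w <- flat_wages(50000)
  expect_equal(productivity_loss_disability(
    data.frame(sex = "male", age = 45, years = 0), w), 0)
  expect_equal(productivity_loss_disability(
    data.frame(sex = "male", age = 45, years = 10), w), 500000)
  # ages past retirement are priced at zero
  expect_equal(productivity_loss_disability(
    data.frame(sex = c("male", "male"), age = c(45, 70),
               years = c(10, 10)), w), 500000)
  expect_error(productivity_loss_disability(
    data.frame(sex = "male", age = 45, years = -1), w), ">= 0")
})

test_that("caregiver cost: direct product, linear fallback, missing-data error", {
  cg <- list(hours = data.frame(condition = "stroke", hours_per_day = 2),
             hourly_cost = 100, intercept = 0, slope = 8)
  u <- data.frame(condition = "stroke", utility = 0.65)
  expect_equal(caregiver_cost(c(stroke = 0), cg, u), 0)
  expect_equal(caregiver_cost(c(stroke = 1), cg, u), 2 * 365 * 100)

  # linear fallback: slope 8 h per unit disability weight, utility 0.75
  cg2 <- list(hours = data.frame(condition = "copd",
                                 hours_per_day = NA_real_),
              hourly_cost = 100, intercept = 0, slope = 8)
  u2 <- data.frame(condition = "copd", utility = 0.75)
  expect_equal(caregiver_cost(c(copd = 1), cg2, u2), 2 * 365 * 100)

  expect_error(caregiver_cost(c(ihd = 1), cg2, u2), "no caregiver hours")
})

test_that("cost breakdown adds exactly and reproduces the published composition", {
  # published components (naira million): direct 526,457; caregiver 59,000;
  # disability 24,300; premature death 23,800 -> total 633,557 (~634 bn)
  cb <- assemble_cost_breakdown(
    list(direct = 526457, productivity_premature_death = 23800,
         productivity_disability = 24300, caregiver = 59000),
    econ = default_econ_params())
  expect_equal(cb$total, 633557)
  expect_equal(round(cb$pct_gdp, 2), 0.36)  # 0.3615% of GDP
  expect_equal(cb$pct_gdp, 100 * 526457 / 145639000)

  z <- assemble_cost_breakdown(list(direct = 0,
                                    productivity_premature_death = 0,
                                    productivity_disability = 0,
                                    caregiver = 0))
  expect_equal(z$total, 0)
})

test_that("attributable cost components match a hand-computed enumeration", {
  # deterministic-ish toy: non-fatal condition, no background death before
  # the cap, disutility 0.2, caregiver 1 h/day at unit cost, flat wage
  p <- toy_params(cond_ids = "pneumonia", inc = 0.05, cf = 0, q = 0,
                  rr_cur = 2, prev_cur = 0.5, util = 0.8, wage = 1000)
  cur <- simulate_cohort(p, n = 3000, seed = 14)
  cf0 <- simulate_cohort(p, n = 3000, seed = 14,
                         prevalence = never_prev(p))
  comp <- attributable_cost_components(cur, cf0, p, uplift = FALSE)
  b <- attributable_burden(cur, cf0, p$population)
  core <- attr(b, "core")

  # direct: attributable first-year events times the unit cost
  unit <- p$costs$first_year_cost[p$costs$condition == "pneumonia"]
  expect_equal(comp$direct,
               b$attr_events[b$condition == "pneumonia"] * unit / 1e6,
               tolerance = 1e-9)
  # caregiver: condition-years x 1 h x 365 x 1
  expect_equal(comp$caregiver, sum(core$attr$cond_years) * 365 * 1 / 1e6,
               tolerance = 1e-9)
  # disability: YLD below retirement x wage
  ages <- p$sim$min_age:p$sim$max_age
  yld_sa <- apply(core$attr$yld, c(1, 2), sum)
  expect_equal(comp$productivity_disability,
               sum(yld_sa[, ages < 60]) * 1000 / 1e6, tolerance = 1e-9)
  # no deaths attributable (non-fatal condition, common background draws)
  expect_equal(comp$productivity_premature_death, 0)
})
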