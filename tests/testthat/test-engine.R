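# Monte Carlo engine: probability layer, degenerate runs, closed-form
# lifetimes, determinism, conservation and the two-cycle enumeration oracle.

test_that("annual_event_probability multiplies, ignores RR for never-smokers, and caps", {
  expect_equal(as.numeric(annual_event_probability(0.01, 2.0, "current")),
               0.02)
  expect_equal(as.numeric(annual_event_probability(0.03, 5.0, "never")),
               0.03)
  capped <- annual_event_probability(0.6, 2.0, "current")
  expect_equal(as.numeric(capped), 1.0)
  expect_true(attr(capped, "capped"))
  expect_false(attr(annual_event_probability(0.3, 2, "former"), "capped"))
  expect_error(annual_event_probability(-0.1, 2, "current"), "non-negative")
})

test_that("disability weight is 1 - utility and range-checked", {
  expect_equal(disability_weight(c(0.8, 1, 0)), c(0.2, 0, 1))
  expect_error(disability_weight(1.2), "utility")
})

test_that("YLL lookup returns residual life expectancy and is monotone", {
  lt <- constant_q_life_table(0.5, 35, 100)
  # geometric expectation under the half-year credit convention:
  # e = E[complete years] + 0.5 = (1-q)/q + 0.5 = 1/q - 0.5 = 1.5 at q = 0.5
  expect_equal(yll_for_death("male", 35, lt), lt$ex[1])
  expect_lt(abs(yll_for_death("male", 40, lt) - 1.5), 0.05)
  expect_gt(yll_for_death("male", 40, lt), yll_for_death("male", 60, lt))
  expect_error(yll_for_death("male", 20, lt), "not covered")
})

test_that("degenerate healthy run: no disease, no background death until the cap", {
  p <- toy_params(inc = 0, q = 0)
  h <- simulate_individual(list(sex = "male", age = 35, status = "never"),
                           p, seed = 7)
  expect_equal(h$death$age, 100)
  expect_equal(h$death$cause, "background")
  expect_equal(h$life_years, 100 - 35 + 0.5)
  expect_equal(h$qalys, h$life_years)
  expect_equal(nrow(h$events), 0)
  expect_equal(h$direct_cost, 0)
})

test_that("constant background mortality gives the geometric mean lifetime", {
  q <- 0.2
  p <- toy_params(inc = 0, q = q, prev_cur = 0)
  out <- simulate_cohort(p, n = 50000, seed = 11)
  ly <- out$ind$life_years
  # closed form under the half-cycle credit: E[LY] = 1/q - 0.5
  se <- stats::sd(ly) / sqrt(length(ly))
  expect_lt(abs(mean(ly) - (1 / q - 0.5)), 3 * se)
})

test_that("simulation is deterministic given (profile, parameters, seed)", {
  p <- toy_params(cond_ids = c("pneumonia", "stroke"), inc = 0.05,
                  cf = c(0.1, 0.3), q = 0.05,
                  rr_cur = 2, prev_cur = 0.3)
  h1 <- simulate_individual(list(sex = "female", age = 40,
                                 status = "current"), p, seed = 3)
  h2 <- simulate_individual(list(sex = "female", age = 40,
                                 status = "current"), p, seed = 3)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$death, h2$death)
  expect_identical(h1$qalys, h2$qalys)

  c1 <- simulate_cohort(p, n = 500, seed = 5)
  c2 <- simulate_cohort(p, n = 500, seed = 5)
  expect_identical(c1$deaths, c2$deaths)
  expect_identical(c1$qaly, c2$qaly)
})

test_that("cohort conservation laws hold", {
  p <- toy_params(cond_ids = c("pneumonia", "copd"), inc = c(0.02, 0.01),
                  cf = c(0.05, 0.02), exc = c(0, 0.05), q = 0.03,
                  rr_cur = c(2, 10), util = c(0.85, 0.75),
                  prev_cur = 0.2, prev_for = 0.1)
  out <- simulate_cohort(p, n = 4000, seed = 9)
  # every individual dies exactly once by the age cap
  expect_equal(sum(out$deaths), 4000)
  # person-years equal summed life-years
  expect_equal(sum(out$py), sum(out$ind$life_years))
  # QALYs never exceed life-years, anywhere
  expect_true(all(out$ind$qalys <= out$ind$life_years + 1e-12))
  expect_true(all(out$qaly <= out$py + 1e-9))
  # YLL + YLD additivity is structural: both are finite and non-negative
  expect_true(all(out$yll >= 0) && all(out$yld >= 0))
})

test_that("with all RR = 1 outcomes are independent of smoking status (common seed)", {
  p <- toy_params(cond_ids = "pneumonia", inc = 0.03, cf = 0.1, q = 0.02,
                  rr_cur = 1, rr_for = 1, prev_cur = 0.4, prev_for = 0.2)
  a <- simulate_cohort(p, n = 3000, seed = 21)
  b <- simulate_cohort(p, n = 3000, seed = 21, prevalence = never_prev(p))
  expect_identical(a$deaths, b$deaths)
  expect_identical(a$events, b$events)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$cost, b$cost)
})

test_that("two-cycle engine matches the exhaustive enumeration oracle", {
  # two acute conditions, 2-year horizon (entry 35, forced death at 36)
  pvec <- c(0.30, 0.20)
  cfv <- c(0.40, 0.25)
  q1 <- 0.10
  oracle <- two_cycle_oracle(pvec, cfv, q1)
  p <- toy_params(cond_ids = c("pneumonia", "cvd_nonihd"), inc = pvec,
                  cf = cfv, q = q1, max_age = 36, entry_age_max = 35)
  n <- 100000
  out <- simulate_cohort(p, n = n, seed = 17)

  ev <- out$ind$events
  se_ev <- stats::sd(ev) / sqrt(n)
  expect_lt(abs(mean(ev) - oracle$events), 3 * se_ev)

  for (k in 1:3) {  # causes: pneumonia, cvd_nonihd, background
    ph <- mean(out$ind$cause == k)
    po <- oracle$death_cause[k]
    se <- sqrt(po * (1 - po) / n)
    expect_lt(abs(ph - po), 3 * se)
  }
  # everyone is dead after the forced terminal cycle
  expect_equal(sum(out$ind$cause == 0), 0)
})

test_that("cohort composition matches strata and prevalence deterministically", {
  p <- nigeria_fixture()
  prof <- tobaccosim:::cohort_profiles(p, 10000)
  expect_equal(nrow(prof), 10000)
  # sex split tracks the national population share
  male_share <- sum(p$population$count[p$population$sex == "male"]) /
    sum(p$population$count)
  expect_lt(abs(mean(prof$sex_i == 1) - male_share), 1e-3)
  # smoking prevalence in the 35-44 male band matches Table values
  band <- prof[prof$sex_i == 1 & prof$age <= 44, ]
  expect_lt(abs(mean(band$status_i == 2) - 0.08), 5e-3)
  expect_lt(abs(mean(band$status_i == 3) - 0.05), 5e-3)
  # entry ages within a status block span the band (no age-status blocking)
  cur_ages <- band$age[band$status_i == 2]
  expect_gt(length(unique(cur_ages)), 5)
})
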