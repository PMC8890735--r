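# Burden attribution: identity under null effects, the closed-form
# excess-risk oracle, scaling laws, uplift arithmetic and DALY identities.

test_that("identical inputs give an all-zero attributable table", {
  p <- toy_params(cond_ids = "pneumonia", inc = 0.02, cf = 0.1, q = 0.02,
                  rr_cur = 1, rr_for = 1, prev_cur = 0.3, prev_for = 0.1)
  cur <- simulate_cohort(p, n = 2000, seed = 4)
  cf <- simulate_cohort(p, n = 2000, seed = 4, prevalence = never_prev(p))
  b <- attributable_burden(cur, cf, p$population, p$sim$entry_age_max)
  expect_equal(max(abs(b$attr_deaths)), 0)
  expect_equal(max(abs(b$attr_events)), 0)
  expect_equal(max(abs(b$attr_cost_mn)), 0)
})

test_that("attributable events match the closed-form excess-risk oracle", {
  # prevalence 50%, RR 2, baseline 0.01, population 1e6:
  # expected annual attributable events = 1e6 * 0.5 * 0.01 * (2 - 1) = 5000
  b0 <- 0.01
  p <- toy_params(cond_ids = "pneumonia", inc = b0, cf = 0, q = 0,
                  rr_cur = 2, rr_for = 1, prev_cur = 0.5, pop = 1e6)
  n <- 20000
  cur <- simulate_cohort(p, n = n, seed = 31)
  cf <- simulate_cohort(p, n = n, seed = 31, prevalence = never_prev(p))
  b <- attributable_burden(cur, cf, p$population, p$sim$entry_age_max)
  est <- b$attr_events[b$condition == "pneumonia"]
  # Monte-Carlo SE from the per-individual common-random-number differences
  d <- (cur$ind$events - cf$ind$events) / mean(cur$ind$life_years)
  se <- 1e6 * stats::sd(d) / sqrt(n)
  expect_lt(abs(est - 5000), 3 * se)
})

test_that("attributable cells scale linearly in the population", {
  p <- toy_params(cond_ids = "pneumonia", inc = 0.02, cf = 0.2, q = 0.02,
                  rr_cur = 3, prev_cur = 0.4)
  cur <- simulate_cohort(p, n = 2000, seed = 6)
  cf <- simulate_cohort(p, n = 2000, seed = 6, prevalence = never_prev(p))
  pop2 <- p$population
  pop2$count <- pop2$count * 2
  b1 <- suppressWarnings(
    attributable_burden(cur, cf, p$population, p$sim$entry_age_max))
  b2 <- suppressWarnings(
    attributable_burden(cur, cf, pop2, p$sim$entry_age_max))
  expect_equal(b2$attr_deaths, b1$attr_deaths * 2)
  expect_equal(b2$attr_events, b1$attr_events * 2)
  expect_equal(b2$attr_daly, b1$attr_daly * 2)
  # YLL share of DALY is invariant to population scaling
  t1 <- b1[b1$condition == "total", ]
  t2 <- b2[b2$condition == "total", ]
  expect_equal(t1$attr_yll / t1$attr_daly, t2$attr_yll / t2$attr_daly)
})

test_that("attributable deaths are monotone in smoking prevalence (common seeds)", {
  base <- toy_params(cond_ids = "copd", inc = 0.01, cf = 0.05, exc = 0.05,
                     q = 0.02, rr_cur = 10, rr_for = 5,
                     prev_cur = 0.1, prev_for = 0.05)
  hi_prev <- base$prevalence
  hi_prev$current <- 0.3
  cf <- simulate_cohort(base, n = 4000, seed = 13,
                        prevalence = never_prev(base))
  lo <- simulate_cohort(base, n = 4000, seed = 13)
  hi <- simulate_cohort(base, n = 4000, seed = 13, prevalence = hi_prev)
  b_lo <- suppressWarnings(attributable_burden(lo, cf, base$population))
  b_hi <- suppressWarnings(attributable_burden(hi, cf, base$population))
  expect_gte(b_hi$attr_deaths[b_hi$condition == "total"],
             b_lo$attr_deaths[b_lo$condition == "total"])
})

test_that("secondhand uplift adds the sex-specific fractions and updates totals", {
  p <- toy_params(cond_ids = "pneumonia", inc = 0.02, cf = 0.2, q = 0.02,
                  rr_cur = 3, prev_cur = 0.4)
  cur <- simulate_cohort(p, n = 2000, seed = 8)
  cf <- simulate_cohort(p, n = 2000, seed = 8, prevalence = never_prev(p))
  b <- suppressWarnings(attributable_burden(cur, cf, p$population))
  bs <- attr(b, "by_sex")
  b2 <- apply_secondhand_uplift(b, 0.136, 0.12)
  up <- b2[b2$condition == "secondhand_other", ]
  expect_equal(up$attr_deaths,
               0.136 * bs$attr_deaths[bs$sex == "male"] +
                 0.12 * bs$attr_deaths[bs$sex == "female"])
  tot0 <- b[b$condition == "total", ]
  tot1 <- b2[b2$condition == "total", ]
  expect_equal(tot1$attr_deaths, tot0$attr_deaths + up$attr_deaths)
  expect_equal(tot1$attr_daly, tot0$attr_daly + up$attr_daly)
  expect_error(apply_secondhand_uplift(b2), "already")

  # synthetic single-sex checks: 100 male deaths -> 13.6 uplift deaths
  bs_m <- bs
  bs_m$attr_deaths <- c(100, 0)
  attr(b, "by_sex") <- bs_m
  up_m <- apply_secondhand_uplift(b, 0.136, 0.12)
  expect_equal(up_m$attr_deaths[up_m$condition == "secondhand_other"], 13.6)
  bs_f <- bs
  bs_f$attr_deaths <- c(0, 100)
  attr(b, "by_sex") <- bs_f
  up_f <- apply_secondhand_uplift(b, 0.136, 0.12)
  expect_equal(up_f$attr_deaths[up_f$condition == "secondhand_other"], 12)
})

test_that("DALY decomposition: DALY = YLL + YLD, zero morbidity means YLD = 0", {
  # utility 1 for the condition -> no disability, all burden is mortality
  p <- toy_params(cond_ids = "pneumonia", inc = 0.02, cf = 0.3, q = 0.02,
                  rr_cur = 3, prev_cur = 0.4, util = 1)
  cur <- simulate_cohort(p, n = 2000, seed = 10)
  cf <- simulate_cohort(p, n = 2000, seed = 10, prevalence = never_prev(p))
  d <- daly_decomposition(cur, cf, p$population)
  expect_equal(d$daly, d$yll + d$yld)
  expect_equal(d$yld, rep(0, 3))

  # attributable YLD over a 1-year window equals prevalent attributable
  # state-years times the disability weight: flat rates, disutility 0.3
  p2 <- toy_params(cond_ids = "pneumonia", inc = 0.02, cf = 0, q = 0,
                   rr_cur = 2, prev_cur = 0.5, util = 0.7)
  cur2 <- simulate_cohort(p2, n = 5000, seed = 12)
  cf2 <- simulate_cohort(p2, n = 5000, seed = 12,
                         prevalence = never_prev(p2))
  b2 <- attributable_burden(cur2, cf2, p2$population)
  core <- attr(b2, "core")
  expect_equal(sum(core$attr$yld),
               sum(core$attr$cond_years) * (1 - 0.7), tolerance = 1e-9)
})

test_that("mismatched strata raise an error", {
  p <- toy_params()
  p2 <- toy_params(max_age = 90)
  a <- simulate_cohort(p, n = 200, seed = 1)
  b <- simulate_cohort(p2, n = 200, seed = 1)
  expect_error(attributable_burden(a, b, p$population), "mismatched")
})
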