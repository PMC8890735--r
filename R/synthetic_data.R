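#' Build a life table from a Gompertz mortality hazard
#'
#' Background (all-cause, never-smoker) mortality is modelled as a Gompertz
#' hazard h(a) = b * exp(theta * (a - min_age)). The level parameter `b` is
#' calibrated by root-finding so that residual life expectancy at the
#' minimum age matches a target; `theta` fixes the age slope. The terminal
#' age has qx = 1, and ex is computed with a half-year credit in the death
#' year, which makes ex strictly decreasing in age by construction.
#'
#' @param e_target named numeric: target residual life expectancy (years) at
#'   `min_age` for `male` and `female`.
#' @param theta Gompertz shape (log-hazard slope per year of age).
#' @param min_age,max_age age range covered (integer years).
#' @return data.frame `sex`, `age`, `qx`, `ex`.
#' @export
gompertz_life_table <- function(e_target = c(male = 36, female = 39),
                                theta = 0.08, min_age = 35, max_age = 100) {
  ages <- min_age:max_age
  make_q <- function(b) {
    h <- b * exp(theta * (ages - min_age))
    q <- 1 - exp(-h)
    q <- pmin(q, 0.99)
    q[length(q)] <- 1
    q
  }
  e_from_q <- function(q) {
    # backward recursion with half-year credit in the year of death
    e <- numeric(length(q))
    e[length(q)] <- 0.5
    for (i in (length(q) - 1L):1L)
      e[i] <- 0.5 + (1 - q[i]) * (0.5 + e[i + 1L])
    e
  }
  out <- do.call(rbind, lapply(.sexes, function(s) {
    tgt <- e_target[[s]]
    b <- stats::uniroot(function(b) e_from_q(make_q(b))[1] - tgt,
                        interval = c(1e-6, 0.2), tol = 1e-10)$root
    q <- make_q(b)
    data.frame(sex = s, age = ages, qx = q, ex = e_from_q(q),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Specification for a randomized synthetic parameter bundle
#'
#' Controls the ranges from which [generate_bundle()] draws an internally
#' consistent parameter set. All generated values satisfy the parameter
#' model's invariants by construction: incidence increases with age,
#' RR(former) lies between 1 and RR(current), the life table has strictly
#' decreasing residual life expectancy.
#'
#' @param seed integer RNG seed; the same spec yields the same bundle.
#' @param n_conditions number of conditions (first `n` of
#'   [condition_table()], between 1 and 15).
#' @param rr_current named list of RR ranges for current smokers by kind
#'   (`acute`, `chronic`, `cancer`); COPD and cancers sit at the high end.
#' @param former_fraction position of the ex-smoker RR between 1 and the
#'   current-smoker RR (0 = never-smoker risk, 1 = current-smoker risk).
#' @param utility named list of utility ranges by kind.
#' @param incidence_at_min named list of baseline annual incidence ranges at
#'   the minimum age by kind (never-smokers).
#' @param incidence_slope range of exponential age slopes (per year).
#' @param e35 range of target residual life expectancies at 35 (years).
#' @param wage_level range of mean annual wages (naira/year).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_conditions = 15,
                           rr_current = list(acute = c(1.5, 3.5),
                                             chronic = c(8, 25),
                                             cancer = c(2, 20)),
                           former_fraction = c(0.3, 0.7),
                           utility = list(acute = c(0.7, 0.95),
                                          chronic = c(0.6, 0.85),
                                          cancer = c(0.55, 0.8)),
                           incidence_at_min = list(acute = c(5e-4, 5e-3),
                                                   chronic = c(2e-4, 1e-3),
                                                   cancer = c(1e-5, 2e-4)),
                           incidence_slope = c(0.04, 0.06),
                           e35 = c(35, 45),
                           wage_level = c(250000, 450000)) {
  stopifnot(n_conditions >= 1, n_conditions <= nrow(condition_table()))
  for (rng in c(rr_current, utility, incidence_at_min,
                list(former_fraction, incidence_slope, e35, wage_level)))
    if (length(rng) != 2 || rng[1] > rng[2])
      stop("infeasible range in synthetic spec", call. = FALSE)
  structure(list(seed = seed, n_conditions = n_conditions,
                 rr_current = rr_current,
                 former_fraction = former_fraction, utility = utility,
                 incidence_at_min = incidence_at_min,
                 incidence_slope = incidence_slope, e35 = e35,
                 wage_level = wage_level),
            class = "synthetic_spec")
}

#' Generate a randomized synthetic parameter bundle
#'
#' Draws a complete [parameter_set()] within the ranges of a
#' [synthetic_spec()]. Deterministic given the spec's seed. Useful for
#' property-style testing (e.g. planting a known relative risk and checking
#' it is recovered from simulated cohorts).
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [parameter_set()].
#' @export
generate_bundle <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  conds <- condition_table()[seq_len(spec$n_conditions), , drop = FALSE]
  min_age <- 35; max_age <- 100
  ages <- min_age:max_age
  runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

  # relative risks: same for both sexes, former intermediate
  rr_cur <- vapply(conds$kind, function(k) runif1(spec$rr_current[[k]]), 0)
  ff <- runif1(spec$former_fraction)
  rr_for <- 1 + (rr_cur - 1) * ff
  relative_risks <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    expand.grid(condition = conds$id[i], sex = .sexes,
                status = c("current", "former"), stringsAsFactors = FALSE)
  }))
  relative_risks$rr <- ifelse(relative_risks$status == "current",
                              rr_cur[match(relative_risks$condition,
                                           conds$id)],
                              rr_for[match(relative_risks$condition,
                                           conds$id)])

  utilities <- data.frame(
    condition = conds$id,
    utility = vapply(conds$kind, function(k) runif1(spec$utility[[k]]), 0),
    stringsAsFactors = FALSE)

  inc0 <- vapply(conds$kind,
                 function(k) runif1(spec$incidence_at_min[[k]]), 0)
  slope <- runif1(spec$incidence_slope)
  cf0 <- ifelse(conds$kind == "acute", stats::runif(nrow(conds), 0.05, 0.3),
         ifelse(conds$kind == "chronic", stats::runif(nrow(conds), 0.01, 0.05),
                stats::runif(nrow(conds), 0.2, 0.5)))
  exc <- ifelse(conds$kind == "chronic", stats::runif(nrow(conds), 0.02, 0.06),
         ifelse(conds$kind == "cancer", stats::runif(nrow(conds), 0.05, 0.15),
                ifelse(conds$followup_state,
                       stats::runif(nrow(conds), 0.005, 0.02), 0)))
  epi_rates <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    do.call(rbind, lapply(.sexes, function(s) data.frame(
      condition = conds$id[i], sex = s, age = ages,
      baseline_incidence = pmin(inc0[i] * exp(slope * (ages - min_age)), 0.5),
      case_fatality = cf0[i],
      excess_mortality = exc[i], stringsAsFactors = FALSE)))
  }))

  life_table <- gompertz_life_table(
    e_target = c(male = runif1(spec$e35), female = runif1(spec$e35)),
    min_age = min_age, max_age = max_age)

  # population / prevalence on the standard three bands
  bands <- data.frame(age_low = c(35, 45, 65), age_high = c(44, 64, 100))
  population <- do.call(rbind, lapply(.sexes, function(s)
    data.frame(sex = s, bands,
               count = round(stats::runif(3, 2e6, 1e7)),
               stringsAsFactors = FALSE)))
  prevalence <- do.call(rbind, lapply(.sexes, function(s)
    data.frame(sex = s, bands,
               current = stats::runif(3, 0.03, 0.15),
               former = stats::runif(3, 0.02, 0.2),
               stringsAsFactors = FALSE)))

  wage0 <- runif1(spec$wage_level)
  wages <- do.call(rbind, lapply(seq_along(.sexes), function(si) {
    a <- min_age:60
    prof <- 1 + 0.25 * exp(-((a - 47) / 11)^2)
    data.frame(sex = .sexes[si], age = a,
               wage = wage0 * prof * c(1, 0.8)[si],
               stringsAsFactors = FALSE)
  }))

  hours <- ifelse(stats::runif(nrow(conds)) < 0.5,
                  round(stats::runif(nrow(conds), 0.5, 6), 1), NA_real_)
  caregiver <- list(
    hours = data.frame(condition = conds$id, hours_per_day = hours,
                       stringsAsFactors = FALSE),
    hourly_cost = wage0 / (250 * 8), intercept = 0, slope = 8)

  p <- parameter_set(conditions = conds, population = population,
                     prevalence = prevalence, epi_rates = epi_rates,
                     life_table = life_table,
                     relative_risks = relative_risks, utilities = utilities,
                     costs = default_cost_table()[
                       default_cost_table()$condition %in% conds$id, ,
                       drop = FALSE],
                     wages = wages, caregiver = caregiver,
                     sim = list(seed = spec$seed))
  assert_valid(p)
}

#' The packaged Nigeria parameter set
#'
#' Embeds the published national inputs verbatim: population and smoking
#' prevalence by sex and age band (GATS 2012), the direct-medical-cost
#' catalogue (naira, March 2020), and the economic parameters (own-price
#' elasticity -0.496, cross-price elasticity 0.17, wage growth 1.21%/yr,
#' 5% discount rate, retirement at 60, tobacco tax revenue 36,300 naira
#' million, GDP 145,639,000 naira million, health-expenditure share 3.76%,
#' exchange rate 306.92 naira/USD, secondhand uplifts 13.6%/12%).
#'
#' Epidemiological rates, relative risks, utilities, the life table, wages
#' and caregiver hours are SYNTHETIC stand-ins: the underlying country
#' calibration (GBD/IARC rates, published RR and utility appendices) is not
#' redistributed, so plausible deterministic values are used instead. Burden
#' magnitudes simulated from this fixture are therefore illustrative, not
#' national estimates; the fixture's role is to exercise every model stage
#' end to end.
#'
#' @return a validated [parameter_set()].
#' @export
#' @examples
#' p <- nigeria_fixture()
#' subset(p$prevalence, sex == "male" & age_low == 35)$current  # 0.08
nigeria_fixture <- function() {
  conds <- condition_table()
  min_age <- 35; max_age <- 100
  ages <- min_age:max_age

  bands <- data.frame(age_low = c(35, 45, 65), age_high = c(44, 64, 100))
  population <- rbind(
    data.frame(sex = "male", bands,
               count = c(9257215, 10298790, 3490399)),
    data.frame(sex = "female", bands,
               count = c(9730940, 8095575, 2757322)))
  prevalence <- rbind(
    data.frame(sex = "male", bands, current = c(0.08, 0.11, 0.08),
               former = c(0.05, 0.09, 0.20)),
    data.frame(sex = "female", bands, current = c(0.05, 0.05, 0.09),
               former = c(0.02, 0.03, 0.12)))

  # synthetic stand-ins (deterministic, flagged in the docs)
  rr_cur <- c(ihd = 2.5, cvd_nonihd = 2.0, stroke = 2.8, copd = 13,
              pneumonia = 2.2, lung_cancer = 21, mouth_cancer = 6,
              larynx_cancer = 10, esophagus_cancer = 4.5,
              stomach_cancer = 2.0, pancreas_cancer = 2.2,
              kidney_cancer = 1.8, bladder_cancer = 3.0,
              cervix_cancer = 1.6, leukemia = 1.5)
  rr_for <- 1 + (rr_cur - 1) * 0.5
  relative_risks <- expand.grid(condition = conds$id, sex = .sexes,
                                status = c("current", "former"),
                                stringsAsFactors = FALSE)
  relative_risks$rr <- ifelse(relative_risks$status == "current",
                              rr_cur[relative_risks$condition],
                              rr_for[relative_risks$condition])

  utilities <- data.frame(condition = conds$id, utility = c(
    0.88, 0.87, 0.65, 0.76, 0.85, 0.58, 0.68, 0.67, 0.60, 0.62,
    0.55, 0.70, 0.71, 0.72, 0.64), stringsAsFactors = FALSE)

  inc0 <- c(1.2e-3, 8e-4, 9e-4, 6e-4, 4e-3, 2e-5, 1.5e-5, 8e-6, 8e-6,
            2e-5, 1.2e-5, 8e-6, 8e-6, 6e-5, 1.5e-5)
  cf <- c(0.18, 0.12, 0.22, 0.04, 0.08, 0.55, 0.35, 0.40, 0.55, 0.45,
          0.60, 0.30, 0.25, 0.30, 0.45)
  exc <- c(0.01, 0, 0.02, 0.035, 0, rep(0.10, 10))
  epi_rates <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    do.call(rbind, lapply(.sexes, function(s) data.frame(
      condition = conds$id[i], sex = s, age = ages,
      baseline_incidence = pmin(inc0[i] * exp(0.055 * (ages - min_age)),
                                0.5),
      case_fatality = cf[i], excess_mortality = exc[i],
      stringsAsFactors = FALSE)))
  }))

  life_table <- gompertz_life_table(c(male = 36, female = 39),
                                    min_age = min_age, max_age = max_age)

  wages <- do.call(rbind, lapply(seq_along(.sexes), function(si) {
    a <- min_age:60
    prof <- 1 + 0.25 * exp(-((a - 47) / 11)^2)
    data.frame(sex = .sexes[si], age = a,
               wage = 380000 * prof * c(1, 0.8)[si],
               stringsAsFactors = FALSE)
  }))

  cg_hours <- c(ihd = 1.0, cvd_nonihd = NA, stroke = 4.6, copd = 2.0,
                pneumonia = NA, lung_cancer = 4.0, mouth_cancer = NA,
                larynx_cancer = NA, esophagus_cancer = NA,
                stomach_cancer = NA, pancreas_cancer = NA,
                kidney_cancer = NA, bladder_cancer = NA,
                cervix_cancer = NA, leukemia = NA)
  caregiver <- list(
    hours = data.frame(condition = conds$id,
                       hours_per_day = unname(cg_hours[conds$id]),
                       stringsAsFactors = FALSE),
    hourly_cost = 380000 / (250 * 8), intercept = 0, slope = 8)

  p <- parameter_set(conditions = conds, population = population,
                     prevalence = prevalence, epi_rates = epi_rates,
                     life_table = life_table,
                     relative_risks = relative_risks, utilities = utilities,
                     wages = wages, caregiver = caregiver)
  assert_valid(p)
}
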