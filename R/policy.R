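# Tax-policy layer: closed-form price-elasticity formulas and ten-year
# price-increase scenarios.

#' Smoking prevalence after a price increase
#'
#' Prev = PrevB + (alpha * eps_d + (1 - alpha) * eps_cp) * dP * Ip * PrevB:
#' a price rise dP lowers consumption through the own-price elasticity
#' (weighted by the licit market share alpha, with partial substitution
#' towards illicit products through the cross-price elasticity), and a
#' fraction Ip of the consumption change materializes as a prevalence
#' change. The result is clamped to [0, 1] with a warning if clamping was
#' needed (it never triggers for the documented parameter ranges).
#'
#' @param prev_b baseline prevalence in \[0, 1\].
#' @param alpha licit market share in (0, 1\].
#' @param eps_d own-price elasticity of demand (negative).
#' @param eps_cp cross-price elasticity licit to illicit.
#' @param delta_p proportional retail price increase (e.g. 0.5 for +50%).
#' @param ip share of the consumption change expressed as prevalence change.
#' @return post-policy prevalence.
#' @export
#' @examples
#' post_policy_prevalence(0.10, 1, -0.496, 0.17, 0.5, 0.5)     # 0.0876
#' post_policy_prevalence(0.10, 0.94, -0.496, 0.17, 0.5, 0.5)  # 0.08860
post_policy_prevalence <- function(prev_b, alpha, eps_d, eps_cp, delta_p,
                                   ip) {
  stopifnot(prev_b >= 0, prev_b <= 1)
  out <- prev_b * (1 + (alpha * eps_d + (1 - alpha) * eps_cp) * delta_p * ip)
  if (any(out < 0 | out > 1)) {
    warning("post-policy prevalence clamped to [0,1]", call. = FALSE)
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Proportional tax-revenue change from a price increase
#'
#' d%R = (1 + eps_d * dP) * (1 + dP / tax_share) - 1, under complete
#' pass-through from excises to retail price: the first factor is the
#' consumption change, the second the proportional tax-rate increase needed
#' to lift the retail price by dP when taxes are a share `tax_share` of it.
#' `reading = "product"` exposes the alternative literal reading
#' (1 + dP * tax_share) for sensitivity analysis.
#'
#' @param eps_d own-price elasticity of demand.
#' @param delta_p proportional retail price increase.
#' @param tax_share taxes as a fraction of the retail price, in (0, 1\].
#' @param reading `"ratio"` (default) or `"product"`.
#' @return proportional revenue change (e.g. 1.01 for +101%).
#' @export
#' @examples
#' revenue_change(-0.496, 0.5, 0.299)  # ~ +101%
revenue_change <- function(eps_d, delta_p, tax_share,
                           reading = c("ratio", "product")) {
  reading <- match.arg(reading)
  if (tax_share <= 0 || tax_share > 1)
    stop("tax_share must be in (0,1]", call. = FALSE)
  tax_up <- if (reading == "ratio") delta_p / tax_share
  else delta_p * tax_share
  (1 + eps_d * delta_p) * (1 + tax_up) - 1
}

#' Share of economic gains retained under illicit-trade substitution
#'
#' Ratio of the prevalence-effect coefficient with illicit substitution to
#' the coefficient without it: (alpha * eps_d + (1 - alpha) * eps_cp) /
#' eps_d. Equal to 1 when the market is fully licit, and to alpha when the
#' cross-price elasticity is zero.
#'
#' @inheritParams post_policy_prevalence
#' @return retained fraction of gains.
#' @export
#' @examples
#' illicit_retention(0.94, -0.496, 0.17)  # ~ 0.92
illicit_retention <- function(alpha, eps_d, eps_cp) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (eps_d == 0) stop("eps_d must be non-zero", call. = FALSE)
  (alpha * eps_d + (1 - alpha) * eps_cp) / eps_d
}

#' Define a price-increase scenario
#'
#' @param delta_p proportional retail price increase (>= 0; 0 is a null
#'   scenario); the published scenarios use 0.25, 0.50 and 0.75.
#' @param horizon years (default 10).
#' @param ip_schedule per-year share of the consumption change expressed as
#'   prevalence change; default 0.5 in years 1-5 and 0.75 in years 6-10.
#' @param illicit_adjustment apply the illicit-trade substitution (use the
#'   alpha-weighted elasticity coefficient)? Default `FALSE` — the headline
#'   scenarios treat the market as licit; the adjusted variant retains
#'   [illicit_retention()] of the gains.
#' @return list of class `policy_scenario`.
#' @export
policy_scenario <- function(delta_p, horizon = 10,
                            ip_schedule = NULL,
                            illicit_adjustment = FALSE) {
  stopifnot(delta_p >= 0, horizon >= 1)
  if (is.null(ip_schedule))
    ip_schedule <- ifelse(seq_len(horizon) <= 5, 0.5, 0.75)
  stopifnot(length(ip_schedule) == horizon,
            all(ip_schedule >= 0 & ip_schedule <= 1))
  structure(list(delta_p = delta_p, horizon = horizon,
                 ip_schedule = ip_schedule,
                 illicit_adjustment = illicit_adjustment),
            class = "policy_scenario")
}

#' Run a price-increase scenario
#'
#' Projects the ten-year health and economic effects of raising cigarette
#' prices through taxes. The prevalence formula determines, for each year's
#' Ip, the standing share of baseline current smokers who are former
#' smokers instead under the policy ("quitters"). Because cohort
#' composition is deterministic and the engine guarantees identical random
#' draws for identical individual slots, non-quitters cancel exactly in the
#' baseline-minus-policy difference; the function therefore simulates the
#' quitter block once under current and once under former status (common
#' random numbers) and scales the per-quitter annual rate difference to the
#' national number of quitters. Averted outcomes accumulate over the
#' horizon without discounting; the tax-collection gain is the baseline
#' revenue times [revenue_change()], held constant across years.
#'
#' @param p a validated [parameter_set()].
#' @param s a [policy_scenario()].
#' @param n simulated quitter-block size (default `p$sim$cohort_size`).
#' @param seed RNG seed (default `p$sim$seed`).
#' @return object of class `scenario_outcomes`: deaths prevented, heart
#'   disease / strokes / cancers / COPD cases avoided, DALYs avoided,
#'   health costs avoided, caregiver costs avoided, productivity losses
#'   avoided, tax-collection increase and total economic benefit (naira
#'   million; total is the exact sum of the four monetary components).
#' @export
run_scenario <- function(p, s, n = p$sim$cohort_size, seed = p$sim$seed) {
  stopifnot(inherits(s, "policy_scenario"))
  e <- p$econ
  coef <- if (s$illicit_adjustment)
    e$alpha * e$epsilon_d + (1 - e$alpha) * e$epsilon_cp else e$epsilon_d
  quit_frac <- pmin(pmax(-coef * s$delta_p * s$ip_schedule, 0), 1)

  # smoker-weighted strata: the quitter block is distributed like current
  # smokers; its absolute size per year is quit_frac of them
  smoker_pop <- p$population
  pr <- p$prevalence[match(paste(smoker_pop$sex, smoker_pop$age_low),
                           paste(p$prevalence$sex, p$prevalence$age_low)), ]
  smoker_pop$count <- smoker_pop$count * pr$current

  all_current <- p$prevalence
  all_current$current <- 1; all_current$former <- 0
  all_former <- p$prevalence
  all_former$current <- 0; all_former$former <- 1

  q_tmp <- p; q_tmp$population <- smoker_pop
  arm_cur <- simulate_cohort(q_tmp, n = n, seed = seed,
                             prevalence = all_current)
  arm_frm <- simulate_cohort(q_tmp, n = n, seed = seed,
                             prevalence = all_former)

  core <- attrib_core(arm_cur, arm_frm, smoker_pop, p$sim$entry_age_max)
  horizon_factor <- sum(quit_frac)   # person-years of quit, per smoker
  nc <- length(core$cond_ids)
  gsum <- function(a, ids) sum(a[, , match(ids, core$cond_ids)])
  kinds <- p$conditions$kind[match(core$cond_ids, p$conditions$id)]

  deaths_prevented <- sum(core$attr$deaths[, , seq_len(nc)]) * horizon_factor
  heart <- gsum(core$attr$events, intersect(c("ihd", "cvd_nonihd"),
                                            core$cond_ids)) * horizon_factor
  strokes <- if ("stroke" %in% core$cond_ids)
    gsum(core$attr$events, "stroke") * horizon_factor else 0
  cancers <- sum(core$attr$events[, , kinds == "cancer"]) * horizon_factor
  copd <- if ("copd" %in% core$cond_ids)
    gsum(core$attr$events, "copd") * horizon_factor else 0
  dalys <- (sum(core$attr$yll[, , seq_len(nc)]) + sum(core$attr$yld)) *
    horizon_factor

  cc <- attributable_cost_components(arm_cur, arm_frm, q_tmp, uplift = FALSE)
  health_costs <- cc$direct * horizon_factor
  caregiver <- cc$caregiver * horizon_factor
  productivity <- (cc$productivity_premature_death +
                     cc$productivity_disability) * horizon_factor

  tax_gain <- s$horizon * e$baseline_tax_revenue *
    revenue_change(e$epsilon_d, s$delta_p, e$tax_share)
  total <- health_costs + caregiver + productivity + tax_gain

  structure(list(
    scenario = s, n = n, seed = seed,
    deaths_prevented = deaths_prevented,
    heart_disease_avoided = heart,
    strokes_avoided = strokes,
    cancers_avoided = cancers,
    copd_avoided = copd,
    dalys_avoided = dalys,
    health_costs_avoided = health_costs,
    caregiver_costs_avoided = caregiver,
    productivity_losses_avoided = productivity,
    tax_collection_increase = tax_gain,
    total_economic_benefit = total),
    class = "scenario_outcomes")
}

#' @export
print.scenario_outcomes <- function(x, ...) {
  cat(sprintf("<scenario_outcomes> price +%.0f%%, %d-year horizon\n",
              100 * x$scenario$delta_p, x$scenario$horizon))
  fmt <- function(lbl, v, money = FALSE)
    cat(sprintf("  %-28s %s\n", lbl,
                if (money) sprintf("%14.0f (naira mn)", v)
                else sprintf("%14.0f", v)))
  fmt("deaths prevented", x$deaths_prevented)
  fmt("heart disease avoided", x$heart_disease_avoided)
  fmt("strokes avoided", x$strokes_avoided)
  fmt("cancers avoided", x$cancers_avoided)
  fmt("COPD avoided", x$copd_avoided)
  fmt("DALYs avoided", x$dalys_avoided)
  fmt("health costs avoided", x$health_costs_avoided, TRUE)
  fmt("caregiver costs avoided", x$caregiver_costs_avoided, TRUE)
  fmt("productivity avoided", x$productivity_losses_avoided, TRUE)
  fmt("tax collection increase", x$tax_collection_increase, TRUE)
  fmt("total economic benefit", x$total_economic_benefit, TRUE)
  invisible(x)
}
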