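# Indirect costs: human-capital value of a statistical life, disability
# productivity loss, and informal caregiver time.

#' Value of a statistical life (human-capital form)
#'
#' Discounted expected future labour income lost by a death at a given age:
#' the sum over ages j from `age_at_death + 1` to the retirement age of
#' S(j | age_at_death) * wage(sex, j) * ((1+g)/(1+r))^(j - age_at_death),
#' where S is the background life-table survival (counterfactual earnings do
#' not embed smoking mortality). Zero when death occurs at or after the
#' retirement age.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_at_death integer age.
#' @param wages wage schedule data.frame (`sex`, `age`, `wage`).
#' @param life_table background life table (`sex`, `age`, `qx`).
#' @param g annual wage growth rate (default 0.0121).
#' @param r annual discount rate for future income (default 0.05).
#' @param retirement_age default 60.
#' @return present value in the wage currency.
#' @export
#' @examples
#' w <- data.frame(sex = "male", age = 35:60, wage = 100)
#' lt <- data.frame(sex = "male", age = 35:60, qx = 0)
#' vsl("male", 59, w, lt, g = 0.0121, r = 0.05)  # 100 * 1.0121/1.05
vsl <- function(sex, age_at_death, wages, life_table, g = 0.0121, r = 0.05,
                retirement_age = 60) {
  sex <- match.arg(sex, .sexes)
  if (age_at_death >= retirement_age) return(0)
  js <- (age_at_death + 1):retirement_age
  w <- wages[wages$sex == sex, , drop = FALSE]
  wj <- w$wage[match(js, w$age)]
  if (anyNA(wj))
    stop("wage schedule does not cover ages ",
         paste(js[is.na(wj)], collapse = ","), " for sex=", sex,
         call. = FALSE)
  if (any(wj < 0)) stop("negative wages", call. = FALSE)
  lt <- life_table[life_table$sex == sex, , drop = FALSE]
  qk <- lt$qx[match(age_at_death:(retirement_age - 1), lt$age)]
  qk[is.na(qk)] <- 0
  surv <- cumprod(1 - qk)              # S(j | age_at_death), j = a+1..R
  disc <- ((1 + g) / (1 + r))^(js - age_at_death)
  sum(surv * wj * disc)
}

#' Productivity loss from smoking-attributable disability
#'
#' Work productivity is assumed to fall in the same proportion as quality
#' of life, so the loss is the attributable disability years (YLD) at each
#' working age times the wage at that age. Ages at or above the retirement
#' age contribute nothing.
#'
#' @param loss data.frame `sex`, `age`, `years` of attributable
#'   quality-of-life loss (YLD).
#' @param wages wage schedule data.frame (`sex`, `age`, `wage`).
#' @param retirement_age default 60.
#' @return total loss in the wage currency.
#' @export
productivity_loss_disability <- function(loss, wages, retirement_age = 60) {
  if (any(loss$years < 0)) stop("QALY loss must be >= 0", call. = FALSE)
  keep <- loss$age < retirement_age
  if (!any(keep)) return(0)
  l <- loss[keep, , drop = FALSE]
  wj <- wages$wage[match(paste(l$sex, l$age), paste(wages$sex, wages$age))]
  if (anyNA(wj))
    stop("wage schedule does not cover all working ages", call. = FALSE)
  sum(l$years * wj)
}

#' Informal caregiver cost
#'
#' Values the informal-care hours generated by attributable disease-years
#' at the opportunity cost of caregiver time: condition-years x hours/day x
#' 365 x hourly cost. Hours per day come from the caregiver table; for
#' conditions without a literature value, a linear model on the disability
#' weight fills the gap (hours = intercept + slope * (1 - utility)), capped
#' at 24.
#'
#' @param condition_years named numeric: attributable prevalent
#'   disease-years per condition.
#' @param caregiver caregiver model list: `hours` (data.frame `condition`,
#'   `hours_per_day`, NA = use linear model), `hourly_cost`, `intercept`,
#'   `slope`.
#' @param utilities data.frame `condition`, `utility` (needed for the
#'   linear fallback).
#' @return total cost in the hourly-cost currency.
#' @export
caregiver_cost <- function(condition_years, caregiver, utilities) {
  if (!length(condition_years)) return(0)
  conds <- names(condition_years)
  h <- caregiver$hours$hours_per_day[
    match(conds, caregiver$hours$condition)]
  need <- is.na(h)
  if (any(need)) {
    u <- utilities$utility[match(conds[need], utilities$condition)]
    if (anyNA(u))
      stop("no caregiver hours and no utility for condition(s): ",
           paste(conds[need][is.na(u)], collapse = ", "), call. = FALSE)
    h[need] <- pmin(caregiver$intercept + caregiver$slope * (1 - u), 24)
  }
  sum(condition_years * h * 365 * caregiver$hourly_cost)
}

#' Attributable cost components from a pair of simulated cohorts
#'
#' Computes the four components of the smoking-attributable economic burden
#' on the national scale, in naira million: direct medical costs,
#' premature-death productivity loss (each attributable death valued at the
#' human-capital VSL for its sex and age), disability productivity loss
#' (attributable YLD at working ages times wages), and informal caregiver
#' cost (attributable condition-years times care hours times opportunity
#' cost). Optionally applies the sex-specific secondhand uplift to every
#' component, mirroring the burden table.
#'
#' @param current,counterfactual [simulate_cohort()] outcome pairs (common
#'   seed).
#' @param p the [parameter_set()] both cohorts were simulated from.
#' @param uplift apply the secondhand uplift fractions from `p$uplift`?
#' @return named list `direct`, `productivity_premature_death`,
#'   `productivity_disability`, `caregiver` (naira million).
#' @export
attributable_cost_components <- function(current, counterfactual, p,
                                         uplift = TRUE) {
  core <- attrib_core(current, counterfactual, p$population,
                      p$sim$entry_age_max)
  nc <- length(core$cond_ids)
  ages <- p$sim$min_age:p$sim$max_age
  up <- if (uplift) c(1 + p$uplift$male, 1 + p$uplift$female) else c(1, 1)

  direct <- sum(vapply(1:2, function(s)
    up[s] * sum(core$attr$cost[s, , ]), 0)) / 1e6

  # premature-death productivity: attributable smoking-cause deaths x VSL
  vsl_mat <- vapply(ages, function(a) c(
    vsl("male", a, p$wages, p$life_table, p$econ$g, p$econ$r,
        p$econ$retirement_age),
    vsl("female", a, p$wages, p$life_table, p$econ$g, p$econ$r,
        p$econ$retirement_age)), numeric(2))
  attr_deaths_sa <- apply(core$attr$deaths[, , seq_len(nc), drop = FALSE],
                          c(1, 2), sum)
  premature <- sum(vapply(1:2, function(s)
    up[s] * sum(attr_deaths_sa[s, ] * vsl_mat[s, ]), 0)) / 1e6

  yld_sa <- apply(core$attr$yld, c(1, 2), sum)
  disability <- sum(vapply(1:2, function(s) {
    l <- data.frame(sex = .sexes[s], age = ages, years = pmax(yld_sa[s, ], 0))
    up[s] * productivity_loss_disability(l, p$wages, p$econ$retirement_age)
  }, 0)) / 1e6

  cys <- apply(core$attr$cond_years, 3, sum)
  names(cys) <- core$cond_ids
  cg_raw <- caregiver_cost(pmax(cys, 0), p$caregiver, p$utilities)
  # sex split for the uplift uses each sex's share of condition-years
  cy_sex <- vapply(1:2, function(s) sum(core$attr$cond_years[s, , ]), 0)
  shares <- if (sum(abs(cy_sex)) > 0) abs(cy_sex) / sum(abs(cy_sex))
  else c(0.5, 0.5)
  caregiver <- sum(cg_raw * shares * up) / 1e6

  list(direct = direct, productivity_premature_death = premature,
       productivity_disability = disability, caregiver = caregiver)
}

#' Assemble the total economic burden
#'
#' Adds the four cost components exactly and, when economic parameters are
#' supplied, expresses the direct component as a share of GDP and of total
#' health expenditure (GDP x health-expenditure share), and the totals in
#' USD at the reference exchange rate.
#'
#' @param components named list or vector with `direct`,
#'   `productivity_premature_death`, `productivity_disability`,
#'   `caregiver` (naira million).
#' @param econ optional economic parameter list (see
#'   [default_econ_params()]); enables the derived shares.
#' @return object of class `cost_breakdown`: the four components, `total`
#'   (exact sum), and if `econ` was given `pct_gdp`, `pct_the`,
#'   `total_usd_mn`.
#' @export
assemble_cost_breakdown <- function(components, econ = NULL) {
  need <- c("direct", "productivity_premature_death",
            "productivity_disability", "caregiver")
  stopifnot(all(need %in% names(components)))
  x <- lapply(components[need], as.numeric)
  x$total <- x$direct + x$productivity_premature_death +
    x$productivity_disability + x$caregiver
  if (!is.null(econ)) {
    the <- econ$gdp * econ$the_share
    x$pct_gdp <- 100 * x$direct / econ$gdp
    x$pct_the <- 100 * x$direct / the
    x$total_usd_mn <- x$total * 1e6 / econ$fx_rate / 1e6
  }
  structure(x, class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> (naira million)\n")
  cat(sprintf("  direct:               %14.1f\n", x$direct))
  cat(sprintf("  premature death:      %14.1f\n",
              x$productivity_premature_death))
  cat(sprintf("  disability:           %14.1f\n",
              x$productivity_disability))
  cat(sprintf("  caregiver:            %14.1f\n", x$caregiver))
  cat(sprintf("  total:                %14.1f\n", x$total))
  if (!is.null(x$pct_gdp))
    cat(sprintf("  direct %% GDP: %.2f%% | direct %% THE: %.2f%%\n",
                x$pct_gdp, x$pct_the))
  invisible(x)
}
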