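# Attributable burden: observed-prevalence cohort minus never-smoker
# counterfactual, read as steady-state annual rates and scaled to the
# national population.

# internal: national persons per sex x single age from banded strata,
# spread uniformly within each band up to the entry-age cap
expand_population <- function(population, min_age, max_age,
                              entry_age_max = 84) {
  na <- max_age - min_age + 1L
  pop <- matrix(0, 2, na)
  for (i in seq_len(nrow(population))) {
    a <- population$age_low[i]:min(population$age_high[i], entry_age_max)
    si <- match(population$sex[i], .sexes)
    pop[si, a - min_age + 1L] <- pop[si, a - min_age + 1L] +
      population$count[i] / length(a)
  }
  pop
}

# internal: per-capita annual rate arrays (occurrences per person-year)
# from cohort outcomes; empty cells (no person-years) yield rate 0
rate_of <- function(X, py) {
  r <- X
  if (length(dim(X)) == 3) {
    for (k in seq_len(dim(X)[3])) r[, , k] <- ifelse(py > 0, X[, , k] / py, 0)
  } else r <- ifelse(py > 0, X / py, 0)
  r
}

# internal shared core: attributable quantity arrays, national scale
attrib_core <- function(current, counterfactual, population,
                        entry_age_max = 84) {
  if (!identical(dim(current$py), dim(counterfactual$py)) ||
      !identical(current$cond_ids, counterfactual$cond_ids))
    stop("mismatched strata between the two cohorts", call. = FALSE)
  min_age <- as.integer(current$dimn$age[1])
  max_age <- as.integer(utils::tail(current$dimn$age, 1))
  pop <- expand_population(population, min_age, max_age, entry_age_max)
  scale_attr <- function(q) {
    d <- rate_of(current[[q]], current$py) -
      rate_of(counterfactual[[q]], counterfactual$py)
    if (length(dim(d)) == 3) {
      for (k in seq_len(dim(d)[3])) d[, , k] <- d[, , k] * pop
    } else d <- d * pop
    d
  }
  scale_total <- function(q) {
    r <- rate_of(current[[q]], current$py)
    if (length(dim(r)) == 3) {
      for (k in seq_len(dim(r)[3])) r[, , k] <- r[, , k] * pop
    } else r <- r * pop
    r
  }
  list(pop = pop, cond_ids = current$cond_ids,
       attr = lapply(stats::setNames(nm = c("deaths", "events", "yll",
                                            "yld", "cost", "cond_years")),
                     scale_attr),
       total = lapply(stats::setNames(nm = c("deaths", "events", "cost")),
                      scale_total))
}

#' Smoking-attributable burden table
#'
#' Differences per-capita annual rates between the observed-prevalence
#' cohort and the never-smoker counterfactual (both simulated from the same
#' parameter set with the same seed, so non-smokers cancel exactly under
#' common random numbers), and multiplies by the national population per
#' sex and single year of age. Annual rates are a steady-state reading of
#' the lifetime simulation: total occurrences divided by person-years at
#' each attained age. Negative cells (possible sampling noise) are reported
#' as-is with a warning, never clipped.
#'
#' @param current [simulate_cohort()] outcomes under observed prevalence.
#' @param counterfactual outcomes with all individuals never-smokers
#'   (e.g. `simulate_cohort(p, n, seed, prevalence = zero-prevalence)`).
#' @param population national strata data.frame (`sex`, `age_low`,
#'   `age_high`, `count`).
#' @param entry_age_max upper age used when spreading the open-ended band.
#' @return object of class `burden_table`: a data.frame with one row per
#'   condition plus a `total` row (`total_deaths`, `attr_deaths`,
#'   `total_events`, `attr_events`, `attr_yll`, `attr_yld`, `attr_daly`,
#'   `total_cost_mn`, `attr_cost_mn`; monetary columns in naira million),
#'   with by-sex attributable totals and the sex-age attribution arrays
#'   kept as attributes for the costing layer.
#' @export
attributable_burden <- function(current, counterfactual, population,
                                entry_age_max = 84) {
  core <- attrib_core(current, counterfactual, population, entry_age_max)
  nc <- length(core$cond_ids)
  csum <- function(a, k) sum(a[, , k])
  rows <- data.frame(
    condition = core$cond_ids,
    total_deaths = vapply(seq_len(nc), function(k)
      csum(core$total$deaths, k), 0),
    attr_deaths = vapply(seq_len(nc), function(k)
      csum(core$attr$deaths, k), 0),
    total_events = vapply(seq_len(nc), function(k)
      csum(core$total$events, k), 0),
    attr_events = vapply(seq_len(nc), function(k)
      csum(core$attr$events, k), 0),
    attr_yll = vapply(seq_len(nc), function(k) csum(core$attr$yll, k), 0),
    attr_yld = vapply(seq_len(nc), function(k) csum(core$attr$yld, k), 0),
    total_cost_mn = vapply(seq_len(nc), function(k)
      csum(core$total$cost, k), 0) / 1e6,
    attr_cost_mn = vapply(seq_len(nc), function(k)
      csum(core$attr$cost, k), 0) / 1e6,
    stringsAsFactors = FALSE)
  rows$attr_daly <- rows$attr_yll + rows$attr_yld

  neg <- sum(vapply(core$attr, function(a) sum(a < 0), 0L))
  if (neg > 0)
    warning(sprintf(
      "%d attributable cell(s) are negative (Monte-Carlo noise); reported as-is",
      neg), call. = FALSE)

  total <- rows[1, ]
  total$condition <- "total"
  for (cl in setdiff(names(rows), "condition"))
    total[[cl]] <- sum(rows[[cl]])
  out <- rbind(rows, total)
  out <- out[, c("condition", "total_deaths", "attr_deaths", "total_events",
                 "attr_events", "attr_yll", "attr_yld", "attr_daly",
                 "total_cost_mn", "attr_cost_mn")]

  by_sex <- data.frame(
    sex = .sexes,
    attr_deaths = vapply(1:2, function(s)
      sum(core$attr$deaths[s, , seq_len(nc)]), 0),
    attr_yll = vapply(1:2, function(s)
      sum(core$attr$yll[s, , seq_len(nc)]), 0),
    attr_yld = vapply(1:2, function(s) sum(core$attr$yld[s, , ]), 0),
    attr_cost_mn = vapply(1:2, function(s)
      sum(core$attr$cost[s, , ]), 0) / 1e6,
    stringsAsFactors = FALSE)
  by_sex$attr_daly <- by_sex$attr_yll + by_sex$attr_yld

  structure(out, class = c("burden_table", "data.frame"),
            by_sex = by_sex, core = core, uplift_applied = FALSE)
}

#' Secondhand-smoke (and other causes) uplift
#'
#' Adds a `secondhand_other` row equal to a sex-specific fraction of each
#' sex's directly-estimated attributable deaths, YLL, YLD, DALYs and costs
#' (defaults: 13.6% for men, 12% for women), and updates the grand totals.
#' The uplift stands in for passive smoking and perinatal burden, which the
#' engine does not model explicitly.
#'
#' @param b a [attributable_burden()] table.
#' @param uplift_male,uplift_female uplift fractions.
#' @return the augmented `burden_table`.
#' @export
apply_secondhand_uplift <- function(b, uplift_male = 0.136,
                                    uplift_female = 0.12) {
  stopifnot(inherits(b, "burden_table"))
  if (isTRUE(attr(b, "uplift_applied")))
    stop("uplift already applied", call. = FALSE)
  bs <- attr(b, "by_sex")
  u <- c(uplift_male, uplift_female)
  up <- data.frame(condition = "secondhand_other",
                   total_deaths = sum(u * bs$attr_deaths),
                   attr_deaths = sum(u * bs$attr_deaths),
                   total_events = NA_real_, attr_events = NA_real_,
                   attr_yll = sum(u * bs$attr_yll),
                   attr_yld = sum(u * bs$attr_yld),
                   attr_daly = sum(u * bs$attr_daly),
                   total_cost_mn = NA_real_,
                   attr_cost_mn = sum(u * bs$attr_cost_mn),
                   stringsAsFactors = FALSE)
  body <- b[b$condition != "total", , drop = FALSE]
  total <- b[b$condition == "total", , drop = FALSE]
  for (cl in c("total_deaths", "attr_deaths", "attr_yll", "attr_yld",
               "attr_daly", "attr_cost_mn"))
    total[[cl]] <- total[[cl]] + up[[cl]]
  out <- rbind(body, up, total)
  rownames(out) <- NULL
  bs2 <- bs
  for (cl in c("attr_deaths", "attr_yll", "attr_yld", "attr_daly",
               "attr_cost_mn"))
    bs2[[cl]] <- bs[[cl]] * (1 + u)
  structure(out, class = c("burden_table", "data.frame"),
            by_sex = bs2, core = attr(b, "core"), uplift_applied = TRUE)
}

#' DALY decomposition by sex
#'
#' Attributable years of life lost to premature mortality (YLL) and years
#' lived with disability (YLD) by sex, with DALY = YLL + YLD exactly — no
#' discounting, no age weighting.
#'
#' @inheritParams attributable_burden
#' @return data.frame with rows `female`, `male`, `total` and columns
#'   `yll`, `yld`, `daly`.
#' @export
daly_decomposition <- function(current, counterfactual, population,
                               entry_age_max = 84) {
  core <- attrib_core(current, counterfactual, population, entry_age_max)
  nc <- length(core$cond_ids)
  yll <- vapply(1:2, function(s) sum(core$attr$yll[s, , seq_len(nc)]), 0)
  yld <- vapply(1:2, function(s) sum(core$attr$yld[s, , ]), 0)
  out <- data.frame(sex = c(.sexes, "total"),
                    yll = c(yll, sum(yll)), yld = c(yld, sum(yld)))
  out$daly <- out$yll + out$yld
  out
}
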