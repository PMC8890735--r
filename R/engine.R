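#' Annual event probability under a smoking-status relative risk
#'
#' The risk of an acute or chronic event in a cycle is the baseline
#' never-smoker probability multiplied by the age-, sex- and
#' condition-specific relative risk for the individual's smoking status
#' (RR = 1 for never-smokers), capped at 1. Capping is flagged so the engine
#' can count and log capped draws.
#'
#' @param baseline annual probability in never-smokers, in \[0, 1\].
#' @param rr relative risk (dimensionless, >= 0) for current/former smokers.
#' @param status `"never"`, `"current"` or `"former"`.
#' @return numeric vector of probabilities with a logical attribute
#'   `capped` marking entries where `baseline * rr` exceeded 1.
#' @export
#' @examples
#' annual_event_probability(0.01, 2.0, "current")  # 0.02
#' annual_event_probability(0.03, 5.0, "never")    # 0.03
annual_event_probability <- function(baseline, rr, status) {
  if (any(baseline < 0) || any(rr < 0))
    stop("baseline and rr must be non-negative", call. = FALSE)
  if (any(baseline > 1))
    stop("baseline must be a probability in [0,1]", call. = FALSE)
  status <- match.arg(status, .statuses)
  p <- if (status == "never") baseline else baseline * rr
  capped <- p > 1
  p <- pmin(p, 1)
  attr(p, "capped") <- capped
  p
}

#' Disability weight from a utility value
#'
#' @param u utility in \[0, 1\] (1 = full health).
#' @return `1 - u`.
#' @export
disability_weight <- function(u) {
  if (any(u < 0 | u > 1)) stop("utility must be in [0,1]", call. = FALSE)
  1 - u
}

#' Years of life lost for a death
#'
#' YLL is the residual life expectancy at the age of death taken from the
#' background life table; undiscounted and not age-weighted.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_at_death integer age (years).
#' @param life_table data.frame `sex`, `age`, `qx`, `ex`.
#' @return years of life lost (numeric).
#' @export
yll_for_death <- function(sex, age_at_death, life_table) {
  sex <- match.arg(sex, .sexes)
  i <- which(life_table$sex == sex & life_table$age == age_at_death)
  if (!length(i))
    stop("age ", age_at_death, " not covered by life table for sex=", sex,
         call. = FALSE)
  life_table$ex[i[1]]
}

# ---- internal: compile a parameter_set into engine arrays --------------------

compile_params <- function(p) {
  conds <- p$conditions
  nc <- nrow(conds)
  min_age <- p$sim$min_age; max_age <- p$sim$max_age
  na <- max_age - min_age + 1L

  grid_fill <- function(df, col) {
    out <- lapply(seq_len(nc), function(i) matrix(0, 2, na))
    ci <- match(df$condition, conds$id)
    si <- match(df$sex, .sexes)
    ai <- df$age - min_age + 1L
    ok <- !is.na(ci) & !is.na(si) & ai >= 1L & ai <= na
    v <- df[[col]]
    for (i in which(ok)) out[[ci[i]]][si[i], ai[i]] <- v[i]
    out
  }
  inc_l <- grid_fill(p$epi_rates, "baseline_incidence")
  cf_l <- grid_fill(p$epi_rates, "case_fatality")
  ex_l <- grid_fill(p$epi_rates, "excess_mortality")

  rr <- array(1, c(nc, 2, 3))
  ci <- match(p$relative_risks$condition, conds$id)
  si <- match(p$relative_risks$sex, .sexes)
  ti <- match(p$relative_risks$status, .statuses)
  ok <- !is.na(ci) & !is.na(si) & !is.na(ti)
  rr[cbind(ci, si, ti)[ok, , drop = FALSE]] <- p$relative_risks$rr[ok]

  qm <- matrix(0, 2, na); em <- matrix(NA_real_, 2, na)
  si <- match(p$life_table$sex, .sexes)
  ai <- p$life_table$age - min_age + 1L
  ok <- !is.na(si) & ai >= 1L & ai <= na
  qm[cbind(si, ai)[ok, , drop = FALSE]] <- p$life_table$qx[ok]
  em[cbind(si, ai)[ok, , drop = FALSE]] <- p$life_table$ex[ok]

  util <- rep(1, nc)
  ui <- match(p$utilities$condition, conds$id)
  util[ui[!is.na(ui)]] <- p$utilities$utility[!is.na(ui)]

  first <- follow <- rep(0, nc)
  ci <- match(p$costs$condition, conds$id)
  first[ci[!is.na(ci)]] <- p$costs$first_year_cost[!is.na(ci)]
  follow[ci[!is.na(ci)]] <- p$costs$followup_annual_cost[!is.na(ci)]
  copd_i <- match("copd", conds$id)
  if (!is.na(copd_i)) first[copd_i] <- follow[copd_i] <- 0

  # persistent states: chronic, cancer, and acute with a follow-up state
  persistent <- conds$kind != "acute"
  state_forming <- persistent | conds$followup_state
  sexr <- match(conds$sex_restriction, .sexes, nomatch = 0L)

  list(nc = nc, na = na, min_age = min_age, max_age = max_age,
       inc_l = inc_l, cf_l = cf_l, ex_l = ex_l, rr = rr, q = qm, e = em,
       logu = matrix(log(pmax(util, 1e-12))), dw = 1 - util,
       first = first, follow = follow, copd_i = copd_i,
       copd_cost = unlist(p$costs_copd[c("mild", "moderate", "severe")]),
       copd_prog = p$sim$copd_progression,
       cancer = conds$kind == "cancer",
       cancer_excess_years = p$sim$cancer_excess_years,
       persistent = persistent, state_forming = state_forming, sexr = sexr,
       rr_on_inc = identical(p$sim$rr_applies, "incidence"),
       cond_ids = conds$id, kind = conds$kind)
}

# ---- internal: deterministic cohort composition ------------------------------

# largest-remainder allocation of n units proportional to weights w
alloc_lr <- function(n, w) {
  if (sum(w) <= 0) return(integer(length(w)))
  t <- n * w / sum(w)
  f <- floor(t)
  k <- n - sum(f)
  if (k > 0) {
    o <- order(t - f, decreasing = TRUE)[seq_len(k)]
    f[o] <- f[o] + 1
  }
  as.integer(f)
}

# Build n individual profiles matching the population strata and smoking
# prevalence of a parameter set. Composition is deterministic (largest
# remainder, round-robin ages, status blocks ordered never/former/current)
# so that two cohorts differing only in prevalence share individuals
# one-for-one — the basis of the common-random-numbers design.
cohort_profiles <- function(p, n, prevalence = NULL) {
  if (n < 1) stop("cohort size must be >= 1", call. = FALSE)
  prev <- if (is.null(prevalence)) p$prevalence else prevalence
  pop <- p$population
  counts <- alloc_lr(n, pop$count)
  rows <- lapply(seq_len(nrow(pop)), function(i) {
    ni <- counts[i]
    if (ni == 0) return(NULL)
    a_hi <- min(pop$age_high[i], p$sim$entry_age_max)
    ages <- rep_len(seq.int(pop$age_low[i], a_hi), ni)
    pr <- prev[prev$sex == pop$sex[i] & prev$age_low == pop$age_low[i], ]
    stopifnot(nrow(pr) == 1)
    st_n <- alloc_lr(ni, c(1 - pr$current - pr$former, pr$former,
                           pr$current))
    # ages deliberately left cycling (not sorted) so that the contiguous
    # never/former/current status blocks each span all entry ages evenly
    data.frame(sex_i = match(pop$sex[i], .sexes),
               age = ages,
               status_i = rep(c(1L, 3L, 2L), st_n),
               stratum = i)
  })
  do.call(rbind, rows)
}

# ---- internal: the annual-cycle engine ---------------------------------------

# Simulates all profiles jointly, vectorized across individuals, looping
# over calendar years. RNG layout is fixed: each cycle draws, in order, an
# incidence uniform per condition, a disease-death uniform per condition, a
# background-mortality uniform and a COPD-progression uniform for every
# individual slot, whether or not the draw is used. Two runs with the same
# seed and the same number of profiles therefore give each individual slot
# identical uniforms regardless of parameter or status differences — the
# common-random-numbers guarantee used by the burden and policy layers.
run_engine <- function(profiles, p, seed, record = FALSE) {
  cp <- compile_params(p)
  nc <- cp$nc; na <- cp$na
  n <- nrow(profiles)
  sx <- profiles$sex_i
  st <- profiles$status_i
  agev <- as.integer(profiles$age)
  entry <- agev

  alive <- rep(TRUE, n)
  has <- matrix(FALSE, n, nc)
  tier <- integer(n)
  cyr <- matrix(-1L, n, nc)
  death_age <- rep(NA_integer_, n)
  cause <- integer(n)

  ly_i <- qaly_i <- cost_i <- ev_i <- numeric(n)

  nb <- 2L * na
  events <- yldA <- costA <- cyA <- matrix(0, nb, nc)
  deaths <- yllA <- matrix(0, nb, nc + 1L)
  pyV <- qalyV <- numeric(nb)
  ncap <- 0L
  ev_log <- if (record) list() else NULL

  add_bins <- function(vec, bin, w) {
    s <- rowsum(w, bin, reorder = FALSE)
    i <- as.integer(rownames(s))
    vec[i] <- vec[i] + as.vector(s)
    vec
  }

  set.seed(seed)
  for (t in seq_len(cp$max_age - min(agev) + 1L)) {
    U_inc <- matrix(stats::runif(n * nc), n, nc)
    U_die <- matrix(stats::runif(n * nc), n, nc)
    u_bg <- stats::runif(n)
    u_pr <- stats::runif(n)
    act <- alive & agev <= cp$max_age
    if (!any(act)) break
    ai <- pmin(pmax(agev - cp$min_age + 1L, 1L), na)
    sa <- cbind(sx, ai)

    # 1) incident events / diagnoses
    newev <- matrix(FALSE, n, nc)
    for (cc in seq_len(nc)) {
      b <- cp$inc_l[[cc]][sa]
      pe <- if (cp$rr_on_inc) b * cp$rr[cbind(cc, sx, st)] else b
      over <- pe > 1 & act
      if (any(over)) ncap <- ncap + sum(over)
      pe <- pmin(pe, 1)
      elig <- act
      if (cp$persistent[cc]) elig <- elig & !has[, cc]
      if (cp$sexr[cc] > 0L) elig <- elig & sx == cp$sexr[cc]
      newev[, cc] <- elig & U_inc[, cc] < pe
    }

    # 2) disease mortality: event-year case fatality and chronic excess,
    #    competed in fixed condition order
    die <- matrix(FALSE, n, nc)
    for (cc in seq_len(nc)) {
      relm <- if (cp$rr_on_inc) 1 else cp$rr[cbind(cc, sx, st)]
      pcf <- pmin(cp$cf_l[[cc]][sa] * relm, 1) * newev[, cc]
      prev_c <- has[, cc]
      if (cp$cancer[cc]) prev_c <- prev_c & cyr[, cc] >= 1L
      pex <- pmin(cp$ex_l[[cc]][sa] * relm, 1) * prev_c
      pd <- 1 - (1 - pcf) * (1 - pex)
      die[, cc] <- act & U_die[, cc] < pd
    }
    fatal <- rowSums(die) > 0
    cz <- integer(n)
    for (cc in rev(seq_len(nc))) cz[die[, cc]] <- cc

    # 3) background mortality (forced at the maximum age)
    qv <- cp$q[sa]
    qv[agev >= cp$max_age] <- 1
    bgdie <- act & !fatal & u_bg < qv
    cz[bgdie] <- nc + 1L
    dead_now <- act & (fatal | bgdie)

    # 4) accrual: half-year credit in the year of death
    idx <- which(act)
    credit <- ifelse(dead_now[idx], 0.5, 1)
    morb <- newev | has
    uyear <- exp(as.vector(morb[idx, , drop = FALSE] %*% cp$logu))
    bin <- (sx[idx] - 1L) * na + ai[idx]

    ly_i[idx] <- ly_i[idx] + credit
    qaly_i[idx] <- qaly_i[idx] + credit * uyear
    pyV <- add_bins(pyV, bin, credit)
    qalyV <- add_bins(qalyV, bin, credit * uyear)

    cost_now <- as.vector(newev[idx, , drop = FALSE] %*% cp$first)
    for (cc in seq_len(nc)) {
      mcc <- morb[idx, cc]
      if (any(mcc)) {
        yldA[, cc] <- add_bins(yldA[, cc], bin[mcc],
                               credit[mcc] * cp$dw[cc])
        cyA[, cc] <- add_bins(cyA[, cc], bin[mcc], credit[mcc])
      }
      evc <- newev[idx, cc]
      if (any(evc)) {
        events[, cc] <- add_bins(events[, cc], bin[evc], rep(1, sum(evc)))
        ccost <- rep(cp$first[cc], sum(evc))
        costA[, cc] <- add_bins(costA[, cc], bin[evc], ccost)
      }
      # annual follow-up cost for pre-existing states
      if (cp$follow[cc] > 0) {
        fmask <- has[idx, cc]
        if (any(fmask))
          costA[, cc] <- add_bins(costA[, cc], bin[fmask],
                                  credit[fmask] * cp$follow[cc])
      }
    }
    if (!is.na(cp$copd_i)) {
      tier_now <- ifelse(newev[idx, cp$copd_i], 1L, tier[idx])
      cmask <- tier_now > 0L
      if (any(cmask)) {
        cost_copd <- cp$copd_cost[tier_now[cmask]] * credit[cmask]
        costA[, cp$copd_i] <- add_bins(costA[, cp$copd_i], bin[cmask],
                                       cost_copd)
      }
    }
    cost_i[idx] <- cost_i[idx] + cost_now  # first-year costs
    ev_i[idx] <- ev_i[idx] + rowSums(newev[idx, , drop = FALSE])

    # deaths and YLL
    didx <- which(dead_now)
    if (length(didx)) {
      dbin <- (sx[didx] - 1L) * na + ai[didx]
      for (cc in seq_len(nc + 1L)) {
        dm <- cz[didx] == cc
        if (any(dm)) {
          deaths[, cc] <- add_bins(deaths[, cc], dbin[dm], rep(1, sum(dm)))
          yllA[, cc] <- add_bins(yllA[, cc], dbin[dm],
                                 cp$e[sa[didx[dm], , drop = FALSE]])
        }
      }
      death_age[didx] <- agev[didx]
      cause[didx] <- cz[didx]
      alive[didx] <- FALSE
    }

    if (record && any(newev[idx, , drop = FALSE]))
      ev_log[[length(ev_log) + 1L]] <- {
        w <- which(newev[idx, , drop = FALSE], arr.ind = TRUE)
        data.frame(individual = idx[w[, 1]], age = agev[idx[w[, 1]]],
                   condition = cp$cond_ids[w[, 2]],
                   kind = cp$kind[w[, 2]], stringsAsFactors = FALSE)
      }

    # 5) state updates for survivors
    surv <- act & !dead_now
    for (cc in which(cp$state_forming))
      has[surv & newev[, cc], cc] <- TRUE
    if (!is.na(cp$copd_i)) {
      tier[surv & newev[, cp$copd_i]] <- 1L
      prog <- surv & has[, cp$copd_i] & !newev[, cp$copd_i] &
        tier < 3L & u_pr < cp$copd_prog[pmax(pmin(tier, 2L), 1L)]
      tier[prog] <- tier[prog] + 1L
    }
    for (cc in which(cp$cancer)) {
      cyr[surv & newev[, cc], cc] <- 0L
      adv <- surv & has[, cc] & !newev[, cc]
      cyr[adv, cc] <- cyr[adv, cc] + 1L
      cured <- surv & has[, cc] & cyr[, cc] >= cp$cancer_excess_years
      has[cured, cc] <- FALSE
    }
    agev <- agev + 1L
  }

  # follow-up and COPD costs were binned straight into costA; roll the
  # per-individual direct-cost total up from the aggregate for reporting
  if (ncap > 0)
    warning(sprintf("%d annual event probabilities were capped at 1", ncap),
            call. = FALSE)

  shape <- function(m) {
    a <- array(m, c(na, 2, ncol(m)))
    aperm(a, c(2, 1, 3))
  }
  dimn <- list(sex = .sexes, age = cp$min_age:cp$max_age)
  out <- list(
    n = n, seed = seed, n_capped = ncap,
    events = shape(events), deaths = shape(deaths),
    yll = shape(yllA), yld = shape(yldA), cost = shape(costA),
    cond_years = shape(cyA),
    py = t(matrix(pyV, na, 2)), qaly = t(matrix(qalyV, na, 2)),
    cond_ids = cp$cond_ids,
    ind = list(sex_i = sx, entry = entry, status_i = st,
               life_years = ly_i, qalys = qaly_i, first_year_cost = cost_i,
               events = ev_i, death_age = death_age, cause = cause),
    dimn = dimn)
  dimnames(out$py) <- dimnames(out$qaly) <- dimn
  out$ev_log <- if (record && length(ev_log)) do.call(rbind, ev_log)
  else if (record) data.frame(individual = integer(), age = integer(),
                              condition = character(), kind = character())
  else NULL
  out
}

#' Simulate a single individual's life history
#'
#' Runs the annual-cycle Monte Carlo for one person with fixed smoking
#' status from the entry age until death (or the maximum age, where death
#' is forced). Each cycle draws incident events per condition from the
#' baseline never-smoker probability times the smoking-status relative
#' risk, then competes mortality in a fixed order — event-year case
#' fatality by condition order, then chronic-state excess mortality (folded
#' into the same per-condition draw), then background mortality — and
#' accrues life-years (half-year credit in the death year), multiplicative
#' utility-weighted QALYs, disability (YLD) and costs. Deterministic given
#' `(profile, p, seed)`.
#'
#' @param profile list with `sex` (`"male"`/`"female"`), `age` (entry age,
#'   >= minimum age) and `status` (`"never"`, `"current"`, `"former"`).
#' @param p a validated [parameter_set()].
#' @param seed integer RNG seed.
#' @return object of class `life_history`: `events` (data.frame of `age`,
#'   `condition`, `kind`), `death` (list `age`, `cause`), `life_years`,
#'   `qalys`, `yll`, `direct_cost` (first-year event costs; annual state
#'   costs are part of cohort aggregates).
#' @export
simulate_individual <- function(profile, p, seed = 1) {
  stopifnot(profile$age >= p$sim$min_age, profile$age <= p$sim$max_age)
  prof <- data.frame(sex_i = match(match.arg(profile$sex, .sexes), .sexes),
                     age = as.integer(profile$age),
                     status_i = match(match.arg(profile$status, .statuses),
                                      .statuses))
  r <- run_engine(prof, p, seed, record = TRUE)
  cause_id <- c(r$cond_ids, "background")[r$ind$cause]
  structure(list(
    profile = profile,
    events = r$ev_log[, c("age", "condition", "kind")],
    death = list(age = r$ind$death_age, cause = cause_id),
    life_years = r$ind$life_years,
    qalys = r$ind$qalys,
    yll = yll_for_death(profile$sex, r$ind$death_age, p$life_table),
    direct_cost = sum(r$cost),
    seed = seed), class = "life_history")
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("<life_history> %s, entry %d, %s smoker\n", x$profile$sex,
              x$profile$age, x$profile$status))
  cat(sprintf("  death at %d (%s); life-years %.1f, QALYs %.2f\n",
              x$death$age, x$death$cause, x$life_years, x$qalys))
  cat(sprintf("  %d event(s); direct cost %.0f\n", nrow(x$events),
              x$direct_cost))
  invisible(x)
}

#' Simulate a cohort matching the national strata
#'
#' Simulates `n` individuals whose sex, entry age and smoking status match
#' the parameter set's population strata and smoking prevalence
#' (deterministic composition: largest-remainder allocation, round-robin
#' entry ages within bands, status blocks ordered never/former/current).
#' Returns aggregate outcomes by sex and single year of attained age, with
#' Monte-Carlo standard errors for the headline per-capita quantities.
#'
#' @param p a validated [parameter_set()].
#' @param n cohort size (>= 1); default from `p$sim$cohort_size`.
#' @param seed RNG seed; default from `p$sim$seed`.
#' @param prevalence optional replacement prevalence table (same layout as
#'   `p$prevalence`), used by the policy layer to simulate post-tax arms
#'   against a common-random-numbers baseline.
#' @return object of class `cohort_outcomes` holding arrays
#'   `events`, `deaths`, `yll`, `yld`, `cost`, `cond_years` indexed
#'   `[sex, age, condition]` (deaths/yll have a final `background` slice),
#'   matrices `py` and `qaly` `[sex, age]`, per-individual summaries, and a
#'   `headline` table of means and standard errors.
#' @export
simulate_cohort <- function(p, n = p$sim$cohort_size, seed = p$sim$seed,
                            prevalence = NULL) {
  if (n < 1) stop("cohort size must be >= 1", call. = FALSE)
  prof <- cohort_profiles(p, n, prevalence)
  r <- run_engine(prof, p, seed)
  ind <- r$ind
  smoke_death <- as.numeric(ind$cause >= 1 & ind$cause <= length(r$cond_ids))
  headline <- do.call(rbind, lapply(
    list(deaths_per_capita = smoke_death,
         events_per_capita = ind$events,
         life_years = ind$life_years,
         qalys = ind$qalys),
    function(v) data.frame(mean = mean(v),
                           se = stats::sd(v) / sqrt(length(v)))))
  headline$quantity <- rownames(headline)
  rownames(headline) <- NULL
  r$headline <- headline[, c("quantity", "mean", "se")]
  r$digest <- param_digest(p)
  class(r) <- "cohort_outcomes"
  r
}

#' @export
print.cohort_outcomes <- function(x, ...) {
  cat(sprintf("<cohort_outcomes> n=%d seed=%d\n", x$n, x$seed))
  print(x$headline, row.names = FALSE)
  invisible(x)
}
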