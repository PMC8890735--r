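# Shared fixtures: minimal toy parameter sets and independent oracles.

# life table with constant annual death probability q (terminal age forced);
# residual life expectancy follows the engine's half-year convention
constant_q_life_table <- function(q, min_age = 35, max_age = 100) {
  ages <- min_age:max_age
  qx <- rep(q, length(ages))
  qx[length(qx)] <- 1
  ex <- numeric(length(ages))
  ex[length(ex)] <- 0.5
  for (i in (length(ages) - 1L):1L)
    ex[i] <- 0.5 + (1 - qx[i]) * (0.5 + ex[i + 1L])
  # strictly decreasing ex requires q < 1 before the terminal age
  do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, age = ages, qx = qx, ex = ex,
               stringsAsFactors = FALSE)))
}

# A flat-rate toy parameter set over a chosen subset of conditions.
# All rates constant in age and sex; single population band 35..max_age.
toy_params <- function(cond_ids = "pneumonia", inc = 0.01, cf = 0, exc = 0,
                       rr_cur = 1, rr_for = 1, util = 1, q = 0,
                       prev_cur = 0, prev_for = 0, pop = 1e6,
                       max_age = 100, entry_age_max = 84,
                       wage = 100, seed = 1) {
  ct <- condition_table()
  conds <- ct[match(cond_ids, ct$id), , drop = FALSE]
  k <- nrow(conds)
  rep_k <- function(x) rep_len(x, k)
  ages <- 35:max_age
  epi <- do.call(rbind, lapply(seq_len(k), function(i)
    do.call(rbind, lapply(c("male", "female"), function(s)
      data.frame(condition = conds$id[i], sex = s, age = ages,
                 baseline_incidence = rep_k(inc)[i],
                 case_fatality = rep_k(cf)[i],
                 excess_mortality = rep_k(exc)[i],
                 stringsAsFactors = FALSE)))))
  rr <- do.call(rbind, lapply(seq_len(k), function(i)
    expand.grid(condition = conds$id[i], sex = c("male", "female"),
                status = c("current", "former"),
                stringsAsFactors = FALSE)))
  rr$rr <- ifelse(rr$status == "current",
                  rep_k(rr_cur)[match(rr$condition, conds$id)],
                  rep_k(rr_for)[match(rr$condition, conds$id)])
  band <- data.frame(age_low = 35, age_high = max_age)
  population <- do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, band, count = pop / 2, stringsAsFactors = FALSE)))
  prevalence <- do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, band, current = prev_cur, former = prev_for,
               stringsAsFactors = FALSE)))
  wages <- do.call(rbind, lapply(c("male", "female"), function(s)
    data.frame(sex = s, age = 35:60, wage = wage, stringsAsFactors = FALSE)))
  cg <- list(hours = data.frame(condition = conds$id,
                                hours_per_day = rep(1, k),
                                stringsAsFactors = FALSE),
             hourly_cost = 1, intercept = 0, slope = 8)
  parameter_set(
    conditions = conds, population = population, prevalence = prevalence,
    epi_rates = epi, life_table = constant_q_life_table(q, 35, max_age),
    relative_risks = rr,
    utilities = data.frame(condition = conds$id, utility = rep_k(util),
                           stringsAsFactors = FALSE),
    costs = default_cost_table()[default_cost_table()$condition %in%
                                   conds$id, , drop = FALSE],
    wages = wages, caregiver = cg,
    sim = list(max_age = max_age, entry_age_max = entry_age_max,
               seed = seed))
}

# Independent oracle: exact expectations for a 1-2 condition, 2-cycle model
# with flat per-cycle event probabilities p (vector), case fatalities cf,
# background mortality q in cycle 1 and forced death in cycle 2.
# Events are drawn before mortality, so the death cycle still counts them.
# Death competes in condition order, then background.
# Returns expected events per person and death-cause probabilities.
two_cycle_oracle <- function(p, cf, q) {
  k <- length(p)
  stopifnot(length(cf) == k, k <= 2)
  # per-cycle: P(die of condition j) and P(survive conditions)
  die_cond <- numeric(k)
  surv_conds <- 1
  for (j in seq_len(k)) {
    die_cond[j] <- p[j] * cf[j] * (if (j > 1) prod(1 - p[seq_len(j - 1)] *
                                                     cf[seq_len(j - 1)])
                                   else 1)
    surv_conds <- surv_conds * (1 - p[j] * cf[j])
  }
  ev_per_cycle <- sum(p)
  die1 <- c(die_cond, surv_conds * q)            # cycle 1, causes 1..k, bg
  alive2 <- 1 - sum(die1)
  die2 <- c(die_cond, surv_conds * 1)            # forced death in cycle 2
  list(events = ev_per_cycle * (1 + alive2),
       death_cause = die1 + alive2 * die2)
}

# convenience: never-smoker prevalence table for a parameter set
never_prev <- function(p) {
  pr <- p$prevalence
  pr$current <- 0
  pr$former <- 0
  pr
}
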