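#' Construct a parameter set
#'
#' A `parameter_set` bundles every input the simulation consumes: national
#' population strata and smoking prevalence, condition-specific epidemiology
#' (baseline never-smoker incidence, case fatality, chronic excess
#' mortality), a background life table, relative risks by smoking status,
#' utilities, unit costs, a wage schedule, the informal-caregiver model,
#' economic parameters and simulation settings. Components default to the
#' built-in condition catalogue and documented economic defaults; tabular
#' components have no defaults and must be supplied (or obtained from
#' [nigeria_fixture()] / [generate_bundle()]).
#'
#' @param conditions condition catalogue, see [condition_table()].
#' @param population data.frame `sex`, `age_low`, `age_high`, `count` —
#'   non-overlapping bands covering ages 35+.
#' @param prevalence data.frame `sex`, `age_low`, `age_high`, `current`,
#'   `former` — baseline smoking prevalence fractions per band.
#' @param epi_rates data.frame `condition`, `sex`, `age`,
#'   `baseline_incidence`, `case_fatality`, `excess_mortality` — annual
#'   probabilities in never-smokers by single year of age.
#' @param life_table data.frame `sex`, `age`, `qx` (annual death
#'   probability), `ex` (residual life expectancy, years).
#' @param relative_risks data.frame `condition`, `sex`, `status`
#'   (`current`/`former`), `rr`. Never-smokers have RR 1 implicitly.
#' @param utilities data.frame `condition`, `utility` in (0, 1]; disability
#'   weight is `1 - utility`.
#' @param costs data.frame `condition`, `first_year_cost`,
#'   `followup_annual_cost` in naira, see [default_cost_table()].
#' @param costs_copd list `mild`, `moderate`, `severe`: annual COPD tier
#'   costs in naira.
#' @param wages data.frame `sex`, `age`, `wage` — annual labour-income proxy
#'   (naira/year) for ages 35 to the retirement age.
#' @param caregiver list: `hours` (data.frame `condition`, `hours_per_day`,
#'   `NA` meaning use the linear model), `hourly_cost` (naira/hour),
#'   `intercept` and `slope` (hours/day per unit disability weight).
#' @param econ list of economic parameters; missing entries take the
#'   documented defaults: `epsilon_d` -0.496 (own-price elasticity),
#'   `epsilon_cp` 0.17 (licit-to-illicit cross-price elasticity), `alpha`
#'   0.94 (licit market share), `tax_share` 0.299 (taxes as share of retail
#'   price), `g` 0.0121 (annual wage growth), `r` 0.05 (discount rate for
#'   future income), `retirement_age` 60, `baseline_tax_revenue` 36300
#'   (naira million/year), `gdp` 145639000 (naira million), `the_share`
#'   0.0376 (health expenditure share of GDP), `fx_rate` 306.92 (naira/USD).
#' @param uplift list `male`, `female`: secondhand-smoke-and-other uplift
#'   fractions applied over direct estimates (defaults 0.136 and 0.12).
#' @param sim list of simulation settings; defaults: `cohort_size` 10000,
#'   `min_age` 35, `max_age` 100, `entry_age_max` 84 (upper entry age used
#'   when expanding the open-ended band), `seed` 1, `copd_progression`
#'   c(0.05, 0.05) (annual mild-to-moderate and moderate-to-severe
#'   probabilities), `cancer_excess_years` 5, `rr_applies` "incidence" (or
#'   "mortality").
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(conditions = condition_table(),
                          population, prevalence, epi_rates, life_table,
                          relative_risks, utilities,
                          costs = default_cost_table(),
                          costs_copd = list(mild = 86782, moderate = 232556,
                                            severe = 3863457),
                          wages, caregiver, econ = list(),
                          uplift = list(male = 0.136, female = 0.12),
                          sim = list()) {
  econ <- utils::modifyList(default_econ_params(), econ)
  sim <- utils::modifyList(default_sim_settings(), sim)
  p <- structure(list(conditions = conditions, population = population,
                      prevalence = prevalence, epi_rates = epi_rates,
                      life_table = life_table,
                      relative_risks = relative_risks, utilities = utilities,
                      costs = costs, costs_copd = costs_copd, wages = wages,
                      caregiver = caregiver, econ = econ, uplift = uplift,
                      sim = sim),
                 class = "parameter_set")
  p
}

#' @rdname parameter_set
#' @export
default_econ_params <- function() {
  list(epsilon_d = -0.496, epsilon_cp = 0.17, alpha = 0.94,
       tax_share = 0.299, g = 0.0121, r = 0.05, retirement_age = 60,
       baseline_tax_revenue = 36300, gdp = 145639000, the_share = 0.0376,
       fx_rate = 306.92)
}

#' @rdname parameter_set
#' @export
default_sim_settings <- function() {
  list(cohort_size = 10000, min_age = 35, max_age = 100, entry_age_max = 84,
       seed = 1, copd_progression = c(0.05, 0.05), cancer_excess_years = 5,
       rr_applies = "incidence")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  conditions: %d | population strata: %d | epi rows: %d\n",
              nrow(x$conditions), nrow(x$population), nrow(x$epi_rates)))
  cat(sprintf("  ages %d-%d, cohort size %d, seed %d\n",
              x$sim$min_age, x$sim$max_age, x$sim$cohort_size, x$sim$seed))
  cat(sprintf("  econ: eps_d=%.3f eps_cp=%.2f alpha=%.2f tax_share=%.3f\n",
              x$econ$epsilon_d, x$econ$epsilon_cp, x$econ$alpha,
              x$econ$tax_share))
  invisible(x)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the input bundle and returns a
#' report rather than stopping: probabilities and prevalences in range
#' (current + former <= 1), costs and counts non-negative, utilities in
#' (0, 1], residual life expectancy strictly decreasing in age, referential
#' integrity (every condition referenced in any table is declared in the
#' condition catalogue), age bands non-overlapping, caregiver hours within
#' [0, 24]. `rr(former) > rr(current)` is reported as a warning, not an
#' error, as is a non-monotone life-table `qx`.
#'
#' @param p a [parameter_set()].
#' @return list of class `validation_report` with character vectors `errors`
#'   and `warnings`; an empty `errors` vector means the bundle is usable.
#' @export
validate_parameters <- function(p) {
  errs <- character()
  warns <- character()
  err <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)
  wrn <- function(...) warns[[length(warns) + 1L]] <<- sprintf(...)
  ids <- p$conditions$id

  if (anyDuplicated(ids)) err("duplicate condition ids in catalogue")
  if (any(p$conditions$sex_restriction == "male" &
          p$conditions$id == "cervix_cancer"))
    err("cervix_cancer cannot be male-restricted")

  chk_ref <- function(tab, name) {
    bad <- setdiff(unique(tab$condition), c(ids, "healthy"))
    if (length(bad))
      err("%s references undeclared condition(s): %s", name,
          paste(bad, collapse = ", "))
  }
  chk_ref(p$epi_rates, "epi_rates")
  chk_ref(p$relative_risks, "relative_risks")
  chk_ref(p$utilities, "utilities")
  chk_ref(p$costs, "costs")
  chk_ref(p$caregiver$hours, "caregiver hours")

  # population / prevalence strata
  for (s in .sexes) {
    b <- p$population[p$population$sex == s, , drop = FALSE]
    b <- b[order(b$age_low), , drop = FALSE]
    if (nrow(b) && any(b$age_low[-1] <= b$age_high[-nrow(b)]))
      err("population age bands overlap for sex=%s", s)
    if (nrow(b) && b$age_low[1] > p$sim$min_age)
      err("population bands do not cover age %d for sex=%s",
          p$sim$min_age, s)
  }
  if (any(p$population$count < 0))
    err("negative population count in stratum %s",
        paste(which(p$population$count < 0), collapse = ","))
  bad <- p$prevalence$current < 0 | p$prevalence$former < 0 |
    p$prevalence$current + p$prevalence$former > 1
  if (any(bad))
    err("prevalence invalid (current + former > 1 or negative) in row(s) %s",
        paste(which(bad), collapse = ","))

  # epi rates
  for (col in c("baseline_incidence", "case_fatality", "excess_mortality")) {
    v <- p$epi_rates[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      err("epi_rates$%s outside [0,1] in row(s) %s", col,
          paste(utils::head(which(v < 0 | v > 1), 5), collapse = ","))
  }

  # life table
  for (s in seq_along(.sexes)) {
    lt <- p$life_table[p$life_table$sex == .sexes[s], , drop = FALSE]
    lt <- lt[order(lt$age), , drop = FALSE]
    if (any(lt$qx < 0 | lt$qx > 1))
      err("life_table qx outside [0,1] for sex=%s", .sexes[s])
    if (any(diff(lt$ex) >= 0))
      err("life_table ex not strictly decreasing in age for sex=%s",
          .sexes[s])
    if (any(diff(lt$qx) < 0))
      wrn("life_table qx not monotone in age for sex=%s", .sexes[s])
  }

  # relative risks
  if (any(p$relative_risks$rr < 0)) err("negative relative risk")
  rrw <- merge(
    p$relative_risks[p$relative_risks$status == "current",
                     c("condition", "sex", "rr")],
    p$relative_risks[p$relative_risks$status == "former",
                     c("condition", "sex", "rr")],
    by = c("condition", "sex"), suffixes = c("_cur", "_for"))
  bad <- rrw$rr_for > rrw$rr_cur
  if (any(bad))
    wrn("rr(former) > rr(current) for %s",
        paste(unique(rrw$condition[bad]), collapse = ", "))

  # utilities
  u <- p$utilities$utility
  if (any(u <= 0 | u > 1))
    err("utility outside (0,1] for condition(s) %s",
        paste(p$utilities$condition[u <= 0 | u > 1], collapse = ", "))

  # costs
  if (any(p$costs$first_year_cost < 0 | p$costs$followup_annual_cost < 0))
    err("negative cost in cost catalogue")
  miss <- setdiff(ids, p$costs$condition)
  if (length(miss))
    err("conditions missing a first-year cost: %s",
        paste(miss, collapse = ", "))
  if (any(unlist(p$costs_copd) < 0)) err("negative COPD tier cost")

  # wages
  if (any(p$wages$wage < 0)) err("negative wage in wage schedule")
  for (s in .sexes) {
    w <- p$wages[p$wages$sex == s, , drop = FALSE]
    need <- p$sim$min_age:p$econ$retirement_age
    if (!all(need %in% w$age))
      err("wage schedule for sex=%s missing ages %s", s,
          paste(utils::head(setdiff(need, w$age), 5), collapse = ","))
  }

  # caregiver
  h <- p$caregiver$hours$hours_per_day
  if (any(h < 0 | h > 24, na.rm = TRUE))
    err("caregiver hours/day outside [0,24]")
  if (is.null(p$caregiver$slope) || p$caregiver$slope < 0)
    err("caregiver linear slope must be >= 0")

  # econ
  e <- p$econ
  if (e$alpha <= 0 || e$alpha > 1) err("alpha outside (0,1]: %g", e$alpha)
  if (e$tax_share <= 0 || e$tax_share > 1)
    err("tax_share outside (0,1]: %g", e$tax_share)
  if (e$r <= 0) err("discount rate r must be > 0")
  if (e$retirement_age <= p$sim$min_age)
    err("retirement_age must exceed minimum age %d", p$sim$min_age)
  if (!p$sim$rr_applies %in% c("incidence", "mortality"))
    err("sim$rr_applies must be 'incidence' or 'mortality'")

  structure(list(errors = errs, warnings = warns),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:   ", e, "\n")
  for (w in x$warnings) cat("  warning: ", w, "\n")
  invisible(x)
}

# internal: stop unless the bundle validates cleanly
assert_valid <- function(p) {
  rep <- validate_parameters(p)
  if (length(rep$errors))
    stop("invalid parameter set: ", paste(rep$errors, collapse = "; "),
         call. = FALSE)
  invisible(p)
}

.bundle_tables <- c(conditions = "conditions.csv",
                    population = "population.csv",
                    prevalence = "prevalence.csv",
                    epi_rates = "epi_rates.csv",
                    life_table = "life_table.csv",
                    relative_risks = "relative_risks.csv",
                    utilities = "utilities.csv",
                    costs = "costs.csv",
                    wages = "wages.csv")

#' Read a parameter bundle from disk
#'
#' A bundle is a directory holding `config.yaml` (scalar parameters:
#' economic block, uplifts, COPD tier costs, caregiver model, simulation
#' settings) plus fixed-layout CSV tables: `conditions.csv`,
#' `population.csv`,
#' `prevalence.csv`, `epi_rates.csv`, `life_table.csv`,
#' `relative_risks.csv`, `utilities.csv`, `costs.csv`, `wages.csv`,
#' `caregiver.csv`. Ages are integer years; probabilities and prevalences
#' are decimal fractions. Missing scalar fields take the documented
#' defaults; a missing table is a load error naming the table, and any
#' out-of-range value is a validation error naming the field.
#'
#' @param bundle_path directory containing the bundle.
#' @return a validated [parameter_set()].
#' @seealso [write_parameters()]
#' @export
load_parameters <- function(bundle_path) {
  if (!dir.exists(bundle_path))
    stop("bundle directory not found: ", bundle_path, call. = FALSE)
  cfg_path <- file.path(bundle_path, "config.yaml")
  if (!file.exists(cfg_path))
    stop("bundle is missing required file: config.yaml", call. = FALSE)
  cfg <- yaml::read_yaml(cfg_path)

  tabs <- lapply(names(.bundle_tables), function(nm) {
    f <- file.path(bundle_path, .bundle_tables[[nm]])
    if (!file.exists(f))
      stop("bundle is missing required table: ", .bundle_tables[[nm]],
           call. = FALSE)
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(tabs) <- names(.bundle_tables)

  cg_f <- file.path(bundle_path, "caregiver.csv")
  if (!file.exists(cg_f))
    stop("bundle is missing required table: caregiver.csv", call. = FALSE)
  cg_hours <- utils::read.csv(cg_f, stringsAsFactors = FALSE)

  caregiver <- c(list(hours = cg_hours), cfg$caregiver)
  tabs$conditions$sex_restriction[is.na(tabs$conditions$sex_restriction)] <- ""
  p <- parameter_set(
    conditions = tabs$conditions,
    population = tabs$population, prevalence = tabs$prevalence,
    epi_rates = tabs$epi_rates, life_table = tabs$life_table,
    relative_risks = tabs$relative_risks, utilities = tabs$utilities,
    costs = tabs$costs, costs_copd = cfg$costs_copd %||%
      list(mild = 86782, moderate = 232556, severe = 3863457),
    wages = tabs$wages, caregiver = caregiver,
    econ = cfg$econ %||% list(),
    uplift = cfg$uplift %||% list(male = 0.136, female = 0.12),
    sim = cfg$sim %||% list())
  rep <- validate_parameters(p)
  if (length(rep$errors))
    stop("parameter bundle failed validation: ",
         paste(rep$errors, collapse = "; "), call. = FALSE)
  for (w in rep$warnings) warning(w, call. = FALSE)
  p
}

#' Write a parameter bundle to disk
#'
#' Inverse of [load_parameters()]: writes `config.yaml` plus the CSV tables
#' in the documented layout. Loading the written bundle reproduces the
#' parameter set field by field.
#'
#' @param p a [parameter_set()].
#' @param bundle_path output directory (created if absent).
#' @return `bundle_path`, invisibly.
#' @export
write_parameters <- function(p, bundle_path) {
  dir.create(bundle_path, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(econ = p$econ, uplift = p$uplift,
              costs_copd = p$costs_copd,
              caregiver = p$caregiver[setdiff(names(p$caregiver), "hours")],
              sim = p$sim)
  yaml::write_yaml(cfg, file.path(bundle_path, "config.yaml"))
  for (nm in names(.bundle_tables))
    utils::write.csv(p[[nm]], file.path(bundle_path, .bundle_tables[[nm]]),
                     row.names = FALSE)
  utils::write.csv(p$caregiver$hours, file.path(bundle_path, "caregiver.csv"),
                   row.names = FALSE)
  invisible(bundle_path)
}

#' Content digest of a parameter set
#'
#' MD5 of the serialized canonical components, used in run manifests so
#' outputs can be traced to the exact inputs that produced them.
#'
#' @param p a [parameter_set()].
#' @return character scalar (32 hex digits).
#' @export
param_digest <- function(p) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(p), f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
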