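# Report writers, derived percentage indicators and run manifests.

#' Derived percentage indicators
#'
#' Re-derives the headline ratios from the raw monetary quantities of a run
#' (never from stored percentages): direct treatment cost as % of GDP and
#' of total health expenditure (THE = GDP x health-expenditure share), and
#' the share of direct and total costs recovered by current tobacco-tax
#' revenue. Percentages are rounded to two decimals in written reports but
#' returned at full precision here.
#'
#' @param direct_cost attributable direct treatment cost (naira million).
#' @param total_cost total economic burden (naira million).
#' @param tax_revenue annual tobacco-tax revenue (naira million).
#' @param gdp GDP (naira million).
#' @param the_share health expenditure as a fraction of GDP.
#' @return named list: `pct_gdp`, `pct_the`, `pct_direct_recovered`,
#'   `pct_total_recovered`.
#' @export
#' @examples
#' derived_indicators(526457, 633557, 36300, 145639000, 0.0376)
derived_indicators <- function(direct_cost, total_cost, tax_revenue, gdp,
                               the_share) {
  if (gdp <= 0 || the_share <= 0 || direct_cost <= 0 || total_cost <= 0)
    stop("denominators must be positive", call. = FALSE)
  list(pct_gdp = 100 * direct_cost / gdp,
       pct_the = 100 * direct_cost / (gdp * the_share),
       pct_direct_recovered = 100 * tax_revenue / direct_cost,
       pct_total_recovered = 100 * tax_revenue / total_cost)
}

#' End-to-end smoking-burden estimate
#'
#' Convenience wrapper running the full attribution pipeline: simulates the
#' observed-prevalence cohort and the never-smoker counterfactual with
#' common random numbers, computes the attributable burden table with the
#' secondhand uplift, the DALY decomposition, the four-component cost
#' breakdown and the derived indicators.
#'
#' @param p a validated [parameter_set()].
#' @param n cohort size per arm.
#' @param seed RNG seed.
#' @return list of class `burden_run`: `burden` ([attributable_burden()]
#'   table with uplift), `daly` ([daly_decomposition()]), `costs`
#'   ([assemble_cost_breakdown()]), `indicators`
#'   ([derived_indicators()]), plus the two `cohort_outcomes`.
#' @export
smoking_burden <- function(p, n = p$sim$cohort_size, seed = p$sim$seed) {
  never <- p$prevalence
  never$current <- 0
  never$former <- 0
  cur <- simulate_cohort(p, n = n, seed = seed)
  cf <- simulate_cohort(p, n = n, seed = seed, prevalence = never)
  b <- attributable_burden(cur, cf, p$population, p$sim$entry_age_max)
  b <- apply_secondhand_uplift(b, p$uplift$male, p$uplift$female)
  daly <- daly_decomposition(cur, cf, p$population, p$sim$entry_age_max)
  comp <- attributable_cost_components(cur, cf, p, uplift = TRUE)
  costs <- assemble_cost_breakdown(comp, p$econ)
  ind <- tryCatch(
    derived_indicators(costs$direct, costs$total,
                       p$econ$baseline_tax_revenue, p$econ$gdp,
                       p$econ$the_share),
    error = function(e) NULL)
  structure(list(burden = b, daly = daly, costs = costs, indicators = ind,
                 current = cur, counterfactual = cf, n = n, seed = seed,
                 digest = param_digest(p)),
            class = "burden_run")
}

#' @export
print.burden_run <- function(x, ...) {
  cat(sprintf("<burden_run> n=%d per arm, seed=%d\n", x$n, x$seed))
  tot <- x$burden[x$burden$condition == "total", ]
  cat(sprintf("  attributable deaths/yr: %.0f | DALYs/yr: %.0f\n",
              tot$attr_deaths, tot$attr_daly))
  cat(sprintf("  direct cost: %.0f naira mn | total burden: %.0f naira mn\n",
              x$costs$direct, x$costs$total))
  invisible(x)
}

#' Write run reports
#'
#' Writes the fixed-schema outputs of a run: `burden.csv` (per-condition
#' attributable table), `daly.csv`, `cost_breakdown.json` and, when
#' scenarios are supplied, `scenarios.csv` (one column per price increase).
#' Every output directory gets exactly one `manifest.json` recording the
#' command, parameter digest, seed, cohort size and package version; reruns
#' with an identical manifest produce byte-identical CSVs (timestamps live
#' only in the manifest).
#'
#' @param run a [smoking_burden()] result.
#' @param scenarios optional list of [run_scenario()] results.
#' @param out_dir output directory (created if needed).
#' @param command label recorded in the manifest.
#' @return invisibly, the named vector of files written.
#' @export
write_reports <- function(run, scenarios = list(), out_dir,
                          command = "burden") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- c()
  neg <- any(run$burden$attr_deaths < 0, na.rm = TRUE) ||
    any(run$burden$attr_events < 0, na.rm = TRUE)
  if (neg)
    warning("burden table contains negative attributable cells ",
            "(Monte-Carlo noise); written as-is", call. = FALSE)

  f <- file.path(out_dir, "burden.csv")
  utils::write.csv(as.data.frame(run$burden), f, row.names = FALSE)
  files["burden"] <- f
  f <- file.path(out_dir, "daly.csv")
  utils::write.csv(run$daly, f, row.names = FALSE)
  files["daly"] <- f
  f <- file.path(out_dir, "cost_breakdown.json")
  jsonlite::write_json(c(unclass(run$costs), run$indicators), f,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["costs"] <- f

  if (length(scenarios)) {
    cols <- lapply(scenarios, function(sc) {
      v <- unlist(sc[c("deaths_prevented", "heart_disease_avoided",
                       "strokes_avoided", "cancers_avoided", "copd_avoided",
                       "dalys_avoided", "health_costs_avoided",
                       "caregiver_costs_avoided",
                       "productivity_losses_avoided",
                       "tax_collection_increase", "total_economic_benefit")])
      round(v, 2)
    })
    df <- data.frame(quantity = names(cols[[1]]),
                     stringsAsFactors = FALSE)
    for (i in seq_along(scenarios))
      df[[sprintf("price_up_%.0f_pct",
                  100 * scenarios[[i]]$scenario$delta_p)]] <- cols[[i]]
    f <- file.path(out_dir, "scenarios.csv")
    utils::write.csv(df, f, row.names = FALSE)
    files["scenarios"] <- f
  }

  manifest <- list(command = command, parameter_digest = run$digest,
                   seed = run$seed, cohort_size = run$n,
                   package_version = as.character(
                     utils::packageVersion("tobaccosim")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- f
  invisible(files)
}

#' Command-line entry point
#'
#' Drives the `burden` and `policy` subcommands used by the
#' `inst/cli/tobaccosim` script:
#' `tobaccosim burden --params <bundle> --n 10000 --seed 1 --out <dir>` and
#' `tobaccosim policy --price-increase 50 --horizon 10 --n 10000 --seed 1
#' --out <dir>` (with `--illicit` enabling the illicit-trade adjustment).
#' Without `--params` the packaged Nigeria fixture is used. Exit codes:
#' 0 ok, 1 validation/usage error, 2 I/O error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
tobaccosim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tobaccosim <burden|policy> [--params DIR] [--n N] [--seed S]",
    "[--out DIR] [--price-increase PCT] [--horizon Y] [--illicit]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(params = NULL, n = 5000L, seed = 1L, out = "tobaccosim_out",
              price_increase = 50, horizon = 10L, illicit = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    nxt <- function() { i <<- i + 1; args[i] }
    switch(a,
           "--params" = opt$params <- nxt(),
           "--n" = opt$n <- as.integer(nxt()),
           "--seed" = opt$seed <- as.integer(nxt()),
           "--out" = opt$out <- nxt(),
           "--price-increase" = opt$price_increase <- as.numeric(nxt()),
           "--horizon" = opt$horizon <- as.integer(nxt()),
           "--illicit" = opt$illicit <- TRUE,
           "--no-illicit" = opt$illicit <- FALSE,
           { message("unknown option: ", a, "\n", usage)
             return(invisible(1L)) })
    i <- i + 1
  }
  p <- tryCatch(
    if (is.null(opt$params)) nigeria_fixture()
    else load_parameters(opt$params),
    error = function(e) { message("parameter error: ", conditionMessage(e))
      NULL })
  if (is.null(p)) return(invisible(1L))

  res <- tryCatch({
    run <- smoking_burden(p, n = opt$n, seed = opt$seed)
    scen <- if (cmd == "policy")
      list(run_scenario(p, policy_scenario(
        opt$price_increase / 100, horizon = opt$horizon,
        illicit_adjustment = opt$illicit), n = opt$n, seed = opt$seed))
    else list()
    write_reports(run, scen, opt$out, command = cmd)
    0L
  }, error = function(e) {
    message("run failed: ", conditionMessage(e))
    2L
  })
  message("outputs written to ", opt$out)
  invisible(res)
}
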