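#' Catalogue of modelled tobacco-related conditions
#'
#' Returns the fixed set of fifteen adult conditions the model simulates:
#' four acute cardiovascular/respiratory event types, chronic obstructive
#' pulmonary disease (COPD, a three-tier progressive state), and ten cancer
#' sites (including leukemia). Each condition carries its natural-history
#' kind, ICD-10 metadata, any sex restriction, and flags controlling how the
#' engine treats it:
#'
#' * `acute` conditions can recur; survivors of conditions with a
#'   `followup_state` (ischemic heart disease, stroke) enter an annual
#'   follow-up state that accrues a follow-up cost and disutility.
#' * `chronic` (COPD) is incident once, then progresses mild to moderate to
#'   severe with tier-specific annual costs.
#' * `cancer` is diagnosed once; the diagnosis year uses the first-year cost
#'   and case fatality, survivors accrue the second-year-onwards cost and a
#'   configurable excess mortality for a fixed number of years, after which
#'   they are considered cured.
#'
#' @return A data.frame with one row per condition: `id`, `label`, `kind`
#'   (`acute`, `chronic`, `cancer`), `icd`, `sex_restriction` (`""`, `male`
#'   or `female`), `followup_state` (logical), `group` (reporting group used
#'   in burden tables).
#' @export
#' @examples
#' condition_table()$id
condition_table <- function() {
  data.frame(
    id = c("ihd", "cvd_nonihd", "stroke", "copd", "pneumonia",
           "lung_cancer", "mouth_cancer", "larynx_cancer",
           "esophagus_cancer", "stomach_cancer", "pancreas_cancer",
           "kidney_cancer", "bladder_cancer", "cervix_cancer", "leukemia"),
    label = c("Ischemic heart disease", "Non-ischemic cardiovascular disease",
              "Stroke", "COPD", "Pneumonia/influenza",
              "Lung cancer", "Mouth and pharynx cancer", "Laryngeal cancer",
              "Esophageal cancer", "Stomach cancer", "Pancreatic cancer",
              "Kidney cancer", "Bladder cancer", "Cervical cancer",
              "Leukemia"),
    kind = c("acute", "acute", "acute", "chronic", "acute",
             rep("cancer", 10)),
    icd = c("I20-I25", "I00-I52;I70", "I60-I69", "J40-J43", "J10-J18",
            "C34", "C00-C14", "C32", "C15", "C16", "C25", "C64", "C67",
            "C53", "C92.0"),
    sex_restriction = c(rep("", 13), "female", ""),
    followup_state = c(TRUE, FALSE, TRUE, FALSE, FALSE, rep(FALSE, 10)),
    group = c("cvd", "cvd", "stroke", "copd", "pneumonia",
              "lung_cancer", rep("other_cancer", 8), "other_cancer"),
    stringsAsFactors = FALSE
  )
}

#' Default direct medical unit costs
#'
#' First-year (event/diagnosis-year) and follow-up annual treatment costs per
#' condition, in Nigerian naira. For COPD the three tier costs live in the
#' parameter set's `costs_copd` entry; its rows here are zero placeholders.
#'
#' @return data.frame with `condition`, `first_year_cost`,
#'   `followup_annual_cost` (naira per year, 0 when a condition has no
#'   follow-up state).
#' @export
default_cost_table <- function() {
  data.frame(
    condition = c("ihd", "cvd_nonihd", "stroke", "copd", "pneumonia",
                  "lung_cancer", "mouth_cancer", "larynx_cancer",
                  "esophagus_cancer", "stomach_cancer", "pancreas_cancer",
                  "kidney_cancer", "bladder_cancer", "cervix_cancer",
                  "leukemia"),
    first_year_cost = c(402411, 1173994, 1208400, 0, 61249,
                        3851526, 1714859, 1792030, 1264945, 1266866,
                        1918056, 1525267, 1241534, 2446750, 2650265),
    followup_annual_cost = c(193106, 0, 363348, 0, 0,
                             4709201, 1277677, 705926, 936001, 1072434,
                             1540811, 1074893, 977246, 1828462, 3153983),
    stringsAsFactors = FALSE
  )
}

# internal: sexes are indexed 1 = male, 2 = female throughout the engine
.sexes <- c("male", "female")
.statuses <- c("never", "current", "former")
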