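#' Registry of the 28 audited variables
#'
#' Each patient record carries 28 variables abstracted from both the paper
#' chart and the EHR: demographics, facility identifiers, HIV-care milestone
#' dates, up to three antiretroviral (ART) regimen lines, the last three drug
#' pickups, and the last three viral-load (VL) results. Fifteen of these make
#' up the per-record concordance score.
#'
#' @return A tibble with one row per variable and columns:
#' \describe{
#'   \item{name}{variable identifier used in record-pair column names
#'     (`paper_<name>` / `ehr_<name>`).}
#'   \item{kind}{one of `"date"`, `"categorical"`, `"demographic"`,
#'     `"drug_regimen"`, `"viral_load"`; drives missingness and matching
#'     rules.}
#'   \item{in_concordance}{whether the variable is one of the 15 scored in
#'     the concordance score.}
#'   \item{hiv_related}{date variables subject to the HIV-treatment epoch
#'     lower bound (a date before HIV care existed is impossible, hence
#'     missing).}
#'   \item{date_class}{`"one_off"` for dates set once (birth, enrollment),
#'     `"repeated"` for dates updated at every encounter (visits, pickups,
#'     VL); `NA` for non-dates. Used by the date-error profile and the
#'     synthetic generator.}
#'   \item{repeated_slot}{slot number 1..3 for the repeated pickup/VL/regimen
#'     families, `NA` otherwise.}
#' }
#' @examples
#' v <- dqa_variables()
#' sum(v$in_concordance)  # 15
#' @export
dqa_variables <- function() {
  tibble::tribble(
    ~name, ~kind, ~in_concordance, ~hiv_related, ~date_class, ~repeated_slot,
    "date_of_birth", "date", TRUE, FALSE, "one_off", NA,
    "gender", "demographic", TRUE, FALSE, NA, NA,
    "health_center_district", "categorical", FALSE, FALSE, NA, NA,
    "health_center_sector", "categorical", FALSE, FALSE, NA, NA,
    "health_center_name", "categorical", FALSE, FALSE, NA, NA,
    "date_of_last_visit", "date", TRUE, FALSE, "repeated", NA,
    "date_first_positive_hiv_test", "date", TRUE, TRUE, "one_off", NA,
    "date_enrollment_hiv_care", "date", TRUE, TRUE, "one_off", NA,
    "date_first_art", "date", TRUE, TRUE, "one_off", NA,
    "initial_who_stage", "categorical", TRUE, FALSE, NA, NA,
    "regimen1_start_date", "date", TRUE, TRUE, "one_off", 1,
    "regimen1_drugs", "drug_regimen", TRUE, FALSE, NA, 1,
    "regimen2_start_date", "date", TRUE, TRUE, "one_off", 2,
    "regimen2_drugs", "drug_regimen", TRUE, FALSE, NA, 2,
    "regimen3_start_date", "date", FALSE, TRUE, "one_off", 3,
    "regimen3_drugs", "drug_regimen", FALSE, FALSE, NA, 3,
    "drug_pickup1_date", "date", TRUE, TRUE, "repeated", 1,
    "drug_pickup1_drugs", "drug_regimen", TRUE, FALSE, NA, 1,
    "drug_pickup2_date", "date", FALSE, TRUE, "repeated", 2,
    "drug_pickup2_drugs", "drug_regimen", FALSE, FALSE, NA, 2,
    "drug_pickup3_date", "date", FALSE, TRUE, "repeated", 3,
    "drug_pickup3_drugs", "drug_regimen", FALSE, FALSE, NA, 3,
    "viral_load1_date", "date", TRUE, TRUE, "repeated", 1,
    "viral_load1_value", "viral_load", TRUE, FALSE, NA, 1,
    "viral_load2_date", "date", FALSE, TRUE, "repeated", 2,
    "viral_load2_value", "viral_load", FALSE, FALSE, NA, 2,
    "viral_load3_date", "date", FALSE, TRUE, "repeated", 3,
    "viral_load3_value", "viral_load", FALSE, FALSE, NA, 3
  )
}

#' Names of the 15 concordance-score variables
#' @return Character vector of length 15.
#' @export
concordance_variables <- function() {
  v <- dqa_variables()
  v$name[v$in_concordance]
}

# Column names of a record-pair table: ids then paper_/ehr_ pairs per variable.
record_pair_columns <- function() {
  v <- dqa_variables()$name
  c("patient_id", "facility_id",
    as.vector(rbind(paste0("paper_", v), paste0("ehr_", v))))
}

stop_unknown_variable <- function(variable) {
  bad <- setdiff(variable, dqa_variables()$name)
  if (length(bad) > 0) {
    stop("unknown variable name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(variable)
}
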