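#' Per-variable observation rates emulating a large facility audit
#'
#' Default fill (completeness) probabilities per source and, for variables
#' whose disagreements behave like independent transcription errors, the
#' probability that the EHR value matches the paper value when both are
#' filled. Defaults reflect the completeness and matching levels reported in
#' large paper-vs-EHR audits of HIV care records: demographics near-perfect,
#' milestone dates complete but mismatching 6-40% of the time, second/third
#' line regimens rare, and viral loads 20-30% less complete in the EHR.
#' Viral-load and drug-pickup/last-visit variables are generated by
#' structural mechanisms (EHR lag and staleness) rather than by a direct
#' match rate, so their `match_given_both` is `NA` here.
#'
#' @return A tibble: `name`, `paper_fill`, `ehr_fill`, `match_given_both`,
#'   `mechanism` (`"direct"`, `"conditional"` for the rare regimen lines,
#'   `"last_visit"`, `"pickup"`, `"vl"`).
#' @export
study_variable_profile <- function() {
  tibble::tribble(
    ~name, ~paper_fill, ~ehr_fill, ~match_given_both, ~mechanism,
    "date_of_birth", 0.9994, 0.9997, 0.9359, "direct",
    "gender", 0.9925, 1.0000, 0.9666, "direct",
    "health_center_district", 1.0000, 1.0000, 0.9957, "direct",
    "health_center_sector", 1.0000, 1.0000, 0.9605, "direct",
    "health_center_name", 1.0000, 1.0000, 1.0000, "direct",
    "date_of_last_visit", 0.9991, 0.9994, NA, "last_visit",
    "date_first_positive_hiv_test", 0.7819, 0.6556, 0.6022, "direct",
    "date_enrollment_hiv_care", 0.9968, 0.9971, 0.7496, "direct",
    "date_first_art", 0.9988, 0.9758, 0.7230, "direct",
    "initial_who_stage", 0.9902, 0.9423, 0.8467, "direct",
    "regimen1_start_date", 0.9818, 0.9763, 0.7170, "direct",
    "regimen1_drugs", 0.9838, 0.9550, 0.8209, "direct",
    "regimen2_start_date", 0.9700, 0.6200, 0.5385, "conditional",
    "regimen2_drugs", 0.9700, 0.6200, 0.4744, "conditional",
    "regimen3_start_date", 0.0000, 1.0000, NA, "conditional",
    "regimen3_drugs", 0.0000, 1.0000, NA, "conditional",
    "drug_pickup1_date", 0.9997, 0.9994, NA, "pickup",
    "drug_pickup1_drugs", 0.9997, 0.9553, NA, "pickup",
    "drug_pickup2_date", 0.9902, 0.9763, NA, "pickup",
    "drug_pickup2_drugs", 0.9905, 0.9325, NA, "pickup",
    "drug_pickup3_date", 0.9792, 0.9423, NA, "pickup",
    "drug_pickup3_drugs", 0.9798, 0.9008, NA, "pickup",
    "viral_load1_date", NA, NA, NA, "vl",
    "viral_load1_value", NA, NA, NA, "vl",
    "viral_load2_date", NA, NA, NA, "vl",
    "viral_load2_value", NA, NA, NA, "vl",
    "viral_load3_date", NA, NA, NA, "vl",
    "viral_load3_value", NA, NA, NA, "vl"
  )
}

#' Configuration of the synthetic dual-source generator
#'
#' Defines the study conditions the generator emulates: 50 facilities, half
#' randomized to an enhanced EHR with clinical alerts (11 of the 25
#' intervention facilities carrying the missing-viral-load alert), 48-76
#' charts per facility totalling 3467 records, chart abstraction in late
#' 2018 with the alert intervention live from July 2018, and the error
#' processes that make the two sources disagree.
#'
#' @param seed Integer seed; mandatory, the dataset is a pure function of
#'   the configuration.
#' @param n_facilities Number of health facilities.
#' @param total_records Total charts audited across facilities; allocated
#'   within `charts_range` per facility.
#' @param charts_range Minimum and maximum charts per facility (LQAS
#'   protocol bounds).
#' @param intervention_fraction Fraction of facilities in the intervention
#'   arm.
#' @param vl_alert_fraction Fraction of intervention facilities with the
#'   missing-VL alert (tier >= 2).
#' @param collection_date Chart-abstraction date.
#' @param cutoff_date Intervention roll-out date.
#' @param variable_profile Per-variable fill and match rates, see
#'   [study_variable_profile()].
#' @param sentinel_date_rate Probability a missing date is written as the
#'   1980-01-01 placeholder instead of left blank.
#' @param small_offset_frac Probability that a transcribed date error lies
#'   within 30 days of the truth, by date class (`one_off` dates are
#'   mistyped near the true value about a third of the time; stale
#'   `repeated` dates are usually far off).
#' @param regimen_split_prob Probability the EHR renders a regimen in the
#'   split "A + B and C" dialect (canonically identical, exercising
#'   standardization).
#' @param vl_decimal_prob Probability the paper chart keeps the decimal of a
#'   viral load the EHR stores as a whole number.
#' @param ehr_vl_old_entry_prob Probability the EHR holds any given
#'   non-recent viral-load entry.
#' @param vl_date_error,vl_value_error Transcription-error probabilities on
#'   EHR viral-load dates and values (non-timely entries).
#' @param vl_recent_match_prob Baseline probability that the EHR holds a
#'   timely, matching copy of a post-cutoff most-recent viral load (the
#'   quantity the missing-VL alert targets).
#' @param pickup_recent_match_prob Same for the most recent drug pickup.
#' @param pickup_drug_error Transcription-error probability on EHR pickup
#'   drug lists.
#' @param last_visit_match_prob Probability the EHR last-visit date is
#'   current rather than stale.
#' @param alert_effect Multiplier applied to `vl_recent_match_prob` and
#'   `pickup_recent_match_prob` at alert facilities; 1 = no effect.
#' @param covariate_effects Slopes of the record-quality model:
#'   `availability` (EHR uptime Likert 1-5, positive = better quality) and
#'   `tech_experience` (0-4). EHR error and missingness probabilities are
#'   scaled by `2 * plogis(-(b_a (avail - 3) + b_t (tech - 2)))`, which has
#'   mean 1 over the symmetric covariate distributions.
#' @param paper_vl_record_prob Probability the paper chart records each
#'   existing viral-load result.
#' @param n_vl_probs Probabilities of a patient having 0..3 viral-load
#'   results.
#' @param regimen2_prevalence,regimen3_prevalence Prevalence of second and
#'   third treatment lines.
#' @return A list of class `dqa_simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_facilities = 50,
                              total_records = 3467,
                              charts_range = c(48, 76),
                              intervention_fraction = 0.5,
                              vl_alert_fraction = 11 / 25,
                              collection_date = as.Date("2018-12-01"),
                              cutoff_date = as.Date("2018-07-01"),
                              variable_profile = study_variable_profile(),
                              sentinel_date_rate = 0.3,
                              small_offset_frac = c(one_off = 0.36, repeated = 0.12),
                              regimen_split_prob = 0.2,
                              vl_decimal_prob = 0.3,
                              ehr_vl_old_entry_prob = 0.72,
                              vl_date_error = 0.30,
                              vl_value_error = 0.08,
                              vl_recent_match_prob = 0.119,
                              pickup_recent_match_prob = 0.187,
                              pickup_drug_error = 0.16,
                              last_visit_match_prob = 0.283,
                              alert_effect = 2.24,
                              covariate_effects = c(availability = 0.3,
                                                    tech_experience = -0.2),
                              paper_vl_record_prob = 0.985,
                              n_vl_probs = c(0.04, 0.09, 0.17, 0.70),
                              regimen2_prevalence = 0.04,
                              regimen3_prevalence = 0.0005) {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory for a reproducible simulation", call. = FALSE)
  }
  probs <- c(sentinel_date_rate, small_offset_frac, regimen_split_prob,
             vl_decimal_prob, ehr_vl_old_entry_prob, vl_date_error,
             vl_value_error, vl_recent_match_prob, pickup_recent_match_prob,
             pickup_drug_error, last_visit_match_prob, intervention_fraction,
             vl_alert_fraction,
             paper_vl_record_prob, n_vl_probs, regimen2_prevalence,
             regimen3_prevalence,
             stats::na.omit(variable_profile$paper_fill),
             stats::na.omit(variable_profile$ehr_fill),
             stats::na.omit(variable_profile$match_given_both))
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (alert_effect < 0) stop("alert_effect must be nonnegative", call. = FALSE)
  if (charts_range[1] > charts_range[2] ||
      total_records < n_facilities * charts_range[1] ||
      total_records > n_facilities * charts_range[2]) {
    stop("total_records not attainable within charts_range", call. = FALSE)
  }
  if (abs(sum(n_vl_probs) - 1) > 1e-8) {
    stop("n_vl_probs must sum to 1", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_facilities = n_facilities,
         total_records = total_records, charts_range = charts_range,
         intervention_fraction = intervention_fraction,
         vl_alert_fraction = vl_alert_fraction,
         collection_date = as.Date(collection_date),
         cutoff_date = as.Date(cutoff_date),
         variable_profile = variable_profile,
         sentinel_date_rate = sentinel_date_rate,
         small_offset_frac = small_offset_frac,
         regimen_split_prob = regimen_split_prob,
         vl_decimal_prob = vl_decimal_prob,
         ehr_vl_old_entry_prob = ehr_vl_old_entry_prob,
         vl_date_error = vl_date_error, vl_value_error = vl_value_error,
         vl_recent_match_prob = vl_recent_match_prob,
         pickup_recent_match_prob = pickup_recent_match_prob,
         pickup_drug_error = pickup_drug_error,
         last_visit_match_prob = last_visit_match_prob,
         alert_effect = alert_effect, covariate_effects = covariate_effects,
         paper_vl_record_prob = paper_vl_record_prob,
         n_vl_probs = n_vl_probs,
         regimen2_prevalence = regimen2_prevalence,
         regimen3_prevalence = regimen3_prevalence),
    class = "dqa_simulation_config"
  )
}

#' Noiseless variant of a simulation configuration
#'
#' All error processes off: every field filled, every timeliness probability
#' 1, no transcription errors. The two sources then agree cell for cell and
#' every metric is perfect — the generator's identity limit, useful for
#' pipeline smoke tests.
#'
#' @param seed Integer seed (chart allocation and truth values still draw
#'   from it).
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `dqa_simulation_config`.
#' @export
noiseless_config <- function(seed, ...) {
  prof <- study_variable_profile()
  prof$paper_fill <- ifelse(is.na(prof$paper_fill), NA, 1)
  prof$ehr_fill <- ifelse(is.na(prof$ehr_fill), NA, 1)
  prof$match_given_both <- ifelse(is.na(prof$match_given_both), NA, 1)
  simulation_config(
    seed = seed, variable_profile = prof, sentinel_date_rate = 0,
    regimen_split_prob = 0, vl_decimal_prob = 0, ehr_vl_old_entry_prob = 1,
    vl_date_error = 0, vl_value_error = 0, vl_recent_match_prob = 1,
    pickup_recent_match_prob = 1, pickup_drug_error = 0,
    last_visit_match_prob = 1,
    alert_effect = 1, covariate_effects = c(availability = 0,
                                            tech_experience = 0),
    paper_vl_record_prob = 1, n_vl_probs = c(0, 0, 0, 1),
    regimen2_prevalence = 1, regimen3_prevalence = 1, ...)
}

# Allocate per-facility chart counts within range summing exactly to total.
allocate_charts <- function(n_fac, range, total, sd = 8.8) {
  sizes <- round(stats::rnorm(n_fac, mean = total / n_fac, sd = sd))
  sizes <- pmin(pmax(sizes, range[1]), range[2])
  gap <- total - sum(sizes)
  while (gap != 0) {
    step <- sign(gap)
    room <- if (step > 0) which(sizes < range[2]) else which(sizes > range[1])
    i <- if (length(room) > 1) sample(room, 1) else room[1]
    sizes[i] <- sizes[i] + step
    gap <- gap - step
  }
  sizes
}

arv_formulary <- function() {
  c("tenofovir(300)+lamivudine(300)+efavirenz(600)",
    "tenofovir(300)+lamivudine(300)+dolutegravir(50)",
    "zidovudine(300)+lamivudine(150)+nevirapine(200)",
    "abacavir(600)+lamivudine(300)+efavirenz(600)",
    "tenofovir(300)+emtricitabine(200)+lopinavir(400)",
    "zidovudine(300)+lamivudine(150)+atazanavir(300)")
}

# Render a canonical regimen id as a human-entered string. split=TRUE uses
# the "A (x) + B (y) and C (z)" dialect (same drugs, different separators).
render_regimen <- function(canon, split = rep(FALSE, length(canon))) {
  out <- character(length(canon))
  for (u in unique(canon[!is.na(canon)])) {
    comps <- strsplit(u, "+", fixed = TRUE)[[1]]
    pretty <- vapply(comps, function(cp) {
      m <- regmatches(cp, regexec("^(.*)\\(([0-9.]+)\\)$", cp))[[1]]
      nm <- m[2]
      substr(nm, 1, 1) <- toupper(substr(nm, 1, 1))
      paste0(nm, " (", m[3], ")")
    }, character(1))
    joined <- paste(pretty, collapse = " + ")
    if (length(pretty) > 2) {
      split_form <- paste0(paste(pretty[-length(pretty)], collapse = " + "),
                           " and ", pretty[length(pretty)])
    } else {
      split_form <- joined
    }
    sel <- !is.na(canon) & canon == u
    out[sel] <- ifelse(split[sel], split_form, joined)
  }
  out[is.na(canon)] <- NA_character_
  out
}

# Random transcription offsets in days: within 30 days with prob
# small_frac, otherwise 31..400, random sign, never zero.
date_offsets <- function(n, small_frac) {
  small <- stats::runif(n) < small_frac
  mag <- ifelse(small, sample(1:30, n, replace = TRUE),
                sample(31:400, n, replace = TRUE))
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a synthetic dual-source audit dataset
#'
#' Draws facility profiles, per-patient ground truth for all 28 variables,
#' and the two observed transcriptions (paper chart and EHR) under the
#' configured error processes: per-variable missingness (with sentinel-date
#' rendering), independent transcription errors on the EHR side,
#' EHR staleness for repeated dates (last visit, drug pickups), an EHR lag
#' process for viral loads in which recent results reach the EHR with low
#' probability — raised by `alert_effect` at alert facilities — plus regimen
#' separator dialects and viral-load decimal precision variants. Every
#' observed-vs-truth discrepancy is labelled in the ground-truth sidecar.
#'
#' The output is deterministic given `cfg$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `dqa_simulation`: `records` (record-pair tibble,
#'   one row per patient), `facilities` (profile tibble with arm, alert
#'   tier, survey covariates), `truth` (list with `values`, the true wide
#'   table, and `error_labels`, a long tibble of injected errors:
#'   `patient_id`, `variable`, `source`, `label`).
#' @examples
#' sim <- simulate_dqa(simulation_config(seed = 1, n_facilities = 4,
#'                                       total_records = 200))
#' nrow(sim$records)
#' @export
simulate_dqa <- function(cfg) {
  stopifnot(inherits(cfg, "dqa_simulation_config"))
  with_preserved_seed(cfg$seed, simulate_dqa_impl(cfg))
}

simulate_dqa_impl <- function(cfg) {
  n_fac <- cfg$n_facilities
  collection <- cfg$collection_date
  cutoff <- cfg$cutoff_date
  prof <- cfg$variable_profile

  ## facilities -------------------------------------------------------------
  facility_id <- sprintf("F%02d", seq_len(n_fac))
  n_int <- round(n_fac * cfg$intervention_fraction)
  arm <- sample(rep(c("intervention", "control"), c(n_int, n_fac - n_int)))
  alert_tier <- ifelse(arm == "intervention", 1L, 0L)
  int_idx <- which(arm == "intervention")
  n_alert <- round(length(int_idx) * cfg$vl_alert_fraction)
  alert_idx <- if (n_alert > 0) sample(int_idx, n_alert) else integer(0)
  alert_tier[alert_idx] <- 2L
  if (n_alert >= 2) alert_tier[sample(alert_idx, floor(n_alert / 2))] <- 3L
  ehr_availability <- sample(1:5, n_fac, TRUE, prob = c(.1, .2, .4, .2, .1))
  tech_experience <- sample(0:4, n_fac, TRUE, prob = c(.1, .2, .4, .2, .1))
  years_ehr_use <- round(stats::runif(n_fac, 1, 8), 1)
  facilities <- tibble::tibble(facility_id, arm, alert_tier,
                               ehr_availability, tech_experience,
                               years_ehr_use)
  district <- paste0("district_", ceiling(seq_len(n_fac) / 5))
  sector <- paste0("sector_", seq_len(n_fac))

  charts <- allocate_charts(n_fac, cfg$charts_range, cfg$total_records)
  n <- sum(charts)
  fac_of <- rep(seq_len(n_fac), charts)
  patient_id <- sprintf("P%05d", seq_len(n))
  is_alert <- alert_tier[fac_of] >= 2

  # record-level EHR quality multiplier (mean 1 over symmetric covariates)
  ce <- cfg$covariate_effects
  eta <- ce[["availability"]] * (ehr_availability[fac_of] - 3) +
    ce[["tech_experience"]] * (tech_experience[fac_of] - 2)
  mult <- 2 * stats::plogis(-eta)

  labels <- list()
  note <- function(idx, variable, source, label) {
    if (length(idx) > 0 && any(idx)) {
      labels[[length(labels) + 1]] <<- tibble::tibble(
        patient_id = patient_id[which(idx)], variable = variable,
        source = source, label = label)
    }
  }

  ## ground truth -----------------------------------------------------------
  days <- function(lo, hi) floor(stats::runif(n, lo, hi + 1))
  truth <- list()
  truth$date_of_birth <- collection - days(18 * 365, 70 * 365)
  truth$gender <- sample(c("F", "M"), n, TRUE, prob = c(0.62, 0.38))
  truth$health_center_district <- district[fac_of]
  truth$health_center_sector <- sector[fac_of]
  truth$health_center_name <- facility_id[fac_of]
  truth$date_of_last_visit <- collection - days(1, 90)
  truth$date_first_positive_hiv_test <- collection - days(365, 14 * 365)
  truth$date_enrollment_hiv_care <- truth$date_first_positive_hiv_test + days(0, 90)
  truth$date_first_art <- truth$date_enrollment_hiv_care + days(0, 60)
  truth$initial_who_stage <- as.character(sample(1:4, n, TRUE,
                                                 prob = c(.4, .3, .2, .1)))
  form <- arv_formulary()
  reg1 <- sample(form[1:4], n, TRUE)
  truth$regimen1_start_date <- truth$date_first_art
  truth$regimen1_drugs <- reg1
  has_reg2 <- stats::runif(n) < cfg$regimen2_prevalence
  reg2 <- ifelse(has_reg2, sample(form[5:6], n, TRUE), NA_character_)
  truth$regimen2_start_date <- pmin(truth$regimen1_start_date + days(365, 5 * 365),
                                    collection - 60)
  truth$regimen2_start_date[!has_reg2] <- NA
  truth$regimen2_drugs <- reg2
  has_reg3 <- stats::runif(n) < cfg$regimen3_prevalence
  truth$regimen3_start_date <- pmin(truth$regimen2_start_date + days(180, 2 * 365),
                                    collection - 30)
  truth$regimen3_start_date[!has_reg3] <- NA
  truth$regimen3_drugs <- ifelse(has_reg3, form[6], NA_character_)
  current_reg <- ifelse(has_reg2, reg2, reg1)
  truth$drug_pickup1_date <- truth$date_of_last_visit
  truth$drug_pickup1_drugs <- current_reg
  truth$drug_pickup2_date <- truth$drug_pickup1_date - days(28, 35)
  truth$drug_pickup2_drugs <- current_reg
  truth$drug_pickup3_date <- truth$drug_pickup2_date - days(28, 35)
  truth$drug_pickup3_drugs <- current_reg

  n_vl <- sample(0:3, n, TRUE, prob = cfg$n_vl_probs)
  vd1 <- collection - days(0, 364)
  vd2 <- vd1 - days(180, 365)
  vd3 <- vd2 - days(180, 365)
  vdate <- cbind(vd1, vd2, vd3)
  vval <- matrix(round(10^stats::runif(3 * n, log10(20), 6), 1), n, 3)
  for (s in 1:3) {
    drop <- n_vl < s
    vdate[drop, s] <- NA
    vval[drop, s] <- NA
  }
  truth$viral_load1_date <- as.Date(vdate[, 1], origin = "1970-01-01")
  truth$viral_load1_value <- vval[, 1]
  truth$viral_load2_date <- as.Date(vdate[, 2], origin = "1970-01-01")
  truth$viral_load2_value <- vval[, 2]
  truth$viral_load3_date <- as.Date(vdate[, 3], origin = "1970-01-01")
  truth$viral_load3_value <- vval[, 3]

  ## observation helpers ----------------------------------------------------
  kind_of <- stats::setNames(dqa_variables()$kind, dqa_variables()$name)
  class_of <- stats::setNames(dqa_variables()$date_class, dqa_variables()$name)

  render <- function(v, kind) {
    if (kind == "date") fmt_date(v)
    else if (kind == "viral_load") ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
    else ifelse(is.na(v), "", as.character(v))
  }
  blank_date <- function(cells, idx, variable, source) {
    # missing dates: sentinel placeholder with configured prob, else blank
    sent <- idx & (stats::runif(n) < cfg$sentinel_date_rate)
    cells[sent] <- "1980-01-01"
    cells[idx & !sent] <- ""
    note(sent, variable, source, "sentinel")
    note(idx & !sent, variable, source, "missing")
    cells
  }
  apply_missing <- function(cells, fill_p, variable, source, scale = 1) {
    miss_p <- pmin(1, (1 - fill_p) * scale)
    idx <- stats::runif(n) < miss_p
    if (kind_of[[variable]] == "date") {
      cells <- blank_date(cells, idx, variable, source)
    } else {
      cells[idx] <- ""
      note(idx, variable, source, "missing")
    }
    cells
  }
  # transcribed dates stay plausible: offsets that would cross the
  # abstraction date are reflected backwards
  clamp_date <- function(v, off) {
    cand <- v + off
    flip <- !is.na(cand) & as.numeric(cand) > as.numeric(collection)
    cand[flip] <- v[flip] - abs(off[flip])
    cand
  }
  perturb <- function(v, variable) {
    kind <- kind_of[[variable]]
    if (kind == "date") {
      sf <- cfg$small_offset_frac[[if (identical(class_of[[variable]], "repeated")) "repeated" else "one_off"]]
      clamp_date(v, date_offsets(n, sf))
    } else if (kind == "drug_regimen") {
      alt <- sample(arv_formulary(), n, TRUE)
      same <- !is.na(v) & alt == v
      alt[same] <- arv_formulary()[(match(v[same], arv_formulary()) %% 6) + 1]
      alt
    } else if (variable == "gender") {
      ifelse(v == "F", "M", "F")
    } else if (variable == "initial_who_stage") {
      as.character((as.integer(v) %% 4) + 1)
    } else {
      paste0(v, "_x")
    }
  }

  paper <- list()
  ehr <- list()
  pr <- function(var) prof[prof$name == var, , drop = FALSE]

  ## direct and conditional variables ---------------------------------------
  for (var in prof$name[prof$mechanism %in% c("direct", "conditional")]) {
    p <- pr(var)
    kind <- kind_of[[var]]
    tv <- truth[[var]]
    absent <- is.na(tv)

    pcells <- render(tv, kind)
    if (kind == "drug_regimen") pcells <- render_regimen(tv)
    err_p <- if (is.na(p$match_given_both)) 0 else pmin(1, (1 - p$match_given_both) * mult)
    err <- stats::runif(n) < err_p & !absent
    ev <- tv
    if (any(err)) {
      pe <- perturb(tv, var)
      ev[err] <- pe[err]
      note(err, var, "ehr", "transcribed")
    }
    if (kind == "drug_regimen") {
      split <- stats::runif(n) < cfg$regimen_split_prob & !is.na(ev)
      ecells <- render_regimen(ev, split)
      note(split, var, "ehr", "split")
    } else {
      ecells <- render(ev, kind)
    }

    pcells <- apply_missing(pcells, p$paper_fill, var, "paper")
    ecells <- apply_missing(ecells, p$ehr_fill, var, "ehr", scale = mult)
    if (p$mechanism == "conditional") {
      # rare treatment lines: truth absent renders blank in both sources
      pcells[absent] <- ""
      ecells[absent] <- ""
    }
    paper[[var]] <- pcells
    ehr[[var]] <- ecells
  }

  ## last visit: timely vs stale EHR date -----------------------------------
  {
    p <- pr("date_of_last_visit")
    tv <- truth$date_of_last_visit
    timely <- stats::runif(n) < cfg$last_visit_match_prob
    ev <- tv
    ev[!timely] <- truth$drug_pickup2_date[!timely]
    note(!timely, "date_of_last_visit", "ehr", "lagged")
    paper$date_of_last_visit <- apply_missing(fmt_date(tv), p$paper_fill,
                                              "date_of_last_visit", "paper")
    ehr$date_of_last_visit <- apply_missing(fmt_date(ev), p$ehr_fill,
                                            "date_of_last_visit", "ehr",
                                            scale = mult)
  }

  ## drug pickups: timely EHR mirrors truth, stale EHR shifted one back -----
  {
    q <- pmin(1, cfg$pickup_recent_match_prob *
                ifelse(is_alert, cfg$alert_effect, 1))
    timely <- stats::runif(n) < q
    td <- list(truth$drug_pickup1_date, truth$drug_pickup2_date,
               truth$drug_pickup3_date)
    tg <- list(truth$drug_pickup1_drugs, truth$drug_pickup2_drugs,
               truth$drug_pickup3_drugs)
    # stale EHR: slot k holds the (k+1)-th pickup; oldest slot one cycle older
    ed <- list(td[[2]], td[[3]], td[[3]] - days(28, 35))
    eg <- list(tg[[2]], tg[[3]], tg[[3]])
    drug_err <- stats::runif(n) < pmin(1, cfg$pickup_drug_error * mult)
    for (s in 1:3) {
      dvar <- sprintf("drug_pickup%d_date", s)
      gvar <- sprintf("drug_pickup%d_drugs", s)
      date_s <- as.Date(ifelse(timely, td[[s]], ed[[s]]), origin = "1970-01-01")
      drugs_s <- ifelse(timely, tg[[s]], eg[[s]])
      note(!timely, dvar, "ehr", "lagged")
      err_s <- drug_err & !is.na(drugs_s)
      if (any(err_s)) {
        drugs_s[err_s] <- perturb(drugs_s, gvar)[err_s]
        note(err_s, gvar, "ehr", "transcribed")
      }
      split <- stats::runif(n) < cfg$regimen_split_prob & !is.na(drugs_s)
      note(split, gvar, "ehr", "split")
      paper[[dvar]] <- apply_missing(fmt_date(td[[s]]), pr(dvar)$paper_fill,
                                     dvar, "paper")
      paper[[gvar]] <- apply_missing(render_regimen(tg[[s]]),
                                     pr(gvar)$paper_fill, gvar, "paper")
      ehr[[dvar]] <- apply_missing(fmt_date(date_s), pr(dvar)$ehr_fill,
                                   dvar, "ehr", scale = mult)
      ehr[[gvar]] <- apply_missing(render_regimen(drugs_s, split),
                                   pr(gvar)$ehr_fill, gvar, "ehr",
                                   scale = mult)
    }
  }

  ## viral loads ------------------------------------------------------------
  {
    recent <- !is.na(vdate[, 1]) & vdate[, 1] >= as.numeric(cutoff)
    q <- pmin(1, cfg$vl_recent_match_prob *
                ifelse(is_alert, cfg$alert_effect, 1))
    # inclusion of each truth entry in the EHR
    inc <- matrix(FALSE, n, 3)
    inc[, 1] <- !is.na(vdate[, 1]) &
      ifelse(recent, stats::runif(n) < q,
             stats::runif(n) < cfg$ehr_vl_old_entry_prob)
    timely1 <- inc[, 1] & recent
    for (s in 2:3) {
      inc[, s] <- !is.na(vdate[, s]) &
        stats::runif(n) < cfg$ehr_vl_old_entry_prob
    }
    note(recent & !inc[, 1], "viral_load1_date", "ehr", "lagged")

    # EHR copies: timely recent entries are exact; others may err
    edate <- vdate
    evalue <- round(vval)
    derr <- matrix(stats::runif(3 * n), n, 3) < pmin(1, cfg$vl_date_error * mult)
    verr <- matrix(stats::runif(3 * n), n, 3) < pmin(1, cfg$vl_value_error * mult)
    derr[timely1, 1] <- FALSE
    verr[timely1, 1] <- FALSE
    for (s in 1:3) {
      off <- date_offsets(n, cfg$small_offset_frac[["repeated"]])
      cand <- clamp_date(vdate[, s], off)
      edate[derr[, s] & inc[, s], s] <- cand[derr[, s] & inc[, s]]
      # guaranteed outside the 1 copy/mL tolerance
      wrong <- round(vval[, s]) + 2 + floor(stats::runif(n, 0, 200))
      evalue[verr[, s] & inc[, s], s] <- wrong[verr[, s] & inc[, s]]
      note(derr[, s] & inc[, s], sprintf("viral_load%d_date", s), "ehr",
           "transcribed")
      note(verr[, s] & inc[, s], sprintf("viral_load%d_value", s), "ehr",
           "transcribed")
    }

    # paper records each truth entry with prob paper_vl_record_prob,
    # keeping the decimal with prob vl_decimal_prob
    prec <- matrix(stats::runif(3 * n), n, 3) < cfg$vl_decimal_prob
    pinc <- matrix(stats::runif(3 * n), n, 3) < cfg$paper_vl_record_prob &
      !is.na(vdate)
    pval_obs <- ifelse(prec, vval, round(vval))
    for (s in 1:3) {
      note(pinc[, s] & prec[, s], sprintf("viral_load%d_value", s), "paper",
           "precision")
      note(!is.na(vdate[, s]) & !pinc[, s], sprintf("viral_load%d_value", s),
           "paper", "missing")
    }

    # compress included entries into slots 1..3 (newest first)
    compress <- function(dates, values, keep) {
      k <- keep & !is.na(dates)
      i1 <- ifelse(k[, 1], 1L, ifelse(k[, 2], 2L, ifelse(k[, 3], 3L, NA_integer_)))
      i2 <- ifelse(k[, 1] & k[, 2], 2L,
                   ifelse((k[, 1] | k[, 2]) & k[, 3], 3L, NA_integer_))
      i3 <- ifelse(k[, 1] & k[, 2] & k[, 3], 3L, NA_integer_)
      pick <- function(m, idx) {
        out <- rep(NA_real_, n)
        ok <- !is.na(idx)
        out[ok] <- m[cbind(which(ok), idx[ok])]
        out
      }
      list(d = cbind(pick(dates, i1), pick(dates, i2), pick(dates, i3)),
           v = cbind(pick(values, i1), pick(values, i2), pick(values, i3)))
    }
    e <- compress(edate, evalue, inc)
    p <- compress(vdate, pval_obs, pinc)
    # empty VL slots stay blank (the sentinel habit concerns unknown dates
    # of events known to have happened, exercised on the milestone dates)
    for (s in 1:3) {
      dvar <- sprintf("viral_load%d_date", s)
      vvar <- sprintf("viral_load%d_value", s)
      paper[[dvar]] <- fmt_date(as.Date(p$d[, s], origin = "1970-01-01"))
      paper[[vvar]] <- render(p$v[, s], "viral_load")
      ehr[[dvar]] <- fmt_date(as.Date(e$d[, s], origin = "1970-01-01"))
      ehr[[vvar]] <- render(e$v[, s], "viral_load")
    }
  }

  ## assemble ---------------------------------------------------------------
  records <- tibble::tibble(patient_id = patient_id,
                            facility_id = facility_id[fac_of])
  for (var in dqa_variables()$name) {
    records[[paste0("paper_", var)]] <- paper[[var]]
    records[[paste0("ehr_", var)]] <- ehr[[var]]
  }

  truth_tbl <- tibble::as_tibble(c(list(patient_id = patient_id,
                                        facility_id = facility_id[fac_of]),
                                   truth))
  error_labels <- if (length(labels) > 0) {
    dplyr::bind_rows(labels)
  } else {
    tibble::tibble(patient_id = character(0), variable = character(0),
                   source = character(0), label = character(0))
  }

  structure(list(records = records, facilities = facilities,
                 truth = list(values = truth_tbl, error_labels = error_labels),
                 config = cfg),
            class = "dqa_simulation")
}

#' @export
print.dqa_simulation <- function(x, ...) {
  cat("Synthetic dual-source audit dataset\n")
  cat(sprintf("  %d records across %d facilities (seed %d)\n",
              nrow(x$records), nrow(x$facilities), x$config$seed))
  cat(sprintf("  %d injected error labels\n", nrow(x$truth$error_labels)))
  invisible(x)
}

#' Recover generative rates from an observed dataset
#'
#' Truth-free validation harness: runs the package's own completeness and
#' matching metrics over a simulated record-pair table so the estimates can
#' be compared with the rates the generator was configured with.
#'
#' @param records A record-pair tibble.
#' @param cfg A [missingness_config()].
#' @return A list with `completeness` (both sources) and `matching` tibbles.
#' @export
recover_parameters <- function(records, cfg = missingness_config()) {
  list(
    completeness = dplyr::bind_rows(
      completeness(records, source = "paper", cfg = cfg),
      completeness(records, source = "ehr", cfg = cfg)
    ),
    matching = matching(records, cfg = cfg)
  )
}
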