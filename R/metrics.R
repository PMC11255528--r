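#' @importFrom dplyr %>%
NULL

# Logical matrix (records x variables) of missingness for one source.
missing_matrix <- function(records, cfg, source = c("paper", "ehr"),
                           variables = NULL) {
  source <- match.arg(source)
  vars <- dqa_variables()
  if (!is.null(variables)) {
    stop_unknown_variable(variables)
    vars <- vars[match(variables, vars$name), , drop = FALSE]
  }
  out <- matrix(NA, nrow(records), nrow(vars),
                dimnames = list(NULL, vars$name))
  for (i in seq_len(nrow(vars))) {
    col <- paste0(source, "_", vars$name[i])
    out[, i] <- is_missing(records[[col]], vars$kind[i], cfg,
                           hiv_related = vars$hiv_related[i],
                           dob = vars$name[i] == "date_of_birth")
  }
  out
}

# Logical vector: do the two sources match on `variable`? NA where either
# side is missing.
match_vector <- function(records, variable, cfg) {
  stop_unknown_variable(variable)
  vars <- dqa_variables()
  kind <- vars$kind[vars$name == variable]
  hiv <- vars$hiv_related[vars$name == variable]
  a <- records[[paste0("paper_", variable)]]
  b <- records[[paste0("ehr_", variable)]]
  ma <- is_missing(a, kind, cfg, hiv_related = hiv,
                   dob = variable == "date_of_birth")
  mb <- is_missing(b, kind, cfg, hiv_related = hiv,
                   dob = variable == "date_of_birth")
  out <- rep(NA, nrow(records))
  both <- !ma & !mb
  if (any(both)) out[both] <- values_match(a[both], b[both], kind, cfg)
  out
}

metric_row <- function(variable, source, numerator, denominator, threshold) {
  frac <- if (denominator > 0) numerator / denominator else NA_real_
  tibble::tibble(
    variable = variable, source = source,
    numerator = numerator, denominator = denominator,
    fraction = frac,
    high_quality = if (is.na(frac)) NA else frac >= threshold
  )
}

#' Completeness of a variable in one source
#'
#' The fraction of records carrying a non-missing value for the variable in
#' the named source, flagged high quality at the LQAS threshold (default
#' >= 85%).
#'
#' @param records A record-pair tibble (see [read_record_pairs()] or
#'   [simulate_dqa()]).
#' @param variables Variable names; default all 28.
#' @param source `"paper"` or `"ehr"`.
#' @param cfg A [missingness_config()].
#' @param threshold High-quality threshold on the fraction (applied with
#'   `>=`).
#' @return A tibble with one row per variable: `variable`, `source`,
#'   `numerator` (records filled), `denominator` (all records), `fraction`,
#'   `high_quality`.
#' @export
completeness <- function(records, variables = NULL,
                         source = c("paper", "ehr"),
                         cfg = missingness_config(), threshold = 0.85) {
  source <- match.arg(source)
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  if (is.null(variables)) variables <- dqa_variables()$name
  mm <- missing_matrix(records, cfg, source, variables)
  dplyr::bind_rows(lapply(variables, function(v) {
    metric_row(v, source, sum(!mm[, v]), nrow(records), threshold)
  }))
}

#' Matching of a variable between the two sources
#'
#' Among records complete in both sources, the fraction whose standardized
#' values are equal under the kind's rule ([values_match()]). When no record
#' is complete in both sources the fraction is undefined and reported `NA`.
#'
#' @inheritParams completeness
#' @return A tibble with one row per variable: `variable`, `numerator`
#'   (matches), `denominator` (complete in both), `fraction`,
#'   `high_quality`.
#' @export
matching <- function(records, variables = NULL, cfg = missingness_config(),
                     threshold = 0.85) {
  if (nrow(records) == 0) stop("empty record collection", call. = FALSE)
  if (is.null(variables)) variables <- dqa_variables()$name
  dplyr::bind_rows(lapply(variables, function(v) {
    mv <- match_vector(records, v, cfg)
    r <- metric_row(v, NA_character_, sum(mv, na.rm = TRUE), sum(!is.na(mv)),
                    threshold)
    r$source <- NULL
    r
  }))
}

#' Per-variable concordance status of each record
#'
#' For each of the 15 concordance variables, a record is
#' `"concordant_match"` when both sources hold equal standardized values,
#' `"concordant_both_missing"` when the value is missing in both sources,
#' and `"discordant"` otherwise (missing in exactly one source, or present
#' in both with unequal values).
#'
#' With `vl = "aligned"` (default) the most-recent viral-load value and date
#' are taken from the date-aligned series — each source contributes its
#' entry at the latest date observed in either source — so that an EHR
#' lagging one result behind scores as missing rather than spuriously
#' mismatching. `vl = "positional"` compares the raw slot-1 entries.
#'
#' @inheritParams completeness
#' @param vl `"aligned"` or `"positional"` handling of the most-recent
#'   viral load.
#' @return A character matrix, records x 15 concordance variables.
#' @export
concordance_status <- function(records, cfg = missingness_config(),
                               vl = c("aligned", "positional")) {
  vl <- match.arg(vl)
  cvars <- concordance_variables()
  n <- nrow(records)
  status <- matrix(NA_character_, n, length(cvars),
                   dimnames = list(NULL, cvars))

  vars <- dqa_variables()
  for (v in cvars) {
    kind <- vars$kind[vars$name == v]
    hiv <- vars$hiv_related[vars$name == v]
    a <- records[[paste0("paper_", v)]]
    b <- records[[paste0("ehr_", v)]]
    ma <- is_missing(a, kind, cfg, hiv_related = hiv,
                     dob = v == "date_of_birth")
    mb <- is_missing(b, kind, cfg, hiv_related = hiv,
                     dob = v == "date_of_birth")
    st <- rep("discordant", n)
    st[ma & mb] <- "concordant_both_missing"
    both <- !ma & !mb
    if (any(both)) {
      eq <- values_match(a[both], b[both], kind, cfg)
      st[both][which(eq)] <- "concordant_match"
    }
    status[, v] <- st
  }

  if (vl == "aligned" && n > 0) {
    al <- vl_aligned_recent(records, cfg)
    num_status <- function(pv, ev, tol) {
      st <- rep("discordant", n)
      bm <- is.na(pv) & is.na(ev)
      st[bm] <- "concordant_both_missing"
      both <- !is.na(pv) & !is.na(ev)
      st[both & abs(pv - ev) <= tol + 1e-9] <- "concordant_match"
      st
    }
    status[, "viral_load1_value"] <- num_status(al$paper_value, al$ehr_value, 1)
    status[, "viral_load1_date"] <- num_status(as.numeric(al$paper_date),
                                               as.numeric(al$ehr_date), 0)
  }
  status
}

#' Per-record concordance scores
#'
#' The concordance score of a record is the number of the 15 designated
#' variables that are concordant — equal standardized values in both
#' sources, or missing in both sources (a both-missing field is counted as
#' agreement). Scores range 0..15.
#'
#' @inheritParams concordance_status
#' @return A tibble with `patient_id`, `facility_id` (when present in
#'   `records`) and integer `score`.
#' @export
concordance_score <- function(records, cfg = missingness_config(),
                              vl = c("aligned", "positional")) {
  status <- concordance_status(records, cfg, vl)
  out <- tibble::tibble(
    patient_id = records$patient_id,
    score = as.integer(rowSums(status != "discordant"))
  )
  if ("facility_id" %in% names(records)) {
    out <- tibble::add_column(out, facility_id = records$facility_id,
                              .after = "patient_id")
  }
  out
}

#' Distribution of date disagreements
#'
#' Among records complete in both sources with unequal dates for the given
#' variable, buckets the absolute paper-EHR difference in days. The default
#' buckets follow the audit convention of "within 1 month" (30 days) and
#' "within 3 months" (90 days).
#'
#' @inheritParams completeness
#' @param variable A single date-kind variable name.
#' @param breaks Increasing day cut points defining the cumulative buckets.
#' @return A tibble with one row per bucket: `bucket` label, `n`,
#'   `fraction` (of mismatching records). Zero rows when no mismatches.
#' @export
date_error_profile <- function(records, variable, cfg = missingness_config(),
                               breaks = c(30, 90)) {
  stop_unknown_variable(variable)
  vars <- dqa_variables()
  if (vars$kind[vars$name == variable] != "date") {
    stop("date_error_profile requires a date variable, got: ", variable,
         call. = FALSE)
  }
  hiv <- vars$hiv_related[vars$name == variable]
  a <- records[[paste0("paper_", variable)]]
  b <- records[[paste0("ehr_", variable)]]
  ma <- is_missing(a, "date", cfg, hiv_related = hiv,
                   dob = variable == "date_of_birth")
  mb <- is_missing(b, "date", cfg, hiv_related = hiv,
                   dob = variable == "date_of_birth")
  da <- parse_dqa_date(a)
  db <- parse_dqa_date(b)
  keep <- !ma & !mb & da != db
  diffs <- abs(as.numeric(da[keep] - db[keep]))
  if (length(diffs) == 0) {
    return(tibble::tibble(bucket = character(0), n = integer(0),
                          fraction = numeric(0)))
  }
  edges <- c(0, breaks, Inf)
  labels <- c(paste0("<=", breaks, "d"), paste0(">", breaks[length(breaks)], "d"))
  idx <- cut(diffs, edges, labels = labels, right = TRUE)
  tab <- table(idx)
  tibble::tibble(bucket = names(tab), n = as.integer(tab),
                 fraction = as.numeric(tab) / length(diffs))
}

#' Facility-level data quality summary
#'
#' Breaks the dataset down by health facility: per-facility record counts,
#' mean and SD of the concordance score, the score as a fraction of its
#' maximum (15), the high-quality flag at the threshold, and per-facility
#' per-variable matching fractions. Dataset-level metrics equal the
#' record-weighted combination of the facility rows.
#'
#' @inheritParams concordance_score
#' @param facilities A facility-profile tibble with a `facility_id` column
#'   covering every facility appearing in `records`.
#' @param threshold High-quality threshold applied to the concordance
#'   fraction (score / 15) and the matching fractions.
#' @param match_variables Variables for the per-facility matching table;
#'   default the 15 concordance variables.
#' @return A list with `concordance` (one row per facility) and `matching`
#'   (facility x variable long tibble).
#' @export
facility_summary <- function(records, facilities, cfg = missingness_config(),
                             threshold = 0.85,
                             match_variables = concordance_variables()) {
  orphans <- setdiff(unique(records$facility_id), facilities$facility_id)
  if (length(orphans) > 0) {
    stop("facility_id values absent from the facility table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  scores <- concordance_score(records, cfg)
  conc <- scores %>%
    dplyr::group_by(.data$facility_id) %>%
    dplyr::summarise(
      n_records = dplyr::n(),
      mean_concordance = mean(.data$score),
      sd_concordance = stats::sd(.data$score),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      concordance_fraction = .data$mean_concordance / 15,
      high_quality = .data$concordance_fraction >= threshold
    )

  match_l <- lapply(match_variables, function(v) {
    mv <- match_vector(records, v, cfg)
    tibble::tibble(facility_id = records$facility_id, variable = v,
                   m = mv) %>%
      dplyr::group_by(.data$facility_id, .data$variable) %>%
      dplyr::summarise(numerator = sum(.data$m, na.rm = TRUE),
                       denominator = sum(!is.na(.data$m)),
                       .groups = "drop")
  })
  match_tbl <- dplyr::bind_rows(match_l) %>%
    dplyr::mutate(
      fraction = ifelse(.data$denominator > 0,
                        .data$numerator / .data$denominator, NA_real_),
      high_quality = ifelse(is.na(.data$fraction), NA,
                            .data$fraction >= threshold)
    ) %>%
    dplyr::arrange(.data$facility_id)
  list(concordance = conc, matching = match_tbl)
}

#' LQAS chart sample size for a facility
#'
#' Maps a facility's patient volume to the number of charts to audit, in the
#' 48-76 range of the lot-quality-assurance-sampling protocol. The default
#' step is a linear interpolation between 48 charts at the low end of the
#' volume range and 76 at the high end, clamped so a facility never samples
#' more charts than it has patients. Monotone nondecreasing in volume.
#'
#' @param patient_volume Positive integer vector of patient counts.
#' @param min_n,max_n Sample-size bounds of the protocol.
#' @param volume_range Volumes at which the interpolation reaches `min_n`
#'   and `max_n`.
#' @return Integer vector of sample sizes.
#' @examples
#' lqas_sample_size(c(30, 60, 10000))
#' @export
lqas_sample_size <- function(patient_volume, min_n = 48, max_n = 76,
                             volume_range = c(500, 3000)) {
  if (any(patient_volume < 1)) stop("patient_volume must be >= 1", call. = FALSE)
  v <- pmin(pmax(patient_volume, volume_range[1]), volume_range[2])
  base <- stats::approx(volume_range, c(min_n, max_n), xout = v)$y
  size <- pmin(round(base), max_n, patient_volume)
  size <- pmax(size, pmin(patient_volume, min_n))
  as.integer(size)
}
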