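#' Run configuration for the assessment pipeline
#'
#' Bundles the knobs of a full run: the missingness rules, the high-quality
#' threshold, the post-intervention cutoff, the statistics options and the
#' seed used by the bootstrap. The configuration is echoed into the report
#' so every output is reproducible from (inputs, config).
#'
#' @param missingness A [missingness_config()].
#' @param threshold LQAS high-quality threshold (default 0.85, applied with
#'   `>=`).
#' @param cutoff_date First day of the post-intervention period.
#' @param continuity Yates continuity correction for the 2x2 chi-square.
#' @param bootstrap_reps Bootstrap resamples for the phi CI.
#' @param bonferroni_m Number of covariate correlations tested together.
#' @param vl_concordance `"aligned"` or `"positional"` most-recent viral
#'   load in the concordance score.
#' @param seed Seed for the bootstrap CI.
#' @return A list of class `dqa_run_config`.
#' @export
dqa_run_config <- function(missingness = missingness_config(),
                           threshold = 0.85,
                           cutoff_date = as.Date("2018-07-01"),
                           continuity = TRUE, bootstrap_reps = 2000,
                           bonferroni_m = 3,
                           vl_concordance = c("aligned", "positional"),
                           seed = 1L) {
  stopifnot(inherits(missingness, "dqa_missingness_config"),
            threshold > 0, threshold <= 1)
  structure(list(missingness = missingness, threshold = threshold,
                 cutoff_date = as.Date(cutoff_date), continuity = continuity,
                 bootstrap_reps = bootstrap_reps, bonferroni_m = bonferroni_m,
                 vl_concordance = match.arg(vl_concordance),
                 seed = as.integer(seed)),
            class = "dqa_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level fields mirror [dqa_run_config()] arguments; a nested
#' `missingness` block is forwarded to [missingness_config()].
#'
#' @param path YAML path.
#' @return A `dqa_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$missingness)) {
    m <- raw$missingness
    margs <- list()
    for (f in c("sentinel_dates", "collection_date", "hiv_epoch", "dob_min")) {
      if (!is.null(m[[f]])) margs[[f]] <- as.Date(unlist(m[[f]]))
    }
    if (!is.null(m$na_codes)) margs$na_codes <- as.character(unlist(m$na_codes))
    if (!is.null(m$synonyms)) margs$synonyms <- unlist(m$synonyms)
    args$missingness <- do.call(missingness_config, margs)
  }
  for (f in c("threshold", "continuity", "bootstrap_reps", "bonferroni_m",
              "vl_concordance", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$cutoff_date)) args$cutoff_date <- as.Date(raw$cutoff_date)
  do.call(dqa_run_config, args)
}

safe_or_note <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(note = conditionMessage(e)), class = "dqa_not_estimable")
  })
}

#' @export
print.dqa_not_estimable <- function(x, ...) {
  cat("not estimable:", x$note, "\n")
  invisible(x)
}

#' Run the full data-quality assessment pipeline
#'
#' Computes, in order: per-source completeness of all 28 variables, matching
#' between the sources, per-record concordance scores with a per-facility
#' breakdown, the covariate correlations (EHR availability, technology
#' experience, years of EHR use — Bonferroni-adjusted together), and the
#' alert-effect contingency analyses for viral loads and drug pickups.
#' Stages whose statistics are undefined on the given data (e.g. a
#' zero-variance covariate, or a degenerate 2x2 table on noiseless input)
#' are reported as not-estimable notes rather than aborting the run.
#'
#' @param records Record-pair tibble.
#' @param facilities Facility-profile tibble.
#' @param config A [dqa_run_config()].
#' @return A list of class `dqa_report` with elements `completeness`,
#'   `matching`, `scores`, `facility`, `correlations`, `alert_vl`,
#'   `alert_pickup`, `summary`, `config`.
#' @export
run_dqa_pipeline <- function(records, facilities, config = dqa_run_config()) {
  stopifnot(inherits(config, "dqa_run_config"))
  cfg <- config$missingness
  thr <- config$threshold

  comp <- dplyr::bind_rows(
    completeness(records, source = "paper", cfg = cfg, threshold = thr),
    completeness(records, source = "ehr", cfg = cfg, threshold = thr)
  )
  match_tbl <- matching(records, cfg = cfg, threshold = thr)
  scores <- concordance_score(records, cfg, vl = config$vl_concordance)
  fac <- facility_summary(records, facilities, cfg, threshold = thr)

  cov_tbl <- dplyr::left_join(scores, facilities, by = "facility_id")
  covs <- c("ehr_availability", "tech_experience", "years_ehr_use")
  correlations <- dplyr::bind_rows(lapply(covs, function(cv) {
    res <- safe_or_note(concordance_covariate_correlation(
      cov_tbl$score, cov_tbl[[cv]], m_comparisons = config$bonferroni_m))
    if (inherits(res, "dqa_not_estimable")) {
      tibble::tibble(covariate = cv, r = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, t_stat = NA_real_, df = NA_real_,
                     p_raw = NA_real_, p_adjusted = NA_real_,
                     note = res$note)
    } else {
      tibble::add_column(res, covariate = cv, .before = 1) %>%
        tibble::add_column(note = NA_character_)
    }
  }))

  alert_vl <- safe_or_note(alert_effect_table(
    records, facilities, "vl", config$cutoff_date, cfg,
    phi_seed = config$seed))
  alert_pickup <- safe_or_note(alert_effect_table(
    records, facilities, "pickup", config$cutoff_date, cfg,
    phi_seed = config$seed))

  summary <- list(
    n_records = nrow(records),
    n_facilities = length(unique(records$facility_id)),
    n_variables = nrow(dqa_variables()),
    n_data_cells = nrow(records) * nrow(dqa_variables()) * 2L,
    mean_records_per_facility = nrow(records) /
      length(unique(records$facility_id)),
    mean_concordance = mean(scores$score),
    sd_concordance = stats::sd(scores$score),
    threshold = thr
  )
  structure(list(completeness = comp, matching = match_tbl, scores = scores,
                 facility = fac, correlations = correlations,
                 alert_vl = alert_vl, alert_pickup = alert_pickup,
                 summary = summary, config = config),
            class = "dqa_report")
}

#' @export
print.dqa_report <- function(x, ...) {
  s <- x$summary
  cat("Data-quality assessment report\n")
  cat(sprintf("  %d records, %d facilities, %d data cells\n",
              s$n_records, s$n_facilities, s$n_data_cells))
  cat(sprintf("  mean concordance %.2f (SD %.2f) of 15\n",
              s$mean_concordance, s$sd_concordance))
  n_hq <- sum(x$facility$concordance$high_quality)
  cat(sprintf("  %d/%d facilities at or above the %.0f%% threshold\n",
              n_hq, nrow(x$facility$concordance), 100 * s$threshold))
  invisible(x)
}

pct2 <- function(x) round(100 * x, 2)

#' Write a report bundle to a directory
#'
#' Emits delimited tables mirroring the audit's standard outputs —
#' completeness per variable and source, matching, per-facility concordance,
#' the statistics table, alert-effect group and ranked facility tables —
#' plus a machine-readable `summary.json` embedding the run configuration.
#' All percentages are printed to 2 decimals and are recomputable from the
#' printed counts.
#'
#' @param report A `dqa_report` from [run_dqa_pipeline()].
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_dqa_report <- function(report, dir) {
  stopifnot(inherits(report, "dqa_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(dir, name),
                     row.names = FALSE, na = "")
  }
  comp <- report$completeness
  comp$pct <- pct2(comp$fraction)
  w(comp, "completeness.csv")
  m <- report$matching
  m$pct <- pct2(m$fraction)
  w(m, "matching.csv")
  fc <- report$facility$concordance
  fc$pct <- pct2(fc$concordance_fraction)
  w(fc, "facility_concordance.csv")
  w(report$correlations, "statistics.csv")
  for (fam in c("alert_vl", "alert_pickup")) {
    a <- report[[fam]]
    if (!inherits(a, "dqa_not_estimable")) {
      w(a$group_summary, paste0(fam, "_groups.csv"))
      w(a$facility_pct, paste0(fam, "_facility_ranked.csv"))
    }
  }
  cfg <- report$config
  summary <- c(report$summary, list(
    run_config = list(
      threshold = cfg$threshold,
      cutoff_date = as.character(cfg$cutoff_date),
      continuity = cfg$continuity, bootstrap_reps = cfg$bootstrap_reps,
      bonferroni_m = cfg$bonferroni_m, vl_concordance = cfg$vl_concordance,
      seed = cfg$seed,
      missingness = list(
        sentinel_dates = as.character(cfg$missingness$sentinel_dates),
        collection_date = as.character(cfg$missingness$collection_date),
        hiv_epoch = as.character(cfg$missingness$hiv_epoch),
        dob_min = as.character(cfg$missingness$dob_min),
        na_codes = cfg$missingness$na_codes))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
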