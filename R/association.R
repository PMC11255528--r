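#' Correlation between concordance and a facility covariate
#'
#' Pearson correlation between per-record concordance scores and a facility
#' covariate broadcast to each of the facility's records, with a Fisher-z
#' 95% confidence interval, the t statistic on n-2 degrees of freedom, and a
#' Bonferroni-adjusted p value for `m_comparisons` tests run together.
#' Working at record level follows the study design: each audited chart is
#' one observation, its facility's survey covariate attached.
#'
#' @param concordance_scores Numeric vector of per-record scores.
#' @param covariate Numeric vector, same length (facility covariate
#'   broadcast to records).
#' @param m_comparisons Number of correlations tested together (Bonferroni
#'   multiplier).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `t_stat`, `df`,
#'   `p_raw`, `p_adjusted`.
#' @export
concordance_covariate_correlation <- function(concordance_scores, covariate,
                                              m_comparisons = 1,
                                              conf_level = 0.95) {
  x <- as.numeric(concordance_scores)
  y <- as.numeric(covariate)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in one of the inputs",
         call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  tibble::tibble(
    r = unname(ct$estimate),
    ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
    t_stat = unname(ct$statistic), df = unname(ct$parameter),
    p_raw = ct$p.value,
    p_adjusted = min(1, m_comparisons * ct$p.value)
  )
}

as_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  m
}

#' Chi-square test for a 2x2 table
#'
#' The classical statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with
#' the Yates continuity correction (subtract N/2 from |ad - bc| before
#' squaring, floored at zero) applied by default, and the p value from the
#' chi-square distribution on 1 df. Rows are the groups (e.g. alert /
#' no-alert facilities), columns the outcomes (match / no match).
#'
#' @param a Either a 2x2 matrix of counts, or the top-left cell with `b`,
#'   `c`, `d` giving the remaining cells in reading order.
#' @param b,c,d Remaining cells when `a` is scalar.
#' @param continuity Apply the Yates correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `continuity`.
#' @examples
#' chi_square_2x2(280, 494, 183, 798)         # 67.5 with continuity
#' chi_square_2x2(280, 494, 183, 798, continuity = FALSE)
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                           continuity = TRUE) {
  m <- as_2x2(a, b, c, d)
  n <- sum(m)
  marg <- c(rowSums(m), colSums(m))
  if (any(marg == 0)) {
    stop("zero marginal: chi-square statistic undefined", call. = FALSE)
  }
  det <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (continuity) det <- max(0, det - n / 2)
  stat <- n * det^2 / prod(marg)
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 continuity = continuity)
}

#' Phi coefficient of a 2x2 table
#'
#' Effect size `phi = sqrt(chi2 / N)` using the uncorrected chi-square; for
#' a 2x2 table this equals the Pearson contingency measure and Cramer's V.
#' The confidence interval is by nonparametric bootstrap over the cell
#' counts (multinomial resampling, percentile interval) by default, or by
#' the Fisher-z approximation.
#'
#' @inheritParams chi_square_2x2
#' @param ci `"bootstrap"` or `"fisher"`.
#' @param reps Bootstrap resamples.
#' @param conf_level Confidence level.
#' @param seed Optional integer seed for the bootstrap (RNG state is
#'   restored afterwards).
#' @return A one-row tibble: `phi`, `ci_low`, `ci_high`, `ci_method`.
#' @examples
#' phi_coefficient(280, 494, 183, 798, seed = 1)
#' @export
phi_coefficient <- function(a, b = NULL, c = NULL, d = NULL,
                            ci = c("bootstrap", "fisher"), reps = 2000,
                            conf_level = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  m <- as_2x2(a, b, c, d)
  n <- sum(m)
  phi_of <- function(mm) {
    marg <- c(rowSums(mm), colSums(mm))
    if (any(marg == 0)) return(NA_real_)
    det <- mm[1, 1] * mm[2, 2] - mm[1, 2] * mm[2, 1]
    sqrt(sum(mm) * det^2 / prod(marg)) / sum(mm) * sqrt(sum(mm))
  }
  phi <- sqrt(chi_square_2x2(m, continuity = FALSE)$statistic / n)
  alpha <- 1 - conf_level
  if (ci == "bootstrap") {
    draws <- with_preserved_seed(seed, {
      counts <- stats::rmultinom(reps, n, prob = as.vector(m) / n)
      apply(counts, 2, function(x) phi_of(matrix(x, 2, 2)))
    })
    qs <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  } else {
    z <- atanh(min(phi, 1 - 1e-12))
    se <- 1 / sqrt(n - 3)
    qs <- tanh(z + stats::qnorm(c(alpha / 2, 1 - alpha / 2)) * se)
  }
  tibble::tibble(phi = phi, ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 ci_method = ci)
}

# Per-record eligibility and match flags for the alert-effect analysis.
# family "vl": eligible records have a non-missing most-recent paper VL
# (value + date) dated on/after the cutoff; matched when the EHR holds an
# equal-dated entry whose value matches within 1 copy/mL.
# family "pickup": eligible records have a non-missing paper pickup-1 date
# and drugs dated on/after the cutoff; matched when some EHR pickup slot has
# the same date and canonically equal drugs.
alert_effect_flags <- function(records, family, cutoff_date, cfg) {
  n <- nrow(records)
  cutoff <- as.numeric(as.Date(cutoff_date))
  if (family == "vl") {
    m <- vl_slot_matrices(records, cfg)
    # most recent complete paper entry
    pd <- m$pd
    pd[is.na(m$pv)] <- NA_real_
    newest <- suppressWarnings(apply(pd, 1, max, na.rm = TRUE))
    newest[!is.finite(newest)] <- NA_real_
    pval <- rep(NA_real_, n)
    for (slot in 3:1) {
      hit <- !is.na(newest) & !is.na(pd[, slot]) & pd[, slot] == newest
      pval[hit] <- m$pv[hit, slot]
    }
    eligible <- !is.na(newest) & newest >= cutoff
    matched <- rep(FALSE, n)
    for (slot in 1:3) {
      hit <- eligible & !is.na(m$ed[, slot]) & m$ed[, slot] == newest &
        !is.na(m$ev[, slot]) & abs(m$ev[, slot] - pval) <= 1 + 1e-9
      matched <- matched | (hit %in% TRUE)
    }
  } else {
    pdate <- records$paper_drug_pickup1_date
    pdrugs <- records$paper_drug_pickup1_drugs
    md <- is_missing(pdate, "date", cfg, hiv_related = TRUE)
    mg <- is_missing(pdrugs, "drug_regimen", cfg)
    d <- as.numeric(parse_dqa_date(pdate))
    eligible <- !md & !mg & !is.na(d) & d >= cutoff
    pcanon <- rep(NA_character_, n)
    pcanon[eligible] <- canonicalize_regimen(pdrugs[eligible], cfg$synonyms)
    matched <- rep(FALSE, n)
    for (slot in 1:3) {
      ed <- records[[sprintf("ehr_drug_pickup%d_date", slot)]]
      eg <- records[[sprintf("ehr_drug_pickup%d_drugs", slot)]]
      emd <- is_missing(ed, "date", cfg, hiv_related = TRUE)
      emg <- is_missing(eg, "drug_regimen", cfg)
      edn <- as.numeric(parse_dqa_date(ed))
      cand <- eligible & !emd & !emg & !is.na(edn) & edn == d
      if (any(cand)) {
        eq <- canonicalize_regimen(eg[cand], cfg$synonyms) == pcanon[cand]
        matched[cand][which(eq)] <- TRUE
      }
    }
  }
  list(eligible = eligible, matched = matched & eligible)
}

#' Alert-effect contingency analysis
#'
#' Tests whether facilities receiving the missing-viral-load clinical alert
#' (alert tier >= 2) show better EHR recording of recent viral loads or drug
#' pickups than facilities without the alert. Records are restricted to the
#' post-intervention period via their last-visit date, then each eligible
#' record (one with a recent paper-chart entry for the family) is classified
#' matched/unmatched according to whether the EHR holds a date-aligned
#' matching entry. The 2x2 table (rows alert / no-alert, columns match / no
#' match) is tested by chi-square (with and without continuity correction)
#' with the phi effect size, and per-facility match percentages are returned
#' ranked for plotting.
#'
#' @inheritParams facility_summary
#' @param family `"vl"` (viral-load results) or `"pickup"` (drug pickups).
#' @param cutoff_date First day of the post-intervention period.
#' @param phi_seed Seed forwarded to the bootstrap CI of
#'   [phi_coefficient()].
#' @param phi_ci Compute the bootstrap CI for phi (skippable when only the
#'   test statistic is needed, e.g. in replicated simulations).
#' @return A list of class `dqa_alert_effect`: `family`, `table` (2x2
#'   matrix), `group_summary` (per-group eligible / matched / percentage),
#'   `facility_pct` (ranked per-facility percentages), `chisq` (both
#'   continuity settings), `phi`.
#' @export
alert_effect_table <- function(records, facilities, family = c("vl", "pickup"),
                               cutoff_date = as.Date("2018-07-01"),
                               cfg = missingness_config(), phi_seed = NULL,
                               phi_ci = TRUE) {
  family <- match.arg(family)
  orphans <- setdiff(unique(records$facility_id), facilities$facility_id)
  if (length(orphans) > 0) {
    stop("facility_id values absent from the facility table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  cutoff <- as.Date(cutoff_date)

  # post-intervention filter on the record's last-visit date
  lv_p <- records$paper_date_of_last_visit
  lv_e <- records$ehr_date_of_last_visit
  mp <- is_missing(lv_p, "date", cfg)
  me <- is_missing(lv_e, "date", cfg)
  dp <- as.numeric(parse_dqa_date(lv_p))
  de <- as.numeric(parse_dqa_date(lv_e))
  dp[mp] <- NA_real_
  de[me] <- NA_real_
  record_date <- pmax(dp, de, na.rm = TRUE)
  keep <- !is.na(record_date) & record_date >= as.numeric(cutoff)
  if (!any(keep)) stop("no records on/after the cutoff date", call. = FALSE)
  rec <- records[keep, , drop = FALSE]

  flags <- alert_effect_flags(rec, family, cutoff, cfg)
  alert_fac <- facilities$facility_id[facilities$alert_tier >= 2]
  in_alert <- rec$facility_id %in% alert_fac

  groups <- list(alert = in_alert, no_alert = !in_alert)
  for (g in names(groups)) {
    if (sum(flags$eligible & groups[[g]]) == 0) {
      stop("no eligible records in group: ", g, call. = FALSE)
    }
  }
  cell <- function(grp, m) sum(flags$eligible & grp & flags$matched == m)
  tab <- matrix(c(cell(in_alert, TRUE), cell(in_alert, FALSE),
                  cell(!in_alert, TRUE), cell(!in_alert, FALSE)),
                2, 2, byrow = TRUE,
                dimnames = list(c("alert", "no_alert"), c("match", "no_match")))

  group_summary <- tibble::tibble(
    group = c("alert", "no_alert"),
    eligible = rowSums(tab),
    matched = tab[, "match"],
    pct_matched = 100 * tab[, "match"] / rowSums(tab)
  )

  fac <- tibble::tibble(facility_id = rec$facility_id,
                        eligible = flags$eligible, matched = flags$matched) %>%
    dplyr::filter(.data$eligible) %>%
    dplyr::group_by(.data$facility_id) %>%
    dplyr::summarise(eligible = dplyr::n(), matched = sum(.data$matched),
                     .groups = "drop") %>%
    dplyr::mutate(pct_matched = 100 * .data$matched / .data$eligible,
                  alert = .data$facility_id %in% alert_fac) %>%
    dplyr::arrange(dplyr::desc(.data$pct_matched))
  fac$rank <- seq_len(nrow(fac))

  safe_stat <- function(expr) tryCatch(expr, error = function(e) NULL)
  chisq <- dplyr::bind_rows(
    safe_stat(chi_square_2x2(tab, continuity = TRUE)),
    safe_stat(chi_square_2x2(tab, continuity = FALSE))
  )
  phi <- if (phi_ci) {
    safe_stat(phi_coefficient(tab, seed = phi_seed))
  } else {
    safe_stat(tibble::tibble(
      phi = sqrt(chi_square_2x2(tab, continuity = FALSE)$statistic / sum(tab)),
      ci_low = NA_real_, ci_high = NA_real_, ci_method = NA_character_))
  }

  structure(list(family = family, table = tab, group_summary = group_summary,
                 facility_pct = fac, chisq = chisq, phi = phi),
            class = "dqa_alert_effect")
}

#' @export
print.dqa_alert_effect <- function(x, ...) {
  cat("Alert-effect analysis (", x$family, ")\n", sep = "")
  print(x$table)
  print(x$group_summary)
  if (!is.null(x$chisq) && nrow(x$chisq) > 0) print(x$chisq)
  if (!is.null(x$phi)) print(x$phi)
  invisible(x)
}
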