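#' Date-keyed alignment of viral-load series
#'
#' Each source holds up to three (value, date) viral-load entries, most
#' recent first. Position-wise comparison misleads whenever one source lags
#' the other by a result, so entries are paired on exact calendar date: an
#' entry pairs with the opposite-source entry carrying the same date, and
#' entries whose date appears only in one source (or whose date is missing)
#' form one-sided pairs, counting as missing in the other source.
#'
#' Two same-source entries sharing a date are a data anomaly: they are paired
#' deterministically in position order and a warning is raised.
#'
#' @param paper_values,ehr_values Numeric vectors (length <= 3), `NA` for a
#'   missing value.
#' @param paper_dates,ehr_dates Date vectors aligned with the values, `NA`
#'   for a missing date. Position 1 is the most recent entry.
#' @return A tibble of class `dqa_aligned_vl`, one row per pair, ordered by
#'   date descending (undated entries last), with columns `date`,
#'   `paper_value`, `ehr_value`, `paper_present`, `ehr_present` and `match`
#'   (`TRUE`/`FALSE` for complete pairs via [vl_values_match()], `NA` for
#'   one-sided pairs or pairs missing a value).
#' @examples
#' d <- as.Date(c("2018-10-01", "2018-04-01", "2017-11-01"))
#' align_vl(c(150, 20, 900), d, c(20, 900), d[2:3])
#' @export
align_vl <- function(paper_values, paper_dates, ehr_values, ehr_dates) {
  stopifnot(length(paper_values) <= 3, length(ehr_values) <= 3,
            length(paper_values) == length(paper_dates),
            length(ehr_values) == length(ehr_dates))
  paper_dates <- as.Date(paper_dates)
  ehr_dates <- as.Date(ehr_dates)

  keep <- function(v, d) {
    i <- which(!(is.na(v) & is.na(d)))
    list(value = as.numeric(v)[i], date = d[i], pos = seq_along(i))
  }
  p <- keep(paper_values, paper_dates)
  e <- keep(ehr_values, ehr_dates)
  if (anyDuplicated(stats::na.omit(p$date)) || anyDuplicated(stats::na.omit(e$date))) {
    warning("duplicate dates within one source; pairing by position order",
            call. = FALSE)
  }

  used_e <- rep(FALSE, length(e$value))
  rows <- vector("list", length(p$value) + length(e$value))
  k <- 0
  for (i in seq_along(p$value)) {
    j <- NA_integer_
    if (!is.na(p$date[i])) {
      cand <- which(!used_e & !is.na(e$date) & e$date == p$date[i])
      if (length(cand) > 0) j <- cand[1]
    }
    k <- k + 1
    if (!is.na(j)) {
      used_e[j] <- TRUE
      rows[[k]] <- list(date = p$date[i], paper_value = p$value[i],
                        ehr_value = e$value[j], paper_present = TRUE,
                        ehr_present = TRUE)
    } else {
      rows[[k]] <- list(date = p$date[i], paper_value = p$value[i],
                        ehr_value = NA_real_, paper_present = TRUE,
                        ehr_present = FALSE)
    }
  }
  for (j in which(!used_e)) {
    k <- k + 1
    rows[[k]] <- list(date = e$date[j], paper_value = NA_real_,
                      ehr_value = e$value[j], paper_present = FALSE,
                      ehr_present = TRUE)
  }
  rows <- rows[seq_len(k)]
  out <- tibble::tibble(
    date = as.Date(vapply(rows, function(r) as.character(r$date), character(1))),
    paper_value = vapply(rows, `[[`, numeric(1), "paper_value"),
    ehr_value = vapply(rows, `[[`, numeric(1), "ehr_value"),
    paper_present = vapply(rows, `[[`, logical(1), "paper_present"),
    ehr_present = vapply(rows, `[[`, logical(1), "ehr_present")
  )
  out <- out[order(is.na(out$date), -as.numeric(out$date)), , drop = FALSE]
  out$match <- ifelse(out$paper_present & out$ehr_present,
                      vl_values_match(out$paper_value, out$ehr_value), NA)
  class(out) <- c("dqa_aligned_vl", class(out))
  out
}

#' Match flag of one aligned pair
#'
#' Applies the viral-load tolerance rule to a complete pair; one-sided pairs
#' contribute to missingness, not matching, so they yield `NA`.
#'
#' @param pair A single row of an [align_vl()] result.
#' @return `TRUE`, `FALSE`, or `NA` when the pair is one-sided.
#' @export
vl_pair_match <- function(pair) {
  stopifnot(nrow(pair) == 1)
  if (!isTRUE(pair$paper_present) || !isTRUE(pair$ehr_present)) return(NA)
  unname(vl_values_match(pair$paper_value, pair$ehr_value))
}

#' "At least one viral load" flag
#'
#' Whether the most recent non-missing EHR value matches (within 1 copy/mL)
#' any of the up-to-three paper values — a lenient summary tolerant of the
#' EHR running one result behind the chart. Matching is value-only; no date
#' agreement is required. An empty EHR side yields `FALSE`.
#'
#' @inheritParams align_vl
#' @return Logical flag.
#' @export
at_least_one_vl <- function(paper_values, paper_dates, ehr_values, ehr_dates) {
  ehr_values <- as.numeric(ehr_values)
  ehr_dates <- as.Date(ehr_dates)
  ok <- which(!is.na(ehr_values))
  if (length(ok) == 0) return(FALSE)
  # newest by date when dates are known, else first by position
  dated <- ok[!is.na(ehr_dates[ok])]
  newest <- if (length(dated) > 0) dated[which.max(ehr_dates[dated])] else ok[1]
  pv <- as.numeric(paper_values)
  pv <- pv[!is.na(pv)]
  if (length(pv) == 0) return(FALSE)
  any(vl_values_match(ehr_values[newest], pv))
}

# ---- vectorised dataset-level helpers ------------------------------------

# Parse the six VL slot columns of a record-pair table into numeric matrices,
# applying the missingness rules. Returns list(pv, pd, ev, ed): n x 3 value
# matrices and n x 3 date matrices (numeric days since epoch).
vl_slot_matrices <- function(records, cfg) {
  n <- nrow(records)
  get <- function(source, what, slot) {
    col <- sprintf("%s_viral_load%d_%s", source, slot, what)
    x <- records[[col]]
    kind <- if (what == "date") "date" else "viral_load"
    miss <- is_missing(x, kind, cfg, hiv_related = (what == "date"))
    if (what == "date") {
      v <- as.numeric(parse_dqa_date(x))
    } else {
      v <- parse_dqa_number(x)
    }
    v[miss] <- NA_real_
    v
  }
  mk <- function(source, what) {
    matrix(c(get(source, what, 1), get(source, what, 2), get(source, what, 3)),
           nrow = n)
  }
  list(pv = mk("paper", "value"), pd = mk("paper", "date"),
       ev = mk("ehr", "value"), ed = mk("ehr", "date"))
}

# Most-recent aligned pair per record, vectorised. For each record take the
# latest date present in either source; each source contributes its value at
# that date if it has one. Records with no valid-dated entries on either side
# fall back to the positional slot-1 values (dates stay NA).
vl_aligned_recent <- function(records, cfg) {
  m <- vl_slot_matrices(records, cfg)
  n <- nrow(records)
  all_dates <- cbind(m$pd, m$ed)
  latest <- suppressWarnings(apply(all_dates, 1, max, na.rm = TRUE))
  latest[!is.finite(latest)] <- NA_real_

  side_at <- function(vals, dates) {
    v <- rep(NA_real_, n)
    d <- rep(NA_real_, n)
    for (slot in 3:1) { # earlier slots win ties (most recent first)
      hit <- !is.na(latest) & !is.na(dates[, slot]) & dates[, slot] == latest
      v[hit] <- vals[hit, slot]
      d[hit] <- dates[hit, slot]
    }
    list(value = v, date = d)
  }
  p <- side_at(m$pv, m$pd)
  e <- side_at(m$ev, m$ed)

  undated <- is.na(latest)
  if (any(undated)) {
    p$value[undated] <- m$pv[undated, 1]
    e$value[undated] <- m$ev[undated, 1]
  }
  tibble::tibble(
    patient_id = records$patient_id,
    paper_value = p$value, paper_date = as.Date(p$date, origin = "1970-01-01"),
    ehr_value = e$value, ehr_date = as.Date(e$date, origin = "1970-01-01")
  )
}
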