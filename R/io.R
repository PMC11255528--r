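#' Write a record-pair table to delimited text
#'
#' One row per patient: `patient_id`, `facility_id`, then a `paper_` and an
#' `ehr_` column for each of the 28 variables (dates ISO-8601, viral loads
#' numeric text, regimens raw strings). Blank cells are written empty so the
#' file round-trips losslessly through [read_record_pairs()].
#'
#' @param records A record-pair tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_pairs <- function(records, path) {
  cols <- record_pair_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack required columns: ",
         paste(head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(records[, cols])
  out[] <- lapply(out, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a record-pair table from delimited text
#'
#' Validates the schema (all 58 columns present), keeps every cell as text,
#' and screens date and viral-load cells: malformed non-blank cells are
#' blanked (hence counted missing downstream), reported in the parse report
#' attached as attribute `"parse_report"`, and summarised in one warning.
#' Dates may be supplied day-first (`dialect = "dayfirst"`, e.g.
#' `31/12/2018`), converted to ISO on read.
#'
#' @param path CSV path.
#' @param dialect `"iso"` (default, `YYYY-MM-DD`) or `"dayfirst"`
#'   (`DD/MM/YYYY`).
#' @return A record-pair tibble; attribute `parse_report` is a tibble of
#'   blanked cells (`row`, `column`, `value`).
#' @export
read_record_pairs <- function(path, dialect = c("iso", "dayfirst")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  cols <- record_pair_columns()
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("record-pair file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("record-pair file has no data rows", call. = FALSE)
  out <- tibble::as_tibble(raw[, cols])

  vars <- dqa_variables()
  checked <- vars$name[vars$kind %in% c("date", "viral_load")]
  report <- list()
  for (v in checked) {
    kind <- vars$kind[vars$name == v]
    for (src in c("paper", "ehr")) {
      col <- paste0(src, "_", v)
      x <- trimws(out[[col]])
      if (kind == "date" && dialect == "dayfirst") {
        df <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
        if (any(df)) {
          x[df] <- format(as.Date(x[df], format = "%d/%m/%Y"), "%Y-%m-%d")
        }
      }
      nonblank <- !is.na(x) & x != ""
      bad <- if (kind == "date") {
        nonblank & is.na(parse_dqa_date(x))
      } else {
        nonblank & is.na(parse_dqa_number(x))
      }
      if (any(bad)) {
        report[[length(report) + 1]] <- tibble::tibble(
          row = which(bad), column = col, value = x[bad])
        x[bad] <- ""
      }
      out[[col]] <- x
    }
  }
  report <- if (length(report) > 0) dplyr::bind_rows(report) else {
    tibble::tibble(row = integer(0), column = character(0),
                   value = character(0))
  }
  if (nrow(report) > 0) {
    warning(nrow(report), " malformed cell(s) treated as missing; see ",
            "attr(x, 'parse_report')", call. = FALSE)
  }
  attr(out, "parse_report") <- report
  out
}

#' Write / read facility profiles
#'
#' Facility table columns: `facility_id`, `arm`, `alert_tier`,
#' `ehr_availability` (Likert 1-5), `tech_experience` (0-4),
#' `years_ehr_use`.
#'
#' @param facilities Facility tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_facility_profiles <- function(facilities, path) {
  utils::write.csv(as.data.frame(facilities), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_facility_profiles
#' @export
read_facility_profiles <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  req <- c("facility_id", "arm", "alert_tier", "ehr_availability",
           "tech_experience", "years_ehr_use")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("facility file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  out$facility_id <- as.character(out$facility_id)
  bad <- out$alert_tier >= 1 & out$arm != "intervention" |
    out$alert_tier == 0 & out$arm == "intervention"
  if (any(bad)) {
    stop("alert_tier >= 1 must coincide with the intervention arm",
         call. = FALSE)
  }
  out
}
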