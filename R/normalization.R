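#' Missing-value configuration
#'
#' Rules deciding when a transcribed field counts as missing: blank cells,
#' explicit not-available codes, sentinel placeholder dates (a well-known
#' habit is typing 1980-01-01 when the true date is unknown), dates in the
#' future of the chart-abstraction date, and HIV-care dates that predate the
#' start of HIV treatment in the country.
#'
#' @param sentinel_dates Dates treated as placeholders, hence missing.
#' @param collection_date Upper plausibility bound for every date variable
#'   (the day the charts were abstracted).
#' @param hiv_epoch Lower bound for HIV-care-related dates (enrollment, ART
#'   start, pickups, VL draws); care in the study setting began around 2002.
#' @param dob_min Lower bound for date of birth.
#' @param na_codes Strings (case-insensitive) coding "information not
#'   available" in the capture tool.
#' @param synonyms Optional named character vector mapping drug-name variants
#'   to a preferred spelling, applied during regimen canonicalization.
#' @return A list of class `dqa_missingness_config`.
#' @examples
#' cfg <- missingness_config()
#' is_missing("1980-01-01", "date", cfg)
#' @export
missingness_config <- function(sentinel_dates = as.Date("1980-01-01"),
                               collection_date = as.Date("2018-12-01"),
                               hiv_epoch = as.Date("2002-01-01"),
                               dob_min = as.Date("1900-01-01"),
                               na_codes = c("unknown", "n/a", "not available"),
                               synonyms = NULL) {
  sentinel_dates <- as.Date(sentinel_dates)
  collection_date <- as.Date(collection_date)
  hiv_epoch <- as.Date(hiv_epoch)
  dob_min <- as.Date(dob_min)
  if (!hiv_epoch < collection_date) {
    stop("hiv_epoch must precede collection_date", call. = FALSE)
  }
  structure(
    list(sentinel_dates = sentinel_dates, collection_date = collection_date,
         hiv_epoch = hiv_epoch, dob_min = dob_min,
         na_codes = tolower(trimws(na_codes)), synonyms = synonyms),
    class = "dqa_missingness_config"
  )
}

#' Load a missingness configuration from a YAML file
#'
#' Fields mirror the arguments of [missingness_config()]; absent fields keep
#' their defaults. `synonyms` may be given as a named mapping.
#'
#' @param path Path to a YAML file.
#' @return A `dqa_missingness_config`.
#' @export
read_missingness_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (f in c("sentinel_dates", "collection_date", "hiv_epoch", "dob_min")) {
    if (!is.null(raw[[f]])) args[[f]] <- as.Date(unlist(raw[[f]]))
  }
  if (!is.null(raw$na_codes)) args$na_codes <- as.character(unlist(raw$na_codes))
  if (!is.null(raw$synonyms)) args$synonyms <- unlist(raw$synonyms)
  do.call(missingness_config, args)
}

# Strict-ish ISO date parser: malformed text yields NA, never an error.
parse_dqa_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\s*\\d{4}-\\d{1,2}-\\d{1,2}\\s*$", x)
  if (any(ok)) out[ok] <- as.Date(trimws(x[ok]), format = "%Y-%m-%d")
  out
}

parse_dqa_number <- function(x) {
  suppressWarnings(as.numeric(as.character(x)))
}

# Lowercase, collapse whitespace, best-effort accent stripping.
norm_string <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  y <- suppressWarnings(iconv(x, from = "", to = "ASCII//TRANSLIT"))
  ifelse(is.na(y) & !is.na(x), x, y)
}

#' Decide whether raw values are missing
#'
#' Vectorised over `x`. A value is missing if it is blank, carries a
#' not-available code, or — for dates — fails to parse, equals a sentinel
#' date, lies after the abstraction date, or (for HIV-care dates) predates
#' the HIV-treatment epoch. Dates of birth use their own plausibility window.
#' Viral-load fields that do not parse as numbers are missing. The decision
#' is total: no input raises an error.
#'
#' @param x Character vector of raw cell values.
#' @param kind Variable kind, see [dqa_variables()].
#' @param cfg A [missingness_config()].
#' @param hiv_related Apply the HIV epoch lower bound (date kind only).
#' @param dob Treat as date of birth (its own window, no epoch rule).
#' @return Logical vector, `TRUE` where missing.
#' @export
is_missing <- function(x, kind, cfg = missingness_config(),
                       hiv_related = FALSE, dob = FALSE) {
  stopifnot(inherits(cfg, "dqa_missingness_config"), length(kind) == 1)
  x <- as.character(x)
  txt <- trimws(x)
  miss <- is.na(x) | txt == "" | tolower(txt) %in% cfg$na_codes
  if (kind == "date") {
    d <- parse_dqa_date(x)
    bad <- is.na(d) | d %in% cfg$sentinel_dates | d > cfg$collection_date
    if (dob) {
      bad <- bad | d < cfg$dob_min
    } else if (hiv_related) {
      bad <- bad | d < cfg$hiv_epoch
    }
    miss <- miss | (!miss & (is.na(d) | bad))
  } else if (kind == "viral_load") {
    miss <- miss | (!miss & is.na(parse_dqa_number(x)))
  }
  miss
}

#' Canonicalize an antiretroviral regimen string
#'
#' Regimens arrive in mixed dialects: components separated by `+`, commas or
#' the word "and", each as a drug name with an optional parenthesised dose,
#' e.g. `"Tenofovir (300) + Lamivudine (300) and Efavirenz (600)"`. The
#' canonical form is the sorted `name(dose)` multiset joined by `+`, with
#' names case-folded, accent-stripped and whitespace-collapsed, so that any
#' two spellings of the same drug/dose combination compare equal. Tokens
#' without a recognisable dose are carried as normalized opaque strings.
#' Canonicalization is idempotent and order-invariant; no spelling
#' correction is attempted (supply `synonyms` for that).
#'
#' @param x Character vector of raw regimen strings.
#' @param synonyms Optional named character vector of drug-name replacements
#'   (names and values compared after normalization).
#' @return Character vector of canonical forms; `NA` for blank input.
#' @examples
#' canonicalize_regimen("Tenofovir (300) + Lamivudine (300) and Efavirenz (600)")
#' @export
canonicalize_regimen <- function(x, synonyms = NULL) {
  syn <- NULL
  if (!is.null(synonyms)) {
    syn <- stats::setNames(norm_string(unname(synonyms)), norm_string(names(synonyms)))
  }
  # regimen columns repeat a small formulary: canonicalize unique strings once
  x <- as.character(x)
  ux <- unique(x)
  canon_u <- vapply(ux, function(s) {
    if (is.na(s) || trimws(s) == "") return(NA_character_)
    toks <- strsplit(s, "\\s*[+,;]\\s*|\\s+(?i:and)\\s+", perl = TRUE)[[1]]
    toks <- trimws(toks)
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) return(NA_character_)
    comps <- vapply(toks, function(tk) {
      tk <- norm_string(tk)
      m <- regmatches(tk, regexec("^(.*?)\\s*\\(\\s*([0-9]+\\.?[0-9]*)\\s*\\)$", tk))[[1]]
      if (length(m) == 3 && nzchar(m[2])) {
        name <- m[2]
        if (!is.null(syn) && name %in% names(syn)) name <- syn[[name]]
        dose <- format(as.numeric(m[3]), scientific = FALSE, trim = TRUE)
        paste0(name, "(", dose, ")")
      } else {
        if (!is.null(syn) && tk %in% names(syn)) tk <- syn[[tk]]
        tk
      }
    }, character(1))
    paste(sort(comps), collapse = "+")
  }, character(1), USE.NAMES = FALSE)
  canon_u[match(x, ux)]
}

#' Viral-load tolerance match
#'
#' Two viral-load results count as matching when they differ by at most
#' 1 copy/mL, absorbing decimal-precision differences between a paper value
#' such as 20.6 and the whole number 20 the EHR stores.
#'
#' @param a,b Numeric vectors (or strings parseable as numbers), recycled.
#' @return Logical vector; `NA` where either side does not parse.
#' @examples
#' vl_values_match(20.6, 20)   # TRUE
#' vl_values_match(1000, 1002) # FALSE
#' @export
vl_values_match <- function(a, b) {
  a <- parse_dqa_number(a)
  b <- parse_dqa_number(b)
  abs(a - b) <= 1 + 1e-9
}

#' Kind-aware value matching
#'
#' Exact equality after the kind's standardization: calendar-date equality
#' for dates, regimen canonicalization for drug regimens, the 1 copy/mL
#' tolerance for viral loads, and normalized string equality otherwise.
#' Both inputs are assumed non-missing under [is_missing()]; the result is
#' `NA` where a side fails to standardize.
#'
#' @param a,b Character vectors of raw values (recycled).
#' @param kind Variable kind, see [dqa_variables()].
#' @param cfg A [missingness_config()] (supplies the regimen synonym map).
#' @return Logical vector.
#' @export
values_match <- function(a, b, kind, cfg = missingness_config()) {
  stopifnot(length(kind) == 1)
  switch(kind,
    date = {
      da <- parse_dqa_date(a)
      db <- parse_dqa_date(b)
      da == db
    },
    viral_load = vl_values_match(a, b),
    drug_regimen = {
      canonicalize_regimen(a, cfg$synonyms) == canonicalize_regimen(b, cfg$synonyms)
    },
    # categorical, demographic
    norm_string(a) == norm_string(b)
  )
}
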