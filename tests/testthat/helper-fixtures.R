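# An all-blank record-pair table with the full 58-column schema.
blank_records <- function(n, facility_id = "F01") {
  cols <- c("patient_id", "facility_id",
            as.vector(rbind(paste0("paper_", dqa_variables()$name),
                            paste0("ehr_", dqa_variables()$name))))
  out <- tibble::as_tibble(
    stats::setNames(as.list(rep("", length(cols))), cols))[rep(1, n), ]
  out$patient_id <- sprintf("P%04d", seq_len(n))
  out$facility_id <- rep_len(facility_id, n)
  out
}

set_pair <- function(records, variable, paper, ehr) {
  records[[paste0("paper_", variable)]] <- paper
  records[[paste0("ehr_", variable)]] <- ehr
  records
}

# A random regimen string in a random dialect (separators, order, casing),
# drawn over a small name/dose pool. Used for canonicalization properties.
random_regimen <- function(k = NULL) {
  pool <- c("Tenofovir", "Lamivudine", "Efavirenz", "Dolutegravir",
            "Abacavir", "Nevirapine")
  doses <- c(50, 150, 200, 300, 600)
  if (is.null(k)) k <- sample(1:4, 1)
  drugs <- sample(pool, k)
  comps <- paste0(drugs, " (", sample(doses, k, replace = TRUE), ")")
  seps <- sample(c(" + ", " and ", ", "), max(k - 1, 0), replace = TRUE)
  out <- comps[1]
  for (i in seq_len(k - 1)) out <- paste0(out, seps[i], comps[i + 1])
  out
}

# ---- independent brute-force oracles -------------------------------------
# Straight per-cell loops with their own parsing, used only on small
# fixtures with clean content (ISO dates, plain numbers, plain category
# strings, the 1980-01-01 sentinel, blanks). Deliberately naive.

oracle_cell_missing <- function(value, kind, collection = as.Date("2018-12-01"),
                                epoch = as.Date("2002-01-01"),
                                hiv_related = FALSE) {
  if (is.na(value) || trimws(value) == "") return(TRUE)
  if (kind == "date") {
    d <- suppressWarnings(as.Date(value, format = "%Y-%m-%d"))
    if (is.na(d)) return(TRUE)
    if (format(d, "%Y-%m-%d") == "1980-01-01") return(TRUE)
    if (d > collection) return(TRUE)
    if (hiv_related && d < epoch) return(TRUE)
    return(FALSE)
  }
  if (kind == "viral_load") {
    return(is.na(suppressWarnings(as.numeric(value))))
  }
  FALSE
}

oracle_cell_match <- function(a, b, kind) {
  if (kind == "viral_load") {
    return(abs(as.numeric(a) - as.numeric(b)) <= 1)
  }
  trimws(tolower(a)) == trimws(tolower(b))
}

oracle_completeness <- function(records, variable, source) {
  vars <- dqa_variables()
  kind <- vars$kind[vars$name == variable]
  hiv <- vars$hiv_related[vars$name == variable]
  filled <- 0
  for (i in seq_len(nrow(records))) {
    v <- records[[paste0(source, "_", variable)]][i]
    if (!oracle_cell_missing(v, kind, hiv_related = hiv)) filled <- filled + 1
  }
  filled / nrow(records)
}

oracle_matching <- function(records, variable) {
  vars <- dqa_variables()
  kind <- vars$kind[vars$name == variable]
  hiv <- vars$hiv_related[vars$name == variable]
  num <- 0
  den <- 0
  for (i in seq_len(nrow(records))) {
    a <- records[[paste0("paper_", variable)]][i]
    b <- records[[paste0("ehr_", variable)]][i]
    if (!oracle_cell_missing(a, kind, hiv_related = hiv) &&
        !oracle_cell_missing(b, kind, hiv_related = hiv)) {
      den <- den + 1
      if (oracle_cell_match(a, b, kind)) num <- num + 1
    }
  }
  c(numerator = num, denominator = den)
}

oracle_concordance <- function(records) {
  # per-record recount of the 15-variable concordance score; valid for
  # fixtures whose viral-load dates agree across sources (aligned scoring
  # then coincides with slot-1 comparison)
  vars <- dqa_variables()
  sapply(seq_len(nrow(records)), function(i) {
    score <- 0
    for (v in concordance_variables()) {
      kind <- vars$kind[vars$name == v]
      hiv <- vars$hiv_related[vars$name == v]
      a <- records[[paste0("paper_", v)]][i]
      b <- records[[paste0("ehr_", v)]][i]
      ma <- oracle_cell_missing(a, kind, hiv_related = hiv)
      mb <- oracle_cell_missing(b, kind, hiv_related = hiv)
      if (ma && mb) {
        score <- score + 1
      } else if (!ma && !mb && oracle_cell_match(a, b, kind)) {
        score <- score + 1
      }
    }
    score
  })
}

oracle_chisq <- function(m) {
  # Pearson statistic from expected counts, no correction
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Small fixture with clean content exercising every concordance state.
small_fixture <- function(n = 20, seed = 99) {
  withr::with_seed(seed, {
    rec <- blank_records(n, facility_id = rep(c("F01", "F02"), length.out = n))
    dates <- format(as.Date("2018-01-01") + sample(0:300, n, TRUE), "%Y-%m-%d")
    flip <- function(x, p_miss = 0.2, p_err = 0.3) {
      # returns ehr side: blank, equal, or perturbed
      out <- x
      r <- stats::runif(length(x))
      out[r < p_miss] <- ""
      err <- r >= p_miss & r < p_miss + p_err
      out[err] <- format(as.Date(x[err]) + 5, "%Y-%m-%d")
      out
    }
    dob <- format(as.Date("1980-06-15") + sample(0:2000, n, TRUE), "%Y-%m-%d")
    rec <- set_pair(rec, "date_of_birth", dob, flip(dob))
    rec <- set_pair(rec, "date_enrollment_hiv_care", dates, flip(dates))
    sent <- dates
    sent[1:3] <- "1980-01-01"
    rec <- set_pair(rec, "date_of_last_visit", sent, dates)
    gender <- sample(c("F", "M"), n, TRUE)
    g2 <- gender
    g2[1:4] <- c("", "F", "M", "")
    rec <- set_pair(rec, "gender", gender, g2)
    vl <- as.character(round(stats::runif(n, 20, 5000), 1))
    vl2 <- as.character(round(as.numeric(vl)) + sample(c(0, 0, 50), n, TRUE))
    rec <- set_pair(rec, "viral_load1_value", vl, vl2)
    rec <- set_pair(rec, "viral_load1_date", dates, dates)
    who <- as.character(sample(1:4, n, TRUE))
    rec <- set_pair(rec, "initial_who_stage", who, who)
    rec
  })
}
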