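test_that("configuration validates probabilities and feasibility", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, sentinel_date_rate = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(seed = 1, vl_recent_match_prob = -0.1),
               "\\[0, 1\\]")
  expect_error(simulation_config(seed = 1, n_facilities = 10,
                                 total_records = 100), "charts_range")
  expect_error(simulation_config(seed = 1, n_vl_probs = c(0.5, 0.5, 0.5, 0)),
               "sum to 1")
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- simulation_config(seed = 5, n_facilities = 4, total_records = 200)
  a <- simulate_dqa(cfg)
  b <- simulate_dqa(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$facilities, b$facilities)
  expect_identical(a$truth, b$truth)
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_dqa(cfg))
  expect_identical(.Random.seed, before)
})

test_that("the study-shaped default has the audit's dimensions", {
  sim <- simulate_dqa(simulation_config(seed = 2))
  expect_equal(nrow(sim$records), 3467)
  expect_equal(nrow(sim$facilities), 50)
  counts <- table(sim$records$facility_id)
  expect_true(all(counts >= 48 & counts <= 76))
  # arm structure: half intervention, 11 alert facilities
  expect_equal(sum(sim$facilities$arm == "intervention"), 25)
  expect_equal(sum(sim$facilities$alert_tier >= 2), 11)
  expect_true(all((sim$facilities$alert_tier >= 1) ==
                    (sim$facilities$arm == "intervention")))
  # total data cells = records x 28 variables x 2 sources
  expect_equal(nrow(sim$records) * nrow(dqa_variables()) * 2, 194152)
})

test_that("the noiseless limit yields identical sources and perfect metrics", {
  sim <- simulate_dqa(noiseless_config(seed = 3, n_facilities = 5,
                                       total_records = 250))
  cfg <- missingness_config()
  comp <- dplyr::bind_rows(
    completeness(sim$records, source = "paper", cfg = cfg),
    completeness(sim$records, source = "ehr", cfg = cfg))
  expect_true(all(comp$fraction == 1))
  expect_true(all(matching(sim$records, cfg = cfg)$fraction == 1))
  expect_true(all(concordance_score(sim$records, cfg)$score == 15))
  expect_equal(nrow(sim$truth$error_labels), 0)
})

test_that("forcing the EHR viral-load lag leaves the newest paper entry unpaired", {
  cfg <- simulation_config(seed = 9, n_facilities = 4, total_records = 200,
                           vl_recent_match_prob = 0, ehr_vl_old_entry_prob = 1,
                           paper_vl_record_prob = 1, vl_date_error = 0,
                           n_vl_probs = c(0, 0, 0, 1))
  sim <- simulate_dqa(cfg)
  mc <- missingness_config()
  m <- ehrdqa:::vl_slot_matrices(sim$records, mc)
  cutoff <- as.numeric(as.Date("2018-07-01"))
  recent <- !is.na(m$pd[, 1]) & m$pd[, 1] >= cutoff
  expect_gt(sum(recent), 0)
  for (i in which(recent)[1:25]) {
    al <- align_vl(m$pv[i, ], as.Date(m$pd[i, ], origin = "1970-01-01"),
                   m$ev[i, ], as.Date(m$ed[i, ], origin = "1970-01-01"))
    unpaired <- al$paper_present & !al$ehr_present
    expect_gte(sum(unpaired), 1)
    # the unpaired entry is the newest one
    expect_true(unpaired[1])
  }
})

test_that("recovered rates sit near the configured generative rates", {
  # moderate scale here; the 3-SE study-scale check lives in the acceptance
  # suite
  cfgs <- simulation_config(seed = 17, n_facilities = 10,
                            total_records = 600,
                            covariate_effects = c(availability = 0,
                                                  tech_experience = 0))
  sim <- simulate_dqa(cfgs)
  rec <- recover_parameters(sim$records)
  prof <- study_variable_profile()
  direct <- prof[prof$mechanism == "direct", ]
  n <- nrow(sim$records)
  for (i in seq_len(nrow(direct))) {
    v <- direct$name[i]
    for (src in c("paper", "ehr")) {
      p <- if (src == "paper") direct$paper_fill[i] else direct$ehr_fill[i]
      est <- rec$completeness$fraction[rec$completeness$variable == v &
                                         rec$completeness$source == src]
      # normal band with a small-count floor (skewed binomials near 0/1)
      tol <- max(4 * sqrt(p * (1 - p) / n), 5 / n)
      expect_lt(abs(est - p), tol + 1e-9, label = paste(v, src, est))
    }
  }
  # missingness 0 gives completeness exactly 1
  expect_equal(
    rec$completeness$fraction[rec$completeness$variable == "gender" &
                                rec$completeness$source == "ehr"], 1)
})

test_that("every observed discrepancy carries an error label", {
  sim <- simulate_dqa(simulation_config(seed = 23, n_facilities = 4,
                                        total_records = 200))
  lab <- sim$truth$error_labels
  expect_true(all(c("patient_id", "variable", "source", "label") %in%
                    names(lab)))
  expect_true(all(lab$label %in% c("missing", "sentinel", "transcribed",
                                   "lagged", "split", "precision")))
  # spot-check: direct-mechanism cells that differ from truth are labelled
  tv <- sim$truth$values
  for (v in c("date_of_birth", "gender", "initial_who_stage")) {
    truth_txt <- as.character(tv[[v]])
    obs <- sim$records[[paste0("ehr_", v)]]
    differs <- obs != truth_txt & obs != ""
    labelled <- sim$records$patient_id %in%
      lab$patient_id[lab$variable == v & lab$source == "ehr"]
    expect_true(all(labelled[differs]), label = v)
  }
})
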