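test_that("2x2 chi-square matches its closed form and the expected-count oracle", {
  withr::with_seed(5, {
    for (i in 1:100) {
      m <- matrix(sample(1:500, 4, replace = TRUE), 2, 2)
      got <- chi_square_2x2(m, continuity = FALSE)
      expect_equal(got$statistic, oracle_chisq(m), tolerance = 1e-12)
      # and agreement with the standard implementation, both settings
      expect_equal(got$statistic,
                   unname(suppressWarnings(
                     stats::chisq.test(m, correct = FALSE))$statistic))
      expect_equal(chi_square_2x2(m, continuity = TRUE)$statistic,
                   unname(suppressWarnings(
                     stats::chisq.test(m, correct = TRUE))$statistic))
    }
  })
})

test_that("continuity correction only lowers the statistic", {
  withr::with_seed(6, {
    for (i in 1:50) {
      m <- matrix(sample(0:50, 4, replace = TRUE), 2, 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      yates <- chi_square_2x2(m, continuity = TRUE)$statistic
      raw <- chi_square_2x2(m, continuity = FALSE)$statistic
      expect_true(raw >= yates)
      expect_true(yates >= 0)
    }
  })
})

test_that("degenerate tables are rejected, flat tables give zero", {
  expect_equal(chi_square_2x2(10, 10, 10, 10, continuity = FALSE)$statistic, 0)
  # identical row proportions
  expect_equal(chi_square_2x2(20, 40, 10, 20, continuity = FALSE)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), "zero marginal")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(chi_square_2x2(0, 0, 0, 0), "empty")
})

test_that("phi equals sqrt(chi2/N) and is transposition-invariant", {
  withr::with_seed(8, {
    for (i in 1:25) {
      m <- matrix(sample(1:300, 4, replace = TRUE), 2, 2)
      p <- phi_coefficient(m, ci = "fisher")
      expect_equal(p$phi,
                   sqrt(chi_square_2x2(m, continuity = FALSE)$statistic / sum(m)))
      expect_equal(phi_coefficient(t(m), ci = "fisher")$phi, p$phi)
      expect_true(p$phi >= 0 && p$phi <= 1)
    }
  })
  expect_equal(phi_coefficient(50, 0, 0, 50, ci = "fisher")$phi, 1)
  expect_equal(phi_coefficient(25, 25, 25, 25, ci = "fisher")$phi, 0)
  # bootstrap CI is seeded and reproducible
  b1 <- phi_coefficient(280, 494, 183, 798, seed = 9)
  b2 <- phi_coefficient(280, 494, 183, 798, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$phi && b1$phi <= b1$ci_high)
})

test_that("correlation handles perfect, inverse and degenerate inputs", {
  x <- 1:20
  r <- concordance_covariate_correlation(x, 2 * x + 3)
  expect_equal(r$r, 1)
  expect_equal(concordance_covariate_correlation(x, -x)$r, -1)
  expect_error(concordance_covariate_correlation(x, rep(2, 20)),
               "zero variance")
  withr::with_seed(10, {
    y <- x + rnorm(20, sd = 5)
    res <- concordance_covariate_correlation(x, y, m_comparisons = 3)
    expect_equal(res$df, 18)
    expect_equal(res$p_adjusted, min(1, 3 * res$p_raw))
    expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
    # matches the standard implementation
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate))
    expect_equal(res$t_stat, unname(ct$statistic))
  })
})

test_that("a positive availability effect is detected at scale with known sign", {
  sim <- simulate_dqa(simulation_config(seed = 77))
  scores <- concordance_score(sim$records)
  tbl <- dplyr::left_join(scores, sim$facilities, by = "facility_id")
  avail <- concordance_covariate_correlation(tbl$score, tbl$ehr_availability,
                                             m_comparisons = 3)
  expect_true(avail$r > 0)
  expect_lt(avail$p_adjusted, 0.05)
  tech <- concordance_covariate_correlation(tbl$score, tbl$tech_experience,
                                            m_comparisons = 3)
  expect_true(tech$r < 0)
})

test_that("alert-effect table counts post-cutoff record entries by group", {
  sim <- simulate_dqa(simulation_config(seed = 55))
  ae <- alert_effect_table(sim$records, sim$facilities, "vl", phi_ci = FALSE)
  expect_equal(sum(ae$table), sum(ae$group_summary$eligible))
  expect_true(all(ae$table >= 0))
  # percentages recompute from counts
  expect_equal(ae$group_summary$pct_matched,
               100 * ae$group_summary$matched / ae$group_summary$eligible)
  # facility percentages cover both arms and are ranked
  expect_false(is.unsorted(-ae$facility_pct$pct_matched))
  # with the configured positive alert effect the alert group is higher
  gs <- ae$group_summary
  expect_gt(gs$pct_matched[gs$group == "alert"],
            gs$pct_matched[gs$group == "no_alert"])
  # records entirely before the cutoff abort
  pre <- sim$records
  pre$paper_date_of_last_visit <- "2018-01-15"
  pre$ehr_date_of_last_visit <- "2018-01-15"
  expect_error(alert_effect_table(pre, sim$facilities, "vl"), "cutoff")
})

test_that("a null alert effect leaves group percentages equal within error", {
  # moderate replication; the full calibration lives in the acceptance suite
  withr::with_seed(3, {
    diffs <- replicate(25, {
      cfg <- simulation_config(seed = sample.int(1e6, 1), n_facilities = 20,
                               total_records = 1200, alert_effect = 1)
      sim <- simulate_dqa(cfg)
      ae <- alert_effect_table(sim$records, sim$facilities, "vl",
                               phi_ci = FALSE)
      gs <- ae$group_summary
      gs$pct_matched[gs$group == "alert"] - gs$pct_matched[gs$group == "no_alert"]
    })
    expect_lt(abs(mean(diffs)), 3) # percentage points, should centre on 0
  })
})
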