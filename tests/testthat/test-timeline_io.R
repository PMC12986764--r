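test_that("day/month conversions use the fixed 30.4375-day month", {
  expect_identical(days_to_months(0), 0)
  expect_equal(days_to_months(365.25), 12)
  expect_equal(days_to_months(241), 241 / 30.4375)
  expect_equal(days_to_months(241), 7.9178, tolerance = 1e-4)
  expect_identical(months_to_days(12), 365L)
  expect_error(days_to_months(-1), class = "ranovol_domain_error")
  expect_error(months_to_days(-0.5), class = "ranovol_domain_error")
  # strict monotonicity over a grid
  d <- sort(runif(50, 0, 2000))
  expect_true(all(diff(days_to_months(d)) > 0))
})

test_that("cohort files round-trip through write_cohort/read_cohort", {
  sim <- small_sim()
  meta <- withr::local_tempfile(fileext = ".csv")
  scans <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$timelines, meta, scans)
  back <- read_cohort(meta, scans)
  expect_length(back, length(sim$timelines))
  for (i in seq_along(back)) {
    a <- sim$timelines[[i]]
    b <- back[[i]]
    expect_identical(a$patient_id, b$patient_id)
    for (f in c("surgery_day", "rt_start_day", "rt_end_day", "last_followup_day",
                "alive_at_last_followup")) {
      expect_identical(a[[f]], b[[f]], info = paste(a$patient_id, f))
    }
    expect_identical(is.null(a$death_day), is.null(b$death_day))
    expect_identical(vapply(a$scans, `[[`, integer(1), "scan_day"),
                     vapply(b$scans, `[[`, integer(1), "scan_day"))
    for (k in seq_along(a$scans)) {
      la <- a$scans[[k]]$lesions
      lb <- b$scans[[k]]$lesions
      ord_a <- order(la$lesion_id, la$compartment)
      ord_b <- order(lb$lesion_id, lb$compartment)
      expect_equal(la$volume_cm3[ord_a], lb$volume_cm3[ord_b], tolerance = 1e-12)
      expect_identical(la$is_new[ord_a], lb$is_new[ord_b])
    }
  }
})

test_that("scan ordering is invariant under input-row permutation", {
  sim <- small_sim()
  meta <- withr::local_tempfile(fileext = ".csv")
  scans <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$timelines, meta, scans)
  df <- read.csv(scans, stringsAsFactors = FALSE)
  set.seed(1)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE, quote = FALSE)
  a <- read_cohort(meta, scans)
  b <- read_cohort(meta, shuffled)
  for (i in seq_along(a)) {
    expect_identical(vapply(a[[i]]$scans, `[[`, integer(1), "scan_day"),
                     vapply(b[[i]]$scans, `[[`, integer(1), "scan_day"))
  }
})

test_that("schema and invariant violations are rejected with informative errors", {
  sim <- small_sim()
  meta <- withr::local_tempfile(fileext = ".csv")
  scans <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$timelines, meta, scans)

  m <- read.csv(meta, stringsAsFactors = FALSE, colClasses = "character")
  # surgery 20 days after the preoperative MRI violates the 1-14 day window
  m2 <- m
  m2$surgery_date[1] <- format(as.Date(m2$diagnosis_date[1]) + 20, "%Y-%m-%d")
  bad_meta <- withr::local_tempfile(fileext = ".csv")
  write.csv(m2, bad_meta, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad_meta, scans), "1-14 days",
               class = "ranovol_validation_error")

  s <- read.csv(scans, stringsAsFactors = FALSE)
  s2 <- s
  s2$volume_cm3[1] <- -0.5
  bad_scans <- withr::local_tempfile(fileext = ".csv")
  write.csv(s2, bad_scans, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(meta, bad_scans), "volume_cm3",
               class = "ranovol_validation_error")

  s3 <- rbind(s, s[1, ])
  dup_scans <- withr::local_tempfile(fileext = ".csv")
  write.csv(s3, dup_scans, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(meta, dup_scans), class = "ranovol_integrity_error")

  s4 <- s[, setdiff(names(s), "compartment")]
  noc <- withr::local_tempfile(fileext = ".csv")
  write.csv(s4, noc, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(meta, noc), "compartment", class = "ranovol_schema_error")

  expect_error(read_cohort("does-not-exist.csv", scans), class = "ranovol_io_error")
})

test_that("validate_timeline reports diagnostics as data, not errors", {
  t <- representative_timeline()
  expect_identical(nrow(validate_timeline(t)), 0L)

  # remove the post-RT baseline scan (day 115)
  t2 <- t
  t2$scans <- Filter(function(s) s$scan_day != 115L, t2$scans)
  d <- validate_timeline(t2)
  expect_true("missing_postrt_baseline_window" %in% d$rule_id)

  # death recorded but alive flag raised
  t3 <- patient_timeline("x", surgery_day = 7L, rt_start_day = 45L, rt_end_day = 87L,
                         scans = t$scans, death_day = 640L, last_followup_day = 640L,
                         alive_at_last_followup = TRUE)
  expect_true("death_consistency" %in% validate_timeline(t3)$rule_id)
})
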