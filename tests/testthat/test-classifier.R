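test_that("total_volume sums targets and caps CE at the 5 largest", {
  s <- scan_record(10L, lesion_table(c("a", "b"), "CE", c(1.2, 0.8)))
  expect_identical(total_volume(s, "CE"), 2.0)
  expect_identical(total_volume(scan_record(10L), "CE"), 0.0)
  s6 <- scan_record(10L, lesion_table(paste0("l", 1:6), "CE", 1:6))
  expect_identical(total_volume(s6, "CE"), 20.0)      # 2+3+4+5+6
  # NE is summed without a cap; non-target lesions never contribute
  s7 <- scan_record(10L, lesion_table(c("a", "b", "c"), "NE", c(1, 2, 4),
                                      is_target = c(TRUE, FALSE, TRUE)))
  expect_identical(total_volume(s7, "NE"), 5.0)
})

test_that("classify_scan applies the volumetric thresholds with PD > CR > PR > SD", {
  cfg <- criteria_config("RANO")
  sc <- function(ce, ne = 0, new = FALSE) {
    ids <- c("L1", if (ne > 0) "T2a", if (new) "N1")
    comp <- c("CE", if (ne > 0) "NE", if (new) "CE")
    vol <- c(ce, if (ne > 0) ne, if (new) 1.5)
    scan_record(50L, lesion_table(ids, comp, vol,
                                  is_new = c(FALSE, if (ne > 0) FALSE, if (new) TRUE)))
  }
  # +40% over nadir is progression
  expect_identical(classify_scan(sc(2.8), 10, 2.0, cfg = cfg)$label, "PD_candidate")
  expect_identical(classify_scan(sc(2.79), 3, 2.0, cfg = cfg)$label, "SD")
  # -65% from baseline is partial response
  expect_identical(classify_scan(sc(3.5), 10, 3.5, cfg = cfg)$label, "PR")
  # a doubling of nonenhancing volume is progression even with stable CE
  r <- classify_scan(sc(2.0, ne = 8.0), 10, 2.0, ne_baseline_vol = 4, ne_nadir_vol = 4,
                     cfg = cfg)
  expect_identical(r$label, "PD_candidate")
  expect_identical(r$trigger, "ne_increase")
  # disappearance of CE volume is complete response
  expect_identical(classify_scan(sc(0), 10, 0.5, cfg = cfg)$label, "CR")
  # a new measurable lesion trumps response labels
  expect_identical(classify_scan(sc(0, new = TRUE), 10, 2.0, cfg = cfg)$trigger,
                   "new_lesion")
  expect_error(classify_scan(sc(1), -1, 0, cfg = cfg), class = "ranovol_domain_error")
})

test_that("sub-measurable changes never raise a progression candidate", {
  cfg <- criteria_config("RANO")
  s <- scan_record(50L, lesion_table("L1", "CE", 0.9))
  expect_identical(classify_scan(s, 0, 0, cfg = cfg)$label, "SD")
  snew <- scan_record(50L, lesion_table(c("L1", "N1"), "CE", c(0.2, 0.5),
                                        is_new = c(FALSE, TRUE)))
  expect_identical(classify_scan(snew, 0.2, 0.2, cfg = cfg)$label, "SD")
})

test_that("select_baseline picks the criterion-specific window", {
  t <- representative_timeline()
  expect_identical(select_baseline(t, criteria_config("RANO"))$scan_day, 8L)
  expect_identical(select_baseline(t, criteria_config("mRANO"))$scan_day, 115L)
  expect_identical(select_baseline(t, criteria_config("RANO2"))$scan_day, 115L)

  t2 <- t
  t2$scans <- Filter(function(s) s$scan_day != 115L, t2$scans)
  expect_error(select_baseline(t2, criteria_config("mRANO")),
               class = "ranovol_baseline_missing")

  # two scans in the post-RT window: earliest wins with a warning
  t3 <- t
  t3$scans <- append(t3$scans, list(scan_record(120L, lesion_table("L1", "CE", 0.4))), after = 3)
  t3$scans <- t3$scans[order(vapply(t3$scans, `[[`, integer(1), "scan_day"))]
  expect_warning(b <- select_baseline(t3, criteria_config("RANO2")), "multiple")
  expect_identical(b$scan_day, 115L)
})

test_that("non-imaging events backdate progression to the last prior scan", {
  t <- representative_timeline()
  mk <- function(reres = NULL, bev = NULL, scan_days = c(100L, 200L, 372L)) {
    patient_timeline("GB-0110", surgery_day = 7L, rt_start_day = 45L, rt_end_day = 87L,
                     scans = lapply(scan_days, function(d)
                       scan_record(d, lesion_table("L1", "CE", 0.5))),
                     reresection_day = reres, bevacizumab_start_day = bev,
                     last_followup_day = 600L, alive_at_last_followup = TRUE)
  }
  censored <- structure(list(patient_id = "GB-0110", criterion = "RANO",
                             progressed = FALSE, progression_day = NULL,
                             censor_day = 372L, reason = "censored_sd_last_scan"),
                        class = "progression_call")
  out <- apply_nonimaging_events(censored, mk(reres = 400L))
  expect_true(out$progressed)
  expect_identical(out$progression_day, 372L)
  expect_identical(out$reason, "reresection")

  pd300 <- structure(list(patient_id = "GB-0110", criterion = "RANO",
                          progressed = TRUE, progression_day = 300L,
                          censor_day = NULL, reason = "imaging_PD"),
                     class = "progression_call")
  out2 <- apply_nonimaging_events(pd300, mk(bev = 350L))
  expect_identical(out2$progression_day, 300L)
  expect_identical(out2$reason, "imaging_PD")

  out3 <- apply_nonimaging_events(censored, mk(bev = 500L, scan_days = c(100L, 200L, 480L)))
  expect_identical(out3$progression_day, 480L)
  expect_identical(out3$reason, "bevacizumab")

  expect_error(apply_nonimaging_events(censored, mk(reres = 50L)),
               class = "ranovol_validation_error")
})

test_that("pseudoprogression summary counts patients once and measures weeks from RT end", {
  t <- representative_timeline()
  tr_m <- run_criteria(t, criteria_config("mRANO"))
  # PsP scan at day 206, RT end day 87: (206 - 87) / 7 = 17 weeks
  s1 <- detect_psp_events(list(tr_m), rt_end_day = 87L)
  expect_identical(s1$count, 1L)
  expect_equal(s1$median_weeks, 17)
  expect_identical(s1$n_within_12wk, 0L)

  # arithmetic contract: 134 days after RT end is 19.142857 weeks
  fake <- list(patient_id = "x", criterion = "mRANO", baseline_day = 0L,
               assessments = data.frame(scan_day = 234L, label = "PsP",
                                        ce_total = 1, ne_total = 1,
                                        reference_baseline = 1, reference_nadir = 1,
                                        trigger = "retro_psp"),
               call = NULL, diagnostics = character(0))
  s2 <- detect_psp_events(list(fake), rt_end_day = 100L)
  expect_equal(s2$median_weeks, 134 / 7, tolerance = 1e-12)

  tr_r2 <- run_criteria(t, criteria_config("RANO2"))
  s0 <- detect_psp_events(list(tr_r2), rt_end_day = 87L)
  expect_identical(s0$count, 0L)
  expect_identical(s0$rate, 0)
})

test_that("a monotone non-increasing trajectory is censored at the last scan", {
  scans <- list(
    scan_record(8L, lesion_table("L1", "CE", 5.0)),
    scan_record(115L, lesion_table("L1", "CE", 4.0)),
    scan_record(206L, lesion_table("L1", "CE", 3.0)),
    scan_record(297L, lesion_table("L1", "CE", 3.0))
  )
  t <- patient_timeline("p", surgery_day = 7L, rt_start_day = 45L, rt_end_day = 87L,
                        scans = scans, last_followup_day = 297L,
                        alive_at_last_followup = TRUE)
  for (cr in c("RANO", "mRANO", "RANO2")) {
    call <- run_criteria(t, criteria_config(cr))$call
    expect_false(call$progressed)
    expect_identical(call$censor_day, 297L)
    expect_identical(call$reason, "censored_sd_last_scan")
  }
})
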