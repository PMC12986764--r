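# A fully worked single-patient fixture exercising every branch of the three
# state machines, mirroring the canonical teaching case for the criteria:
# gross total resection, a new measurable lesion at the second follow-up
# (beyond 12 weeks post-radiotherapy), shrinkage at the third, stability at
# the fourth, a second new lesion at the fifth, and further growth at the
# sixth.

#' Representative patient timeline
#'
#' A gross-totally-resected patient whose course separates the three
#' criteria: the new measurable lesion at the second follow-up (more than 12
#' weeks after radiotherapy) is immediate progression under the
#' post-operative-baseline criterion (RANO) and under RANO 2.0 (no
#' confirmation needed beyond the guard), but only preliminary progression
#' under mRANO; the shrinkage at the third follow-up retro-labels it
#' pseudoprogression, and the second new lesion at the fifth follow-up -
#' confirmed by further growth at the sixth - dates mRANO progression to the
#' fifth follow-up.
#'
#' Schedule (study-clock days): preoperative MRI day 0, surgery day 7,
#' post-op baseline day 8, radiotherapy days 45-87, post-RT baseline
#' (follow-up 1) day 115, follow-ups 2-6 at days 206, 297, 388, 479, 570;
#' death day 640.
#'
#' @return A [patient_timeline()].
#' @export
representative_timeline <- function() {
  scans <- list(
    scan_record(0L, lesion_table(c("L1", "T2a"), c("CE", "NE"), c(22.0, 30.0))),
    scan_record(8L, lesion_table("T2a", "NE", 9.0),
                role_hint = "postop_baseline"),                       # CE resected to 0
    scan_record(115L, lesion_table(c("L1", "T2a"), c("CE", "NE"), c(0.4, 9.0)),
                role_hint = "postrt_baseline"),
    scan_record(206L, lesion_table(c("L1", "L2", "T2a"), c("CE", "CE", "NE"),
                                   c(0.4, 1.2, 9.0),
                                   is_new = c(FALSE, TRUE, FALSE))),  # new measurable lesion
    scan_record(297L, lesion_table(c("L1", "L2", "T2a"), c("CE", "CE", "NE"),
                                   c(0.3, 0.5, 9.0))),                # shrinkage
    scan_record(388L, lesion_table(c("L1", "L2", "T2a"), c("CE", "CE", "NE"),
                                   c(0.3, 0.5, 9.0))),                # stable
    scan_record(479L, lesion_table(c("L1", "L2", "L3", "T2a"),
                                   c("CE", "CE", "CE", "NE"),
                                   c(0.3, 0.5, 1.5, 9.0),
                                   is_new = c(FALSE, FALSE, TRUE, FALSE))),  # 2nd new lesion
    scan_record(570L, lesion_table(c("L1", "L2", "L3", "T2a"),
                                   c("CE", "CE", "CE", "NE"),
                                   c(0.4, 0.8, 3.0, 10.0)))           # further growth
  )
  patient_timeline(
    patient_id = "GB-0110",
    surgery_day = 7L, rt_start_day = 45L, rt_end_day = 87L,
    scans = scans,
    death_day = 640L, last_followup_day = 640L,
    alive_at_last_followup = FALSE
  )
}
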