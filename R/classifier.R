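# Volumetric response-criteria state machines.
#
# RANO, mRANO and RANO 2.0 share the same volumetric thresholds and differ in
# two switches: which baseline scan anchors the assessment (post-operative for
# RANO, post-radiotherapy for mRANO / RANO 2.0) and when a suspected
# progression must be confirmed by the next scan (always for mRANO; only
# within the 12-week post-radiotherapy guard for RANO and RANO 2.0).

#' Criteria configuration and presets
#'
#' All thresholds and windows that distinguish the three criteria, each
#' tunable.  Defaults follow the volumetric adaptation of the RANO framework:
#' progression at a >= 40% increase in contrast-enhancing (CE) volume over the
#' nadir, a >= 100% increase in nonenhancing (NE) volume over its nadir, or a
#' new measurable lesion; partial response at a >= 65% CE decrease from
#' baseline; complete response at disappearance of CE target volume;
#' measurability floor 1 cm^3.
#'
#' @param criterion `"RANO"`, `"mRANO"` or `"RANO2"`; selects the preset
#'   `baseline_rule` / `confirmation_rule` pair.
#' @param pd_increase_frac Fractional CE increase over nadir defining
#'   suspected progression (default 0.40).
#' @param pr_decrease_frac Fractional CE decrease from baseline defining
#'   partial response (default 0.65).
#' @param cr_volume_cm3 CE total at or below which response is complete
#'   (default 0).
#' @param ne_pd_increase_frac Fractional NE increase over the NE nadir
#'   defining progression (default 1.00, i.e. a 100% increase).
#' @param measurable_min_cm3 Measurability floor in cm^3 (default 1).
#' @param confirmation_window_weeks Ideal interval to the confirming scan;
#'   the next scan outside this window is still used, with a diagnostic.
#' @param psp_extra_increase_frac Additional fractional CE increase on the
#'   confirming scan required to confirm progression (default 0.40).
#' @param early_pd_guard_weeks Post-radiotherapy guard during which suspected
#'   progression always needs confirmation (default 12 weeks from RT end).
#' @param baseline_rule `"postop"` or `"postrt"`; overrides the preset.
#' @param confirmation_rule `"never_required_after_guard"`,
#'   `"always_required"` or `"required_within_guard_only"`; overrides the
#'   preset.
#' @return A list of class `"criteria_config"`.
#' @export
criteria_config <- function(criterion = c("RANO", "mRANO", "RANO2"),
                            pd_increase_frac = 0.40,
                            pr_decrease_frac = 0.65,
                            cr_volume_cm3 = 0.0,
                            ne_pd_increase_frac = 1.00,
                            measurable_min_cm3 = 1.0,
                            confirmation_window_weeks = c(4, 8),
                            psp_extra_increase_frac = 0.40,
                            early_pd_guard_weeks = 12,
                            baseline_rule = NULL,
                            confirmation_rule = NULL) {
  criterion <- match.arg(criterion)
  preset <- switch(criterion,
    RANO  = list(baseline_rule = "postop", confirmation_rule = "never_required_after_guard"),
    mRANO = list(baseline_rule = "postrt", confirmation_rule = "always_required"),
    RANO2 = list(baseline_rule = "postrt", confirmation_rule = "required_within_guard_only")
  )
  baseline_rule <- if (is.null(baseline_rule)) preset$baseline_rule else
    match.arg(baseline_rule, c("postop", "postrt"))
  confirmation_rule <- if (is.null(confirmation_rule)) preset$confirmation_rule else
    match.arg(confirmation_rule, c("never_required_after_guard", "always_required",
                                   "required_within_guard_only"))
  if (pd_increase_frac < 0 || pr_decrease_frac < 0 || ne_pd_increase_frac < 0 ||
      psp_extra_increase_frac < 0) {
    ranovol_abort("criteria fractions must be >= 0", "ranovol_domain_error")
  }
  if (measurable_min_cm3 <= 0) {
    ranovol_abort("measurable_min_cm3 must be > 0", "ranovol_domain_error")
  }
  if (confirmation_window_weeks[1] >= confirmation_window_weeks[2]) {
    ranovol_abort("confirmation window lower bound must be < upper bound",
                  "ranovol_domain_error")
  }
  structure(list(
    criterion = criterion,
    pd_increase_frac = pd_increase_frac,
    pr_decrease_frac = pr_decrease_frac,
    cr_volume_cm3 = cr_volume_cm3,
    ne_pd_increase_frac = ne_pd_increase_frac,
    measurable_min_cm3 = measurable_min_cm3,
    confirmation_window_weeks = confirmation_window_weeks,
    psp_extra_increase_frac = psp_extra_increase_frac,
    early_pd_guard_weeks = early_pd_guard_weeks,
    baseline_rule = baseline_rule,
    confirmation_rule = confirmation_rule
  ), class = "criteria_config")
}

#' Summed target volume of one compartment at one scan
#'
#' Sums `volume_cm3` over target lesions of the compartment.  For CE, at most
#' the 5 largest target lesions contribute (ties broken by lesion id for
#' determinism); NE target lesions are summed without a cap.
#'
#' @param s A [scan_record()].
#' @param compartment `"CE"` or `"NE"`.
#' @return Total volume in cm^3; `0` when the compartment is empty.
#' @export
total_volume <- function(s, compartment = c("CE", "NE")) {
  compartment <- match.arg(compartment)
  les <- s$lesions
  les <- les[les$compartment == compartment & les$is_target, , drop = FALSE]
  if (!nrow(les)) return(0.0)
  if (compartment == "CE" && nrow(les) > 5L) {
    ord <- order(-les$volume_cm3, les$lesion_id)
    les <- les[ord[1:5], , drop = FALSE]
  }
  sum(les$volume_cm3)
}

new_measurable_lesion <- function(s, cfg) {
  les <- s$lesions
  any(les$is_new & les$volume_cm3 >= cfg$measurable_min_cm3)
}

# Progression-candidate test against current nadirs.  The CE/NE increase must
# amount to measurable disease (total >= measurability floor) and be a strict
# increase, so a flat zero-volume trajectory never triggers.
pd_trigger <- function(ce, ne, has_new, nadir_ce, nadir_ne, cfg) {
  if (ce >= (1 + cfg$pd_increase_frac) * nadir_ce &&
      ce >= cfg$measurable_min_cm3 && ce > nadir_ce) {
    return("ce_increase")
  }
  if (ne >= (1 + cfg$ne_pd_increase_frac) * nadir_ne &&
      ne >= cfg$measurable_min_cm3 && ne > nadir_ne) {
    return("ne_increase")
  }
  if (has_new) return("new_lesion")
  "none"
}

#' Classify a single scan against reference volumes
#'
#' Raw per-scan label with precedence PD-candidate > CR > PR > SD: suspected
#' progression on a >= `pd_increase_frac` CE increase over the nadir (when the
#' increase amounts to measurable disease), a >= `ne_pd_increase_frac` NE
#' increase over the NE nadir, or a new measurable lesion; otherwise complete
#' response at CE total <= `cr_volume_cm3`, partial response at CE total <=
#' `(1 - pr_decrease_frac) *` baseline, else stable disease.
#'
#' @param current A [scan_record()].
#' @param baseline_vol,nadir_vol CE reference volumes (cm^3).
#' @param ne_baseline_vol,ne_nadir_vol NE reference volumes (cm^3).
#' @param cfg A [criteria_config()].
#' @return A list with `label` (`"PD_candidate"`, `"CR"`, `"PR"` or `"SD"`)
#'   and `trigger` (`"none"`, `"ce_increase"`, `"ne_increase"`,
#'   `"new_lesion"`).
#' @export
classify_scan <- function(current, baseline_vol, nadir_vol,
                          ne_baseline_vol = 0, ne_nadir_vol = 0, cfg) {
  if (baseline_vol < 0 || nadir_vol < 0 || ne_baseline_vol < 0 || ne_nadir_vol < 0) {
    ranovol_abort("reference volumes must be non-negative", "ranovol_domain_error")
  }
  ce <- total_volume(current, "CE")
  ne <- total_volume(current, "NE")
  trig <- pd_trigger(ce, ne, new_measurable_lesion(current, cfg),
                     nadir_ce = nadir_vol, nadir_ne = ne_nadir_vol, cfg = cfg)
  label <- if (trig != "none") {
    "PD_candidate"
  } else if (ce <= cfg$cr_volume_cm3) {
    "CR"
  } else if (ce <= (1 - cfg$pr_decrease_frac) * baseline_vol) {
    "PR"
  } else {
    "SD"
  }
  list(label = label, trigger = trig)
}

#' Select the baseline scan for a criterion
#'
#' The post-operative rule picks the unique scan 1-2 days after surgery
#' (24-48 h); the post-radiotherapy rule picks the unique scan 21-35 days
#' after the end of radiotherapy.  With several scans in the window the
#' earliest is chosen and a `"multiple_baseline_candidates"` warning is
#' issued; with none, a `baseline_missing` error is raised (such patients are
#' excluded from the criterion, mirroring the cohort inclusion rules).
#'
#' @param t A [patient_timeline()].
#' @param cfg A [criteria_config()].
#' @return The baseline [scan_record()].
#' @export
select_baseline <- function(t, cfg) {
  win <- if (cfg$baseline_rule == "postop") {
    c(t$surgery_day + 1L, t$surgery_day + 2L)
  } else {
    c(t$rt_end_day + 21L, t$rt_end_day + 35L)
  }
  sd <- scan_days(t)
  idx <- which(sd >= win[1] & sd <= win[2])
  if (!length(idx)) {
    ranovol_abort(sprintf(
      "patient %s: no %s baseline scan in window day %d-%d",
      t$patient_id, cfg$baseline_rule, win[1], win[2]),
      "ranovol_baseline_missing")
  }
  if (length(idx) > 1L) {
    warning(sprintf("patient %s: multiple scans in %s baseline window; using day %d",
                    t$patient_id, cfg$baseline_rule, sd[idx[1]]),
            call. = FALSE)
  }
  t$scans[[idx[1]]]
}

progression_call <- function(patient_id, criterion, progressed,
                             progression_day = NULL, censor_day = NULL, reason) {
  structure(list(
    patient_id = patient_id, criterion = criterion, progressed = progressed,
    progression_day = progression_day, censor_day = censor_day, reason = reason
  ), class = "progression_call")
}

#' Run one response criterion over a patient timeline
#'
#' Walks the scans after the criterion's baseline in order, maintaining CE
#' and NE nadirs (minimum totals from baseline onward, updated only by
#' non-progressive scans).  A suspected progression is finalized immediately
#' when no confirmation is required (RANO and RANO 2.0 beyond the 12-week
#' post-RT guard), otherwise the next scan decides: a further
#' >= `psp_extra_increase_frac` CE increase or additional new measurable
#' lesions confirm, and the progression is back-dated to the scan of first
#' suspicion; otherwise the suspicious scan is relabelled pseudoprogression
#' (PsP) and the walk resumes with the nadir reset at the resolving scan.  A
#' suspicion pending at the end of follow-up is censored, not converted.
#' Non-imaging overrides (re-resection, bevacizumab) are applied afterwards
#' via [apply_nonimaging_events()].
#'
#' @param t A [patient_timeline()].
#' @param cfg A [criteria_config()].
#' @param apply_events Apply non-imaging overrides (default `TRUE`).
#' @return An `"assessment_track"`: list with `patient_id`, `criterion`,
#'   `baseline_day`, `assessments` (one data.frame row per assessed scan:
#'   `scan_day`, `label`, `ce_total`, `ne_total`, `reference_baseline`,
#'   `reference_nadir`, `trigger`), `call` (a progression call) and
#'   `diagnostics` (character).
#' @export
run_criteria <- function(t, cfg, apply_events = TRUE) {
  bl <- select_baseline(t, cfg)
  base_ce <- total_volume(bl, "CE")
  base_ne <- total_volume(bl, "NE")
  nadir_ce <- base_ce
  nadir_ne <- base_ne
  guard_end <- t$rt_end_day + round(cfg$early_pd_guard_weeks * 7)

  after <- Filter(function(s) s$scan_day > bl$scan_day, t$scans)
  rows <- list()
  diags <- character(0)
  emit <- function(s, label, ce, ne, nadir, trigger) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scan_day = s$scan_day, label = label, ce_total = ce, ne_total = ne,
      reference_baseline = base_ce, reference_nadir = nadir, trigger = trigger,
      stringsAsFactors = FALSE
    )
  }

  call <- NULL
  i <- 1L
  n <- length(after)
  while (i <= n) {
    s <- after[[i]]
    ce <- total_volume(s, "CE")
    ne <- total_volume(s, "NE")
    cls <- classify_scan(s, base_ce, nadir_ce, base_ne, nadir_ne, cfg)

    if (cls$label != "PD_candidate") {
      emit(s, cls$label, ce, ne, nadir_ce, "none")
      nadir_ce <- min(nadir_ce, ce)
      nadir_ne <- min(nadir_ne, ne)
      i <- i + 1L
      next
    }

    within_guard <- s$scan_day <= guard_end
    need_conf <- switch(cfg$confirmation_rule,
      always_required = TRUE,
      never_required_after_guard = within_guard,
      required_within_guard_only = within_guard
    )

    if (!need_conf) {
      emit(s, "PD", ce, ne, nadir_ce, cls$trigger)
      call <- progression_call(t$patient_id, cfg$criterion, TRUE,
                               progression_day = s$scan_day, reason = "imaging_PD")
      break
    }

    if (i == n) {
      # suspicion with no further imaging: leave preliminary, censor at last scan
      emit(s, "pPD", ce, ne, nadir_ce, cls$trigger)
      call <- progression_call(t$patient_id, cfg$criterion, FALSE,
                               censor_day = s$scan_day, reason = "censored_lost")
      break
    }

    s2 <- after[[i + 1L]]
    ce2 <- total_volume(s2, "CE")
    ne2 <- total_volume(s2, "NE")
    gap_weeks <- (s2$scan_day - s$scan_day) / 7
    if (gap_weeks < cfg$confirmation_window_weeks[1] ||
        gap_weeks > cfg$confirmation_window_weeks[2]) {
      diags <- c(diags, sprintf(
        "confirmation scan at day %d is %.1f weeks after suspicion (ideal %g-%g)",
        s2$scan_day, gap_weeks,
        cfg$confirmation_window_weeks[1], cfg$confirmation_window_weeks[2]))
    }
    # confirmation demands *further* growth: an additional >= 40% volume
    # increase (in either compartment) or additional new measurable lesions
    confirms <- (ce2 >= (1 + cfg$psp_extra_increase_frac) * ce && ce2 > ce) ||
      (ne2 >= (1 + cfg$psp_extra_increase_frac) * ne && ne2 > ne) ||
      new_measurable_lesion(s2, cfg)

    if (confirms) {
      emit(s, "PD", ce, ne, nadir_ce, cls$trigger)
      emit(s2, "PD", ce2, ne2, nadir_ce, "confirmation")
      call <- progression_call(t$patient_id, cfg$criterion, TRUE,
                               progression_day = s$scan_day, reason = "imaging_PD")
      break
    }

    # pseudoprogression: the suspicious scan is relabelled retrospectively and
    # the nadir restarts at the resolving scan (the transient peak is never a
    # reference, and pre-episode lows would re-trigger immediately).
    emit(s, "PsP", ce, ne, nadir_ce, "retro_psp")
    nadir_ce <- ce2
    nadir_ne <- ne2
    cls2 <- classify_scan(s2, base_ce, nadir_ce, base_ne, nadir_ne, cfg)
    emit(s2, if (cls2$label == "PD_candidate") "SD" else cls2$label,
         ce2, ne2, nadir_ce, "none")
    i <- i + 2L
  }

  if (is.null(call)) {
    last_day <- if (length(rows)) rows[[length(rows)]]$scan_day else bl$scan_day
    call <- progression_call(t$patient_id, cfg$criterion, FALSE,
                             censor_day = last_day, reason = "censored_sd_last_scan")
  }

  assessments <- if (length(rows)) do.call(rbind, rows) else data.frame(
    scan_day = integer(0), label = character(0), ce_total = numeric(0),
    ne_total = numeric(0), reference_baseline = numeric(0),
    reference_nadir = numeric(0), trigger = character(0), stringsAsFactors = FALSE
  )
  track <- structure(list(
    patient_id = t$patient_id, criterion = cfg$criterion,
    baseline_day = bl$scan_day, assessments = assessments,
    call = call, diagnostics = diags
  ), class = "assessment_track")
  if (apply_events) track$call <- apply_nonimaging_events(track$call, t)
  track
}

#' Apply re-resection / bevacizumab progression overrides
#'
#' When a re-resection or start of second-line bevacizumab is recorded and no
#' imaging progression was dated at or before that event, the patient is
#' considered progressed at the last scan strictly before the event; earlier
#' imaging progression is never overridden.
#'
#' @param call A progression call from [run_criteria()].
#' @param t The matching [patient_timeline()].
#' @return The (possibly updated) progression call.
#' @export
apply_nonimaging_events <- function(call, t) {
  events <- list()
  if (!is.null(t$reresection_day)) events$reresection <- t$reresection_day
  if (!is.null(t$bevacizumab_start_day)) events$bevacizumab <- t$bevacizumab_start_day
  if (!length(events)) return(call)
  sd <- scan_days(t)
  for (nm in names(events)[order(unlist(events))]) {
    ev <- events[[nm]]
    if (call$progressed && call$progression_day <= ev) next
    prior <- sd[sd < ev]
    if (!length(prior)) {
      ranovol_abort(sprintf(
        "patient %s: %s at day %d precedes all scans", t$patient_id, nm, ev),
        "ranovol_validation_error")
    }
    call <- progression_call(call$patient_id, call$criterion, TRUE,
                             progression_day = max(prior), reason = nm)
  }
  call
}

#' Summarize pseudoprogression events across tracks
#'
#' A patient counts once if any scan in their track is labelled PsP; the time
#' of PsP is measured in 7-day weeks from the end of radiotherapy to the
#' (first) PsP scan.
#'
#' @param tracks List of `"assessment_track"` objects from a
#'   confirmation-bearing criterion.
#' @param rt_end_day Integer vector of RT end days, one per track (recycled).
#' @return List with `count`, `rate` (fraction of tracks), `weeks` (one entry
#'   per PsP patient), `median_weeks` and `n_within_12wk`.
#' @export
detect_psp_events <- function(tracks, rt_end_day) {
  rt_end_day <- rep_len(rt_end_day, length(tracks))
  weeks <- numeric(0)
  for (k in seq_along(tracks)) {
    a <- tracks[[k]]$assessments
    psp <- a$scan_day[a$label == "PsP"]
    if (length(psp)) weeks <- c(weeks, (psp[1] - rt_end_day[k]) / 7)
  }
  list(
    count = length(weeks),
    rate = if (length(tracks)) length(weeks) / length(tracks) else 0,
    weeks = weeks,
    median_weeks = if (length(weeks)) stats::median(weeks) else NA_real_,
    n_within_12wk = sum(weeks <= 12)
  )
}
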