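# Per-patient survival endpoints derived from progression calls.
#
# PFS runs from the preoperative MRI (day 0) to progression or censoring;
# OS from day 0 to death or last follow-up; PPS from progression to death or
# last follow-up (defined only for progressed patients).  All endpoints are
# reported in months (see DAYS_PER_MONTH).

#' Compute PFS / PPS / OS for one patient under one criterion
#'
#' @param t A [patient_timeline()].
#' @param call The matching progression call (from [run_criteria()]).
#' @return One-row `data.frame` with `patient_id`, `criterion`, `pfs_months`,
#'   `pfs_event`, `pps_months`, `pps_event` (NA when not progressed),
#'   `os_months`, `os_event`.
#' @export
compute_endpoints <- function(t, call) {
  if (!identical(call$patient_id, t$patient_id)) {
    ranovol_abort("progression call does not belong to this timeline",
                  "ranovol_validation_error")
  }
  os_day <- if (!is.null(t$death_day)) t$death_day else t$last_followup_day
  os_event <- !is.null(t$death_day)

  if (call$progressed) {
    if (!is.null(t$death_day) && call$progression_day > t$death_day) {
      ranovol_abort(sprintf("patient %s: progression day %d after death day %d",
                            t$patient_id, call$progression_day, t$death_day),
                    "ranovol_validation_error")
    }
    pfs_day <- call$progression_day
    pfs_event <- TRUE
    pps_months <- days_to_months(os_day - pfs_day)
    pps_event <- os_event
  } else {
    pfs_day <- call$censor_day
    pfs_event <- FALSE
    pps_months <- NA_real_
    pps_event <- NA
  }
  data.frame(
    patient_id = t$patient_id, criterion = call$criterion,
    pfs_months = days_to_months(pfs_day), pfs_event = pfs_event,
    pps_months = pps_months, pps_event = pps_event,
    os_months = days_to_months(os_day), os_event = os_event,
    stringsAsFactors = FALSE
  )
}

#' Long endpoint table for a cohort
#'
#' One row per patient per criterion, ordered by (`patient_id`,
#' `criterion`).  Every patient must carry exactly one call per criterion.
#'
#' @param timelines List of [patient_timeline()] objects.
#' @param calls Named list: one entry per criterion, each a list of
#'   progression calls covering every timeline.
#' @return `data.frame` with `length(timelines) * length(calls)` rows.
#' @export
cohort_endpoint_table <- function(timelines, calls) {
  tl_ids <- vapply(timelines, function(t) t$patient_id, character(1))
  rows <- list()
  for (crit in names(calls)) {
    cl <- calls[[crit]]
    ids <- vapply(cl, function(c) c$patient_id, character(1))
    if (anyDuplicated(ids)) {
      ranovol_abort(sprintf("criterion %s: duplicate call for patient %s",
                            crit, ids[duplicated(ids)][1]),
                    "ranovol_completeness_error")
    }
    missing <- setdiff(tl_ids, ids)
    if (length(missing)) {
      ranovol_abort(sprintf("criterion %s: missing call for patient(s) %s",
                            crit, paste(missing, collapse = ", ")),
                    "ranovol_completeness_error")
    }
    lookup <- stats::setNames(cl, ids)
    for (t in timelines) {
      rows[[length(rows) + 1L]] <- compute_endpoints(t, lookup[[t$patient_id]])
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$criterion), , drop = FALSE]
}

#' Median and interquartile range
#'
#' Linear-interpolation quartiles (R's default type 7), the convention used
#' for every endpoint summary in the package.
#'
#' @param x Numeric vector (NAs dropped).
#' @return List with `median`, `iqr`, `q1`, `q3`, `n`.
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(median = NA_real_, iqr = NA_real_,
                              q1 = NA_real_, q3 = NA_real_, n = 0L))
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], iqr = q[3] - q[1], q1 = q[1], q3 = q[3], n = length(x))
}
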