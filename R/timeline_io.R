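# Cohort data model and delimited-text I/O.
#
# All times inside the package are integer day offsets on a "study clock"
# anchored at the preoperative MRI (day 0, the date of diagnosis).  Calendar
# dates in input files are converted to day offsets at read time; writers
# convert back against a fixed origin date.

#' Days per month used for all endpoint conversions
#'
#' One twelfth of a Julian year (365.25 / 12 = 30.4375 days).  Survival
#' endpoints are computed in days and reported in months via this constant.
#'
#' @export
DAYS_PER_MONTH <- 30.4375

ranovol_abort <- function(message, class) {
  stop(structure(
    class = c(class, "ranovol_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

#' Convert study-clock days to months
#'
#' @param d Non-negative number of days.
#' @param month_days Days per month (default [DAYS_PER_MONTH]).
#' @return `d / month_days`, exact to floating precision.
#' @examples
#' days_to_months(365.25)  # 12
#' @export
days_to_months <- function(d, month_days = DAYS_PER_MONTH) {
  if (any(d < 0, na.rm = TRUE)) {
    ranovol_abort("days_to_months(): days must be non-negative", "ranovol_domain_error")
  }
  d / month_days
}

#' Convert months to the nearest integer study-clock day
#'
#' @param m Non-negative number of months.
#' @inheritParams days_to_months
#' @return Integer day count, rounded to the nearest day.
#' @export
months_to_days <- function(m, month_days = DAYS_PER_MONTH) {
  if (any(m < 0, na.rm = TRUE)) {
    ranovol_abort("months_to_days(): months must be non-negative", "ranovol_domain_error")
  }
  as.integer(round(m * month_days))
}

#' Build a lesion table for one scan
#'
#' One row per lesion per compartment.  `CE` is contrast-enhancing tumor on
#' post-gadolinium T1; `NE` is nonenhancing T2/FLAIR abnormality.  Volumes are
#' in cubic centimetres.
#'
#' @param lesion_id Character vector of lesion identifiers.
#' @param compartment `"CE"` or `"NE"`, recycled.
#' @param volume_cm3 Non-negative lesion volumes (cm^3).
#' @param is_target Logical; lesions eligible for the summed target volume.
#' @param is_new Logical; `TRUE` at the scan where a lesion first appears.
#' @return A `data.frame` with the five columns above.
#' @export
lesion_table <- function(lesion_id, compartment, volume_cm3,
                         is_target = TRUE, is_new = FALSE) {
  df <- data.frame(
    lesion_id = as.character(lesion_id),
    compartment = as.character(compartment),
    volume_cm3 = as.numeric(volume_cm3),
    is_target = rep_len(as.logical(is_target), length(lesion_id)),
    is_new = rep_len(as.logical(is_new), length(lesion_id)),
    stringsAsFactors = FALSE
  )
  if (any(!df$compartment %in% c("CE", "NE"))) {
    ranovol_abort("lesion compartment must be 'CE' or 'NE'", "ranovol_validation_error")
  }
  if (any(df$volume_cm3 < 0)) {
    ranovol_abort("lesion volume_cm3 must be non-negative", "ranovol_validation_error")
  }
  df
}

empty_lesion_table <- function() {
  lesion_table(character(0), character(0), numeric(0))
}

#' Construct a scan record
#'
#' @param scan_day Integer day offset from the preoperative MRI (day 0).
#' @param lesions A lesion table (see [lesion_table()]); may be empty.
#' @param role_hint Optional `"postop_baseline"`, `"postrt_baseline"` or
#'   `"followup"`.
#' @return A list of class `"scan_record"`.
#' @export
scan_record <- function(scan_day, lesions = empty_lesion_table(), role_hint = NULL) {
  if (length(scan_day) != 1L || is.na(scan_day) || scan_day < 0) {
    ranovol_abort("scan_day must be a single non-negative integer", "ranovol_validation_error")
  }
  structure(
    list(scan_day = as.integer(scan_day), lesions = lesions, role_hint = role_hint),
    class = "scan_record"
  )
}

#' Construct a patient timeline
#'
#' A timeline bundles one patient's dated clinical events (surgery,
#' radiotherapy, optional re-resection / bevacizumab start, death or last
#' follow-up) with an ordered series of scans.  Scans are sorted by
#' `scan_day` on construction; full invariant checking is performed by
#' [validate_timeline()].
#'
#' @param patient_id Opaque patient identifier.
#' @param surgery_day,rt_start_day,rt_end_day Integer day offsets.
#' @param scans List of [scan_record()] objects.
#' @param last_followup_day Day of death or last documented visit.
#' @param alive_at_last_followup Logical.
#' @param diagnosis_day Day of the preoperative MRI; 0 by convention.
#' @param reresection_day,bevacizumab_start_day,death_day Optional day offsets.
#' @return A list of class `"patient_timeline"`.
#' @export
patient_timeline <- function(patient_id, surgery_day, rt_start_day, rt_end_day,
                             scans, last_followup_day, alive_at_last_followup,
                             diagnosis_day = 0L, reresection_day = NULL,
                             bevacizumab_start_day = NULL, death_day = NULL) {
  ord <- order(vapply(scans, function(s) s$scan_day, integer(1)))
  structure(
    list(
      patient_id = as.character(patient_id),
      diagnosis_day = as.integer(diagnosis_day),
      surgery_day = as.integer(surgery_day),
      rt_start_day = as.integer(rt_start_day),
      rt_end_day = as.integer(rt_end_day),
      scans = scans[ord],
      reresection_day = if (is.null(reresection_day)) NULL else as.integer(reresection_day),
      bevacizumab_start_day = if (is.null(bevacizumab_start_day)) NULL else as.integer(bevacizumab_start_day),
      death_day = if (is.null(death_day)) NULL else as.integer(death_day),
      last_followup_day = as.integer(last_followup_day),
      alive_at_last_followup = isTRUE(alive_at_last_followup)
    ),
    class = "patient_timeline"
  )
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf(
    "<patient_timeline %s: surgery d%d, RT d%d-d%d, %d scans, %s d%d>\n",
    x$patient_id, x$surgery_day, x$rt_start_day, x$rt_end_day, length(x$scans),
    if (is.null(x$death_day)) "censored" else "death", x$last_followup_day
  ))
  invisible(x)
}

scan_days <- function(t) vapply(t$scans, function(s) s$scan_day, integer(1))

diag_row <- function(patient_id, rule_id, message) {
  data.frame(patient_id = patient_id, rule_id = rule_id, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a patient timeline
#'
#' Checks every structural invariant of the data model and the windows the
#' analysis relies on.  Diagnostics are data, never errors: an empty return
#' means the timeline is well formed.
#'
#' Rules checked: event ordering (`diagnosis <= surgery < rt_start < rt_end`),
#' the 1-14 day preoperative-MRI-to-surgery window, death/alive-flag
#' consistency, scans not exceeding the last follow-up, strictly increasing
#' scan days, non-negative volumes, per-scan lesion uniqueness, and the
#' presence of the post-operative (surgery + 1-2 days) and post-radiotherapy
#' (RT end + 21-35 days) baseline windows.
#'
#' @param t A [patient_timeline()].
#' @return A `data.frame` with columns `patient_id`, `rule_id`, `message`;
#'   zero rows iff all invariants hold.
#' @export
validate_timeline <- function(t) {
  out <- list()
  pid <- t$patient_id
  add <- function(rule, msg) out[[length(out) + 1L]] <<- diag_row(pid, rule, msg)

  if (!(t$diagnosis_day <= t$surgery_day && t$surgery_day < t$rt_start_day &&
        t$rt_start_day < t$rt_end_day)) {
    add("event_order", "requires diagnosis_day <= surgery_day < rt_start_day < rt_end_day")
  }
  gap <- t$surgery_day - t$diagnosis_day
  if (gap < 1L || gap > 14L) {
    add("surgery_window", sprintf(
      "surgery %d days after the preoperative MRI; must be within 1-14 days", gap))
  }
  if (!is.null(t$death_day)) {
    if (t$alive_at_last_followup) {
      add("death_consistency", "death_day present but alive_at_last_followup is TRUE")
    }
    if (t$last_followup_day != t$death_day) {
      add("death_consistency", "last_followup_day must equal death_day when death observed")
    }
  }
  sd <- scan_days(t)
  if (length(sd)) {
    if (any(sd < 0L)) add("scan_day_nonnegative", "scan_day must be >= 0")
    if (any(diff(sd) <= 0L)) add("scan_day_increasing", "scan_day values must be strictly increasing")
    if (any(sd > t$last_followup_day)) {
      add("scan_before_followup_end", "every scan_day must be <= last_followup_day")
    }
  }
  for (s in t$scans) {
    les <- s$lesions
    if (nrow(les)) {
      if (any(les$volume_cm3 < 0)) {
        add("volume_nonnegative", sprintf("negative volume_cm3 at scan day %d", s$scan_day))
      }
      key <- paste(les$lesion_id, les$compartment)
      if (anyDuplicated(key)) {
        add("lesion_unique_per_scan", sprintf(
          "duplicate lesion/compartment at scan day %d", s$scan_day))
      }
    }
  }
  if (!any(sd >= t$surgery_day + 1L & sd <= t$surgery_day + 2L)) {
    add("missing_postop_baseline_window",
        "no scan 24-48 h (1-2 days) after surgery: post-operative baseline missing")
  }
  if (!any(sd >= t$rt_end_day + 21L & sd <= t$rt_end_day + 35L)) {
    add("missing_postrt_baseline_window",
        "no scan 21-35 days after radiotherapy end: post-RT baseline window missing")
  }
  if (length(out)) do.call(rbind, out) else diag_row(character(0), character(0), character(0))
}

# Rules that make a cohort file unreadable (as opposed to analytic exclusions,
# e.g. a missing baseline window, which select_baseline() handles per criterion).
FATAL_RULES <- c("event_order", "surgery_window", "death_consistency",
                 "scan_day_nonnegative", "scan_day_increasing",
                 "scan_before_followup_end", "volume_nonnegative",
                 "lesion_unique_per_scan")

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    ranovol_abort(
      sprintf("%s: missing required column(s): %s", path, paste(missing, collapse = ", ")),
      "ranovol_schema_error"
    )
  }
}

parse_date <- function(x, col, path) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- !is.na(x) & x != "" & is.na(d)
  if (any(bad)) {
    ranovol_abort(sprintf("%s: column %s contains non-ISO-8601 dates", path, col),
                  "ranovol_schema_error")
  }
  d
}

#' Read a cohort from delimited text files
#'
#' `cohort_meta.csv` holds one row per patient with ISO-8601 event dates;
#' `cohort_scans.csv` holds one row per lesion per compartment per scan.  All
#' dates are converted to integer day offsets from each patient's
#' `diagnosis_date` (the preoperative MRI).
#'
#' @param metadata_path Path to the patient metadata CSV.
#' @param scans_path Path to the per-lesion scan CSV.
#' @return A list of [patient_timeline()] objects, scans sorted by day.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(metadata_path, scans_path) {
  for (p in c(metadata_path, scans_path)) {
    if (!file.exists(p)) {
      ranovol_abort(sprintf("input file not found: %s", p), "ranovol_io_error")
    }
  }
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  scans <- utils::read.csv(scans_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  require_columns(meta, c("patient_id", "diagnosis_date", "surgery_date",
                          "rt_start_date", "rt_end_date", "reresection_date",
                          "bevacizumab_start_date", "death_date",
                          "last_followup_date", "alive"), metadata_path)
  require_columns(scans, c("patient_id", "scan_date", "lesion_id",
                           "compartment", "volume_cm3", "is_new"), scans_path)

  key <- paste(scans$patient_id, scans$scan_date, scans$lesion_id, scans$compartment)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    ranovol_abort(sprintf("%s: duplicate (patient, scan, lesion, compartment) row: %s",
                          scans_path, dup), "ranovol_integrity_error")
  }

  scans$scan_date <- parse_date(scans$scan_date, "scan_date", scans_path)
  scans$volume_cm3 <- as.numeric(scans$volume_cm3)
  if (any(is.na(scans$volume_cm3))) {
    ranovol_abort(sprintf("%s: non-numeric volume_cm3", scans_path), "ranovol_schema_error")
  }
  if (any(scans$volume_cm3 < 0)) {
    ranovol_abort(sprintf("%s: volume_cm3 must be non-negative", scans_path),
                  "ranovol_validation_error")
  }
  scans$is_new <- scans$is_new %in% c("1", "TRUE", "true")

  timelines <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    pid <- row$patient_id
    d0 <- parse_date(row$diagnosis_date, "diagnosis_date", metadata_path)
    day_of <- function(col) {
      v <- row[[col]]
      if (is.na(v) || v == "") return(NULL)
      as.integer(parse_date(v, col, metadata_path) - d0)
    }
    ps <- scans[scans$patient_id == pid, , drop = FALSE]
    sr <- list()
    for (dte in sort(unique(ps$scan_date))) {
      rows <- ps[ps$scan_date == dte, , drop = FALSE]
      sr[[length(sr) + 1L]] <- scan_record(
        scan_day = as.integer(as.Date(dte, origin = "1970-01-01") - d0),
        lesions = lesion_table(rows$lesion_id, rows$compartment,
                               rows$volume_cm3, is_new = rows$is_new)
      )
    }
    timelines[[i]] <- patient_timeline(
      patient_id = pid,
      surgery_day = day_of("surgery_date"),
      rt_start_day = day_of("rt_start_date"),
      rt_end_day = day_of("rt_end_date"),
      scans = sr,
      reresection_day = day_of("reresection_date"),
      bevacizumab_start_day = day_of("bevacizumab_start_date"),
      death_day = day_of("death_date"),
      last_followup_day = day_of("last_followup_date"),
      alive_at_last_followup = row$alive %in% c("1", "TRUE", "true")
    )
  }

  diags <- do.call(rbind, lapply(timelines, validate_timeline))
  fatal <- diags[diags$rule_id %in% FATAL_RULES, , drop = FALSE]
  if (nrow(fatal)) {
    ranovol_abort(paste0(
      "cohort validation failed:\n",
      paste(sprintf("  %s [%s]: %s", fatal$patient_id, fatal$rule_id, fatal$message),
            collapse = "\n")
    ), "ranovol_validation_error")
  }
  timelines
}

#' Write a cohort to delimited text files
#'
#' Emits the same two-file dialect that [read_cohort()] reads.  Study-clock
#' days are rendered as calendar dates against `origin` (the preoperative MRI
#' date); a read/write round trip preserves every day offset.
#'
#' @param timelines List of [patient_timeline()] objects.
#' @param metadata_path,scans_path Output CSV paths.
#' @param origin Calendar date assigned to day 0.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(timelines, metadata_path, scans_path,
                         origin = as.Date("2015-01-01")) {
  fmt <- function(day) if (is.null(day)) "" else format(origin + day, "%Y-%m-%d")
  meta <- do.call(rbind, lapply(timelines, function(t) {
    data.frame(
      patient_id = t$patient_id,
      diagnosis_date = fmt(t$diagnosis_day),
      surgery_date = fmt(t$surgery_day),
      rt_start_date = fmt(t$rt_start_day),
      rt_end_date = fmt(t$rt_end_day),
      reresection_date = fmt(t$reresection_day),
      bevacizumab_start_date = fmt(t$bevacizumab_start_day),
      death_date = fmt(t$death_day),
      last_followup_date = fmt(t$last_followup_day),
      alive = as.integer(t$alive_at_last_followup),
      stringsAsFactors = FALSE
    )
  }))
  srows <- list()
  for (t in timelines) {
    for (s in t$scans) {
      if (!nrow(s$lesions)) next
      srows[[length(srows) + 1L]] <- data.frame(
        patient_id = t$patient_id,
        scan_date = fmt(s$scan_day),
        lesion_id = s$lesions$lesion_id,
        compartment = s$lesions$compartment,
        volume_cm3 = s$lesions$volume_cm3,
        is_new = as.integer(s$lesions$is_new),
        stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, srows), scans_path, row.names = FALSE, quote = FALSE)
  invisible(c(metadata_path, scans_path))
}
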