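# End-to-end orchestration: read -> classify (x criteria) -> endpoints ->
# statistics -> report, with a manifest of checksummed outputs.

CRITERIA <- c("RANO", "mRANO", "RANO2")

#' Run the full analysis pipeline
#'
#' Reads a cohort, runs the requested response criteria over every patient
#' with both baselines available, derives endpoints and the comparative
#' statistics, and writes `assessments.csv`, `calls.csv`, `endpoints.csv`,
#' `stats_report.json` and `manifest.json` into `output_dir`.  Any stage
#' error removes partial outputs and aborts naming the stage.
#'
#' Statistics computed: per-criterion median/IQR of PFS and PPS over
#' observed events and Spearman PFS-OS correlation (patients with observed
#' progression and death); Kruskal-Wallis plus Dunn/Bonferroni across
#' criteria for PFS and PPS; landmark analyses per criterion and landmark;
#' and the pseudoprogression summary (from the always-confirming criterion's
#' tracks when available).
#'
#' @param meta_path,scans_path Cohort CSV paths (see [read_cohort()]).
#' @param output_dir Output directory (created if needed).
#' @param criteria Subset of `c("RANO", "mRANO", "RANO2")`.
#' @param landmarks Landmark months (default `c(8, 12)`).
#' @return The run manifest, invisibly (also written as JSON): inputs,
#'   criteria, per-stage row counts, excluded patients, file checksums,
#'   timestamp.
#' @export
run_all <- function(meta_path, scans_path, output_dir,
                    criteria = CRITERIA, landmarks = c(8, 12)) {
  criteria <- match.arg(criteria, CRITERIA, several.ok = TRUE)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  out_files <- file.path(output_dir, c("assessments.csv", "calls.csv",
                                       "endpoints.csv", "stats_report.json",
                                       "manifest.json"))
  stage <- "read"
  tryCatch({
    timelines <- read_cohort(meta_path, scans_path)

    stage <- "classify"
    # a patient enters the comparison only with every required baseline
    usable <- logical(length(timelines))
    for (i in seq_along(timelines)) {
      usable[i] <- all(vapply(criteria, function(cr) {
        !inherits(tryCatch(select_baseline(timelines[[i]], criteria_config(cr)),
                           error = function(e) e), "error")
      }, logical(1)))
    }
    excluded <- vapply(timelines[!usable], function(t) t$patient_id, character(1))
    timelines <- timelines[usable]
    if (!length(timelines)) {
      ranovol_abort("no patient has all required baseline scans", "ranovol_validation_error")
    }
    tracks <- lapply(criteria, function(cr) {
      cfg <- criteria_config(cr)
      lapply(timelines, function(t) suppressWarnings(run_criteria(t, cfg)))
    })
    names(tracks) <- criteria

    stage <- "endpoints"
    calls <- lapply(tracks, function(trs) lapply(trs, `[[`, "call"))
    endpoints <- cohort_endpoint_table(timelines, calls)

    stage <- "stats"
    report <- build_stats_report(timelines, tracks, endpoints, criteria, landmarks)

    stage <- "write"
    assess <- do.call(rbind, lapply(criteria, function(cr) {
      do.call(rbind, lapply(tracks[[cr]], function(tr) {
        if (!nrow(tr$assessments)) return(NULL)
        cbind(data.frame(patient_id = tr$patient_id, criterion = cr,
                         stringsAsFactors = FALSE), tr$assessments)
      }))
    }))
    calls_df <- do.call(rbind, lapply(criteria, function(cr) {
      do.call(rbind, lapply(calls[[cr]], function(cl) data.frame(
        patient_id = cl$patient_id, criterion = cl$criterion,
        progressed = cl$progressed,
        progression_day = if (is.null(cl$progression_day)) NA_integer_ else cl$progression_day,
        censor_day = if (is.null(cl$censor_day)) NA_integer_ else cl$censor_day,
        reason = cl$reason, stringsAsFactors = FALSE
      )))
    }))
    utils::write.csv(assess, out_files[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(calls_df, out_files[2], row.names = FALSE, quote = FALSE)
    utils::write.csv(endpoints, out_files[3], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report, out_files[4], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")

    manifest <- list(
      tool = "ranovol",
      version = as.character(utils::packageVersion("ranovol")),
      inputs = list(meta = normalizePath(meta_path), scans = normalizePath(scans_path)),
      criteria = criteria, landmarks = landmarks,
      n_patients_read = length(usable), n_patients_analyzed = length(timelines),
      excluded_patients = as.list(excluded),
      rows = list(assessments = nrow(assess), calls = nrow(calls_df),
                  endpoints = nrow(endpoints)),
      checksums = as.list(tools::md5sum(out_files[1:4])),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    names(manifest$checksums) <- basename(out_files[1:4])
    jsonlite::write_json(manifest, out_files[5], auto_unbox = TRUE, pretty = TRUE)
    message(sprintf("[run_all] %d/%d patients analyzed; %d criteria; outputs in %s",
                    length(timelines), length(usable), length(criteria), output_dir))
    invisible(manifest)
  }, error = function(e) {
    unlink(out_files)
    ranovol_abort(sprintf("pipeline failed at stage '%s': %s", stage,
                          conditionMessage(e)), "ranovol_pipeline_error")
  })
}

build_stats_report <- function(timelines, tracks, endpoints, criteria, landmarks) {
  per_crit <- list()
  pfs_groups <- list()
  pps_groups <- list()
  for (cr in criteria) {
    rows <- endpoints[endpoints$criterion == cr, , drop = FALSE]
    obs <- rows[rows$pfs_event & rows$os_event, , drop = FALSE]
    pfs_obs <- rows$pfs_months[rows$pfs_event]
    pps_obs <- rows$pps_months[rows$pfs_event & !is.na(rows$pps_event) & rows$pps_event]
    pfs_groups[[cr]] <- pfs_obs
    pps_groups[[cr]] <- pps_obs
    lms <- list()
    for (lm in landmarks) {
      res <- tryCatch(landmark_analysis(rows, lm), error = function(e) {
        list(landmark_months = lm, error = conditionMessage(e))
      })
      lms[[paste0("m", lm)]] <- unclass(res)
    }
    block <- list(
      n = nrow(rows),
      n_progressed = sum(rows$pfs_event),
      pfs = median_iqr(pfs_obs),
      pps = median_iqr(pps_obs),
      os = median_iqr(rows$os_months[rows$os_event]),
      landmarks = lms
    )
    if (nrow(obs) >= 3) block$spearman_pfs_os <- spearman_pfs_os(obs)
    per_crit[[cr]] <- block
  }
  report <- list(
    schema_version = 1L,
    n_patients = length(timelines),
    criteria = per_crit
  )
  # optional components are omitted entirely (not serialized as null/empty)
  if (length(criteria) >= 2) {
    report$between_criteria <- list(
      pfs = list(kruskal_wallis = kruskal_wallis(pfs_groups),
                 dunn_bonferroni = dunn_bonferroni(pfs_groups)),
      pps = list(kruskal_wallis = kruskal_wallis(pps_groups),
                 dunn_bonferroni = dunn_bonferroni(pps_groups))
    )
  }
  psp_source <- if ("mRANO" %in% criteria) "mRANO" else criteria[1]
  if (psp_source %in% names(tracks)) {
    rt_end <- vapply(timelines, function(t) t$rt_end_day, integer(1))
    s <- detect_psp_events(tracks[[psp_source]], rt_end)
    report$pseudoprogression <- list(
      criterion = psp_source, count = s$count, rate = s$rate,
      median_weeks = s$median_weeks, n_within_12wk = s$n_within_12wk)
  }
  report
}

#' Render a statistics report as markdown
#'
#' Deterministic human-readable summary of a `stats_report.json` produced by
#' [run_all()]; no statistic is recomputed at render time.
#'
#' @param report Either the parsed report list or a path to the JSON file.
#' @return Character vector of markdown lines, invisibly printed with `cat`.
#' @export
render_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  }
  if (is.null(report$schema_version) || report$schema_version != 1L) {
    ranovol_abort("stats report schema version mismatch (expected 1)",
                  "ranovol_schema_error")
  }
  if (!length(report$criteria)) {
    ranovol_abort("report contains no criteria", "ranovol_schema_error")
  }
  fm <- function(x) {
    if (is.null(x) || !length(x) || is.na(x) || !is.finite(x)) "-" else sprintf("%.2f", x)
  }
  fp <- function(p) {
    if (is.null(p) || !length(p) || is.na(p)) "-"
    else if (p < 0.001) "<.001" else sprintf("%.3f", p)
  }
  L <- c(sprintf("# Volumetric response assessment report (n = %d)", report$n_patients), "")
  L <- c(L, "## Endpoints by criterion", "",
         "| Criterion | n PD | Median PFS (mo) | IQR | Median PPS (mo) | IQR | Spearman rho (PFS, OS) |",
         "|---|---|---|---|---|---|---|")
  for (cr in names(report$criteria)) {
    b <- report$criteria[[cr]]
    rho <- if (is.null(b$spearman_pfs_os) || !length(b$spearman_pfs_os)) "-" else
      sprintf("%.2f (p %s)", b$spearman_pfs_os$rho, fp(b$spearman_pfs_os$p_value))
    L <- c(L, sprintf("| %s | %d | %s | %s | %s | %s | %s |", cr, b$n_progressed,
                      fm(b$pfs$median), fm(b$pfs$iqr), fm(b$pps$median),
                      fm(b$pps$iqr), rho))
  }
  L <- c(L, "", "## Landmark analysis", "",
         "| Landmark | Criterion | SD n | PD n | Median OS SD (mo) | IQR | Median OS PD (mo) | IQR | rank p | HR (95% CI) |",
         "|---|---|---|---|---|---|---|---|---|---|")
  for (cr in names(report$criteria)) {
    for (nm in names(report$criteria[[cr]]$landmarks)) {
      lm <- report$criteria[[cr]]$landmarks[[nm]]
      if (!is.null(lm$error)) {
        L <- c(L, sprintf("| %s mo | %s | - | - | - | - | - | - | - | %s |",
                          sub("^m", "", nm), cr, lm$error))
        next
      }
      hr_cell <- if (isTRUE(lm$monotone)) {
        "unbounded (monotone likelihood)"
      } else {
        sprintf("%s (%s-%s)", fm(lm$hr), fm(lm$ci_low), fm(lm$ci_high))
      }
      L <- c(L, sprintf("| %s mo | %s | %d | %d | %s | %s | %s | %s | %s | %s |",
                        sub("^m", "", nm), cr, lm$n_sd, lm$n_pd,
                        fm(lm$median_os_sd), fm(lm$iqr_sd),
                        fm(lm$median_os_pd), fm(lm$iqr_pd),
                        fp(lm$rank_p), hr_cell))
    }
  }
  if (!is.null(report$between_criteria)) {
    L <- c(L, "", "## Between-criteria tests", "",
           sprintf("- PFS Kruskal-Wallis: H = %.3f, p %s",
                   report$between_criteria$pfs$kruskal_wallis$statistic,
                   fp(report$between_criteria$pfs$kruskal_wallis$p_value)),
           sprintf("- PPS Kruskal-Wallis: H = %.3f, p %s",
                   report$between_criteria$pps$kruskal_wallis$statistic,
                   fp(report$between_criteria$pps$kruskal_wallis$p_value)))
    dn <- report$between_criteria$pfs$dunn_bonferroni
    for (j in seq_len(nrow(dn))) {
      L <- c(L, sprintf("  - PFS Dunn %s: adjusted p %s", dn$pair[j], fp(dn$p_adj[j])))
    }
  }
  if (!is.null(report$pseudoprogression)) {
    ps <- report$pseudoprogression
    L <- c(L, "", "## Pseudoprogression", "",
           sprintf("- %d patients (%.1f%%), median %.1f weeks after radiotherapy; %d within 12 weeks (per %s)",
                   ps$count, 100 * ps$rate,
                   if (is.null(ps$median_weeks) || is.na(ps$median_weeks)) NA_real_ else ps$median_weeks,
                   ps$n_within_12wk, ps$criterion))
  }
  cat(paste(L, collapse = "\n"), "\n")
  invisible(L)
}
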