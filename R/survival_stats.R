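# Comparative statistics: PFS-OS correlation, between-criteria rank tests,
# and fixed-landmark Cox models.
#
# Standard tests are delegated to stats (cor.test, kruskal.test, wilcox.test)
# and survival (coxph); Dunn's post-hoc test is implemented here since no
# dependency provides it.

#' Spearman correlation between PFS and OS
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation (`cor.test(..., method = "spearman", exact = FALSE)`).
#'
#' @param rows Endpoint rows for a single criterion (needs `pfs_months` and
#'   `os_months`; see [cohort_endpoint_table()]).
#' @return List with `criterion`, `rho`, `p_value`, `n`.
#' @export
spearman_pfs_os <- function(rows) {
  x <- rows$pfs_months
  y <- rows$os_months
  if (length(x) < 3L) {
    ranovol_abort("Spearman correlation needs at least 3 observations",
                  "ranovol_domain_error")
  }
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    ranovol_abort("Spearman correlation undefined for a constant vector",
                  "ranovol_undefined_correlation")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(
    criterion = if ("criterion" %in% names(rows)) unique(rows$criterion)[1] else NA_character_,
    rho = unname(ct$estimate), p_value = ct$p.value, n = length(x)
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups, min_groups = 2L)
  if (length(unique(unlist(groups))) == 1L) {
    # fully tied data: the tie correction degenerates to 0/0; H is 0 by
    # convention (no rank variation at all)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = as.integer(unname(kt$parameter)))
}

check_groups <- function(groups, min_groups) {
  if (!is.list(groups) || length(groups) < min_groups) {
    ranovol_abort(sprintf("need at least %d groups", min_groups), "ranovol_domain_error")
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    ranovol_abort("all groups must be non-empty", "ranovol_domain_error")
  }
}

#' Dunn's post-hoc test with Bonferroni adjustment
#'
#' Pairwise z statistics on mean pooled ranks with the usual tie correction
#' `sum(t^3 - t) / (12 (N - 1))`; two-sided normal p-values multiplied by the
#' number of pairs and capped at 1.
#'
#' @param groups List of two or more non-empty numeric vectors (names are
#'   used as group labels).
#' @return `data.frame` with `pair`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_bonferroni <- function(groups) {
  check_groups(groups, min_groups = 2L)
  k <- length(groups)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  r <- rank(x)                       # average ranks for ties
  N <- length(x)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(r, g, mean)
  n_i <- tabulate(g, k)
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(pair = character(n_pairs), z = numeric(n_pairs),
                    p_raw = numeric(n_pairs), p_adj = numeric(n_pairs),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_pairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / n_i[a] + 1 / n_i[b]))
    z <- if (se > 0) (mean_rank[a] - mean_rank[b]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    out$pair[j] <- paste(labels[a], labels[b], sep = " vs ")
    out$z[j] <- z
    out$p_raw[j] <- p
    out$p_adj[j] <- min(1, p * n_pairs)
  }
  out
}

#' Mann-Whitney U test
#'
#' Two-sided, normal approximation with tie and continuity correction
#' (delegates to [stats::wilcox.test()]; the reported statistic is U for the
#' first sample).
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with `U`, `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) {
    ranovol_abort("both groups must be non-empty", "ranovol_domain_error")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Cox proportional-hazards model with one binary covariate
#'
#' Partial-likelihood fit via [survival::coxph()] (Newton-Raphson; Efron tie
#' handling by default, Breslow available for cross-checks).  Monotone
#' likelihoods (complete separation of events by group) are flagged rather
#' than returned as silently divergent estimates.
#'
#' @param times Positive follow-up times.
#' @param events Logical/0-1 event indicators (at least one event).
#' @param group_flags Logical/0-1 group membership (the "exposed" group is 1).
#' @param ties `"efron"` or `"breslow"`.
#' @return List with `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p_value`,
#'   `monotone` (TRUE when the likelihood is monotone and the HR estimate is
#'   infinite or zero).
#' @export
cox_binary <- function(times, events, group_flags, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  events <- as.logical(events)
  flags <- as.numeric(as.logical(group_flags))
  if (length(unique(flags)) < 2L) {
    ranovol_abort("group flag is constant; hazard ratio undefined",
                  "ranovol_degenerate_stratification")
  }
  if (!any(events)) {
    ranovol_abort("no events observed; Cox model undefined", "ranovol_domain_error")
  }
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ flags, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || abs(beta) > 15 || se > 100) monotone <- TRUE
  z <- beta / se
  list(
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.959963984540054 * se),
    ci_high = exp(beta + 1.959963984540054 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    monotone = monotone
  )
}

#' Fixed-landmark survival analysis
#'
#' Patients still under observation beyond the landmark are stratified by
#' progression status at the landmark (PD if progression was dated at or
#' before it; CR/PR/SD pooled as "SD") and compared on residual survival
#' (OS minus the landmark): median/IQR per group over observed deaths, a
#' Mann-Whitney rank test on observed residual survival, and a Cox model with
#' the binary PD flag (Wald 95% CI).  Patients who died at or before the
#' landmark — and, by design, patients censored at or before it, who are not
#' evaluable — are excluded.
#'
#' @param rows Endpoint rows for one criterion (see [cohort_endpoint_table()]).
#' @param landmark_months Landmark in months (the study uses 8 and 12).
#' @param ties Tie handling for the Cox fit.
#' @return List of class `"landmark_result"`: `landmark_months`, `criterion`,
#'   `n_included`, `n_sd`, `n_pd`, `median_os_sd`, `iqr_sd`, `median_os_pd`,
#'   `iqr_pd`, `rank_p`, `hr`, `ci_low`, `ci_high`, `cox_p`, `monotone`.
#' @export
landmark_analysis <- function(rows, landmark_months, ties = "efron") {
  if (landmark_months <= 0) {
    ranovol_abort("landmark_months must be positive", "ranovol_domain_error")
  }
  keep <- rows$os_months > landmark_months
  inc <- rows[keep, , drop = FALSE]
  pd <- inc$pfs_event & inc$pfs_months <= landmark_months + 1e-9
  if (!any(pd) || all(pd)) {
    ranovol_abort(sprintf(
      "landmark %g months: a stratum is empty (n_pd = %d of %d); HR undefined",
      landmark_months, sum(pd), nrow(inc)), "ranovol_degenerate_stratification")
  }
  residual <- inc$os_months - landmark_months
  ev <- inc$os_event

  sd_obs <- residual[!pd & ev]
  pd_obs <- residual[pd & ev]
  msd <- median_iqr(sd_obs)
  mpd <- median_iqr(pd_obs)
  rank_p <- if (length(sd_obs) && length(pd_obs)) {
    mann_whitney(pd_obs, sd_obs)$p_value
  } else NA_real_

  cox <- cox_binary(residual, ev, pd, ties = ties)
  structure(list(
    landmark_months = landmark_months,
    criterion = if ("criterion" %in% names(rows)) unique(rows$criterion)[1] else NA_character_,
    n_included = nrow(inc), n_sd = sum(!pd), n_pd = sum(pd),
    median_os_sd = msd$median, iqr_sd = msd$iqr,
    median_os_pd = mpd$median, iqr_pd = mpd$iqr,
    rank_p = rank_p,
    hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
    cox_p = cox$p_value, monotone = cox$monotone
  ), class = "landmark_result")
}
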