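# Synthetic glioblastoma cohort generator.
#
# The generator produces timelines with the clinical structure the analysis
# assumes: preoperative MRI at day 0, surgery within 1-14 days, post-op scan
# at 24-48 h, radiotherapy starting a median of 38 days after surgery and
# lasting 6 weeks, a post-RT baseline scan 21-35 days after RT end, and
# roughly 3-monthly follow-ups thereafter.
#
# Contrast-enhancing volume is the sum of three simple components:
#   * the post-surgical residual (zero after gross total resection),
#   * a treatment-related enhancement that ramps up over the radiotherapy
#     course and then persists -- this is what makes the post-RT baseline
#     systematically larger than the post-op one, the mechanism behind the
#     divergence of post-op- and post-RT-anchored criteria,
#   * after a latent true-progression day, an exponentially growing tumor
#     component.
# Pseudoprogression is a single-scan transient bump above the 40% threshold
# that resolves at the next scan; patients with pseudoprogression draw their
# true progression after the episode has resolved (mirroring the slightly
# better survival of pseudoprogressors).  These are the simplest mechanisms
# that exercise every branch of the classifiers; they make no claim of
# biological realism.

lnorm_pars <- function(median, iqr) {
  # median/IQR parameterization: q75 - q25 = 2 * median * sinh(qnorm(.75) * sdlog)
  sdlog <- asinh(iqr / (2 * median)) / stats::qnorm(0.75)
  c(meanlog = log(median), sdlog = sdlog)
}

#' Simulation configuration
#'
#' Defaults encode the cohort conditions the generator emulates: 137
#' patients, 87.6% gross total resection, median 38 days (IQR 12) from
#' surgery to radiotherapy, a 42-day radiotherapy course, ~3-monthly
#' follow-up, pseudoprogression in 17.5% of patients at a median of 19.1
#' weeks (IQR 5.7) after radiotherapy, post-progression survival calibrated
#' so cohort median overall survival is about 20.7 months, and about 19/137
#' patients censored for survival.  Intervals, volumes and growth use
#' log-normal distributions (median/IQR parameterized where the emulated
#' quantity is reported that way), post-progression survival an exponential,
#' and event flags Bernoulli draws.
#'
#' @param n_patients Cohort size.
#' @param seed Root seed; drives one independent stream per patient.
#' @param frac_gtr Probability of gross total resection (zero CE residual).
#' @param surgery_to_rt_median_days,surgery_to_rt_iqr_days Surgery-to-RT gap.
#' @param rt_duration_days Radiotherapy duration.
#' @param followup_interval_days,followup_jitter_sd_days Follow-up cadence.
#' @param postop_residual_median_cm3,postop_residual_sdlog CE residual after
#'   partial resection (cm^3).
#' @param treatment_enhancement_median_cm3,treatment_enhancement_sdlog
#'   Persistent treatment-related CE component reached by the end of
#'   radiotherapy (cm^3); 0 disables the component.
#' @param onset_ce_cm3 CE growth-component seed volume at the latent
#'   progression day (cm^3); the seed is never below 45% of the surgical
#'   residual, so regrowth after partial resection is immediately above the
#'   progression threshold.
#' @param growth_doubling_median_days,growth_doubling_sdlog CE doubling time
#'   after progression onset.
#' @param time_to_progression_median_months,time_to_progression_sdlog Latent
#'   true-progression time from diagnosis.
#' @param psp_prob Pseudoprogression probability.
#' @param psp_onset_median_weeks,psp_onset_iqr_weeks PsP onset after RT end.
#' @param psp_extra_frac_range Uniform range of the transient bump's margin
#'   above the 40% progression threshold.
#' @param post_progression_median_months Median of the exponential
#'   post-progression survival (from the latent progression day) for a
#'   patient progressing at the cohort-median time.
#' @param survival_coupling_gamma Aggressiveness coupling: the patient's
#'   post-progression survival median is scaled by
#'   `(t_prog / median t_prog)^gamma` (clamped to 0.4-2.2), so early
#'   progressors also die faster -- the mechanism that makes progression
#'   status prognostic at a landmark.  0 decouples the two.
#' @param frac_lost_followup Probability of OS censoring (lost / alive at
#'   study end).
#' @param reresection_prob,bevacizumab_prob Probabilities of the non-imaging
#'   progression markers among progressing patients.
#' @param ne_background_median_cm3,ne_background_sdlog Stable nonenhancing
#'   T2/FLAIR background volume.
#' @param ne_growth_factor NE doubling rate relative to CE after onset.
#' @param measurement_noise_sdlog Multiplicative log-normal measurement noise
#'   applied to every volume (0 = noiseless).
#' @param new_lesion_frac Fraction of progressions presenting as a distinct
#'   new lesion rather than regrowth of the index lesion.
#' @param max_followup_months Administrative censoring horizon.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_patients = 137L,
                              seed = 1L,
                              frac_gtr = 0.876,
                              surgery_to_rt_median_days = 38,
                              surgery_to_rt_iqr_days = 12,
                              rt_duration_days = 42,
                              followup_interval_days = 91,
                              followup_jitter_sd_days = 7,
                              postop_residual_median_cm3 = 2.5,
                              postop_residual_sdlog = 0.5,
                              treatment_enhancement_median_cm3 = 0.85,
                              treatment_enhancement_sdlog = 0.25,
                              onset_ce_cm3 = 0.15,
                              growth_doubling_median_days = 55,
                              growth_doubling_sdlog = 0.2,
                              time_to_progression_median_months = 6.0,
                              time_to_progression_sdlog = 0.85,
                              psp_prob = 0.175,
                              psp_onset_median_weeks = 19.1,
                              psp_onset_iqr_weeks = 5.7,
                              psp_extra_frac_range = c(0.15, 0.80),
                              post_progression_median_months = 11,
                              survival_coupling_gamma = 1.5,
                              frac_lost_followup = 19 / 137,
                              reresection_prob = 0.06,
                              bevacizumab_prob = 0.06,
                              ne_background_median_cm3 = 12,
                              ne_background_sdlog = 0.4,
                              ne_growth_factor = 0.6,
                              measurement_noise_sdlog = 0.04,
                              new_lesion_frac = 0.25,
                              max_followup_months = 120) {
  cfg <- as.list(environment())
  probs <- c(frac_gtr, psp_prob, frac_lost_followup, reresection_prob,
             bevacizumab_prob, new_lesion_frac)
  if (any(probs < 0 | probs > 1)) {
    ranovol_abort("probabilities must lie in [0, 1]", "ranovol_domain_error")
  }
  scales <- c(surgery_to_rt_median_days, rt_duration_days, followup_interval_days,
              onset_ce_cm3, growth_doubling_median_days,
              time_to_progression_median_months, post_progression_median_months,
              ne_background_median_cm3, max_followup_months)
  if (any(scales <= 0)) {
    ranovol_abort("all scale parameters must be positive", "ranovol_domain_error")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate one patient timeline
#'
#' @param cfg A [simulation_config()].
#' @param patient_id Identifier for the generated patient.
#' @param seed Per-patient stream seed (set by [simulate_cohort()]).
#' @return List with `timeline` (a [patient_timeline()]) and `truth`
#'   (one-row data.frame: latent progression day, PsP flag and scan day,
#'   resection status, death/censoring).
#' @export
simulate_patient <- function(cfg, patient_id, seed) {
  set.seed(seed)
  noise1 <- function() {
    if (cfg$measurement_noise_sdlog > 0) stats::rlnorm(1, 0, cfg$measurement_noise_sdlog) else 1
  }

  surgery_day <- sample(2:10, 1L)
  postop_day <- surgery_day + sample(1:2, 1L)
  p <- lnorm_pars(cfg$surgery_to_rt_median_days, cfg$surgery_to_rt_iqr_days)
  rt_start <- surgery_day + max(14L, round(stats::rlnorm(1, p[1], p[2])))
  rt_end <- rt_start + as.integer(cfg$rt_duration_days)
  postrt_day <- rt_end + sample(21:35, 1L)

  gtr <- stats::runif(1) < cfg$frac_gtr
  v0 <- if (gtr) 0 else stats::rlnorm(1, log(cfg$postop_residual_median_cm3),
                                      cfg$postop_residual_sdlog)
  delta <- if (cfg$treatment_enhancement_median_cm3 > 0) {
    stats::rlnorm(1, log(cfg$treatment_enhancement_median_cm3),
                  cfg$treatment_enhancement_sdlog)
  } else 0
  ne0 <- stats::rlnorm(1, log(cfg$ne_background_median_cm3), cfg$ne_background_sdlog)
  doubling <- stats::rlnorm(1, log(cfg$growth_doubling_median_days),
                            cfg$growth_doubling_sdlog)
  g0 <- max(cfg$onset_ce_cm3, 0.45 * v0)

  # latent true-progression day; at least 4 weeks after RT start
  tp_day <- round(stats::rlnorm(1, log(cfg$time_to_progression_median_months * DAYS_PER_MONTH),
                                cfg$time_to_progression_sdlog))
  tp_day <- max(tp_day, rt_start + 28L)

  # pseudoprogression episode; true progression then follows the resolved
  # episode, never precedes it
  has_psp <- stats::runif(1) < cfg$psp_prob
  psp_day <- NA_integer_
  if (has_psp) {
    pw <- lnorm_pars(cfg$psp_onset_median_weeks, cfg$psp_onset_iqr_weeks)
    psp_day <- rt_end + round(stats::rlnorm(1, pw[1], pw[2]) * 7)
    tp_day <- max(tp_day, psp_day + 2L * as.integer(cfg$followup_interval_days) + 14L)
  }
  psp_extra <- stats::runif(1, cfg$psp_extra_frac_range[1], cfg$psp_extra_frac_range[2])

  tp_ref <- cfg$time_to_progression_median_months * DAYS_PER_MONTH
  couple <- min(2.2, max(0.4, (tp_day / tp_ref)^cfg$survival_coupling_gamma))
  pp_rate <- log(2) / (cfg$post_progression_median_months * DAYS_PER_MONTH * couple)
  death_day <- tp_day + max(1L, round(stats::rexp(1, pp_rate)))
  death_day <- max(death_day, postrt_day + 40L)

  horizon <- round(cfg$max_followup_months * DAYS_PER_MONTH)
  lost <- stats::runif(1) < cfg$frac_lost_followup
  if (lost) {
    censor_day <- max(postrt_day + 30L, round(stats::runif(1, 0.35, 0.90) * death_day))
    censor_day <- min(censor_day, horizon)
  } else if (death_day > horizon) {
    lost <- TRUE
    censor_day <- horizon
  } else {
    censor_day <- NA_integer_
  }
  end_day <- if (lost) censor_day else death_day

  new_lesion_mode <- stats::runif(1) < cfg$new_lesion_frac

  enh <- function(day) {
    # treatment-related enhancement ramps over the RT course, then persists
    delta * min(1, max(0, (day - rt_start) / (rt_end - rt_start)))
  }
  growth <- function(day) {
    if (day < tp_day) 0 else min(150, g0 * 2^((day - tp_day) / doubling))
  }
  ne_base <- function(day) {
    if (day < tp_day) ne0 else
      min(300, ne0 * 2^(cfg$ne_growth_factor * (day - tp_day) / doubling))
  }

  # scan schedule
  days <- c(0L, postop_day, postrt_day)
  nxt <- postrt_day
  repeat {
    gap <- max(30L, round(stats::rnorm(1, cfg$followup_interval_days,
                                       cfg$followup_jitter_sd_days)))
    nxt <- nxt + gap
    if (nxt > end_day) break
    days <- c(days, nxt)
  }
  followups <- days[days > postrt_day]
  psp_scan <- if (has_psp && length(followups)) {
    cand <- followups[followups >= psp_day & followups < tp_day]
    if (length(cand)) cand[1] else NA_integer_
  } else NA_integer_

  scans <- vector("list", length(days))
  new_flag_done <- FALSE
  for (k in seq_along(days)) {
    day <- days[k]
    if (day == 0L) {
      # preoperative MRI: the untouched tumor
      scans[[k]] <- scan_record(day, lesion_table(
        c("L1", "T2a"), c("CE", "NE"),
        c(stats::rlnorm(1, log(25), 0.3), stats::rlnorm(1, log(35), 0.3))))
      next
    }
    base <- v0 + enh(day)
    g <- growth(day)
    ce <- base + g
    if (!is.na(psp_scan) && day == psp_scan) {
      ce <- max(1.2, (1 + 0.4 + psp_extra) * max(ce, 0.8))
    }
    ce <- ce * noise1()
    ne <- ne_base(day) * noise1()
    lesions <- if (new_lesion_mode && day >= tp_day && g > 0) {
      # progression presents as a distinct lesion carrying the growth component
      lesion_table(c("L1", "L2", "T2a"), c("CE", "CE", "NE"),
                   c(max(0, ce - g), g, ne),
                   is_new = c(FALSE, !new_flag_done, FALSE))
    } else {
      lesion_table(c("L1", "T2a"), c("CE", "NE"), c(ce, ne))
    }
    if (new_lesion_mode && day >= tp_day && g > 0) new_flag_done <- TRUE
    scans[[k]] <- scan_record(day, lesions)
  }

  # non-imaging progression markers
  reres_day <- NULL
  bev_day <- NULL
  if (!lost && stats::runif(1) < cfg$reresection_prob) {
    d <- tp_day + sample(10:40, 1L)
    if (d < end_day && any(days > 0 & days < d)) reres_day <- d
  }
  if (!lost && is.null(reres_day) && stats::runif(1) < cfg$bevacizumab_prob) {
    d <- tp_day + sample(60:120, 1L)
    if (d < end_day && any(days > 0 & days < d)) bev_day <- d
  }

  timeline <- patient_timeline(
    patient_id = patient_id,
    surgery_day = surgery_day, rt_start_day = rt_start, rt_end_day = rt_end,
    scans = scans,
    reresection_day = reres_day, bevacizumab_start_day = bev_day,
    death_day = if (lost) NULL else death_day,
    last_followup_day = end_day,
    alive_at_last_followup = lost
  )
  truth <- data.frame(
    patient_id = patient_id, true_progression_day = tp_day,
    psp = !is.na(psp_scan), psp_scan_day = psp_scan,
    gtr = gtr, death_day = if (lost) NA_integer_ else death_day,
    lost_to_followup = lost, stringsAsFactors = FALSE
  )
  list(timeline = timeline, truth = truth)
}

#' Simulate a cohort
#'
#' A single root seed drives one independent, reproducible stream per
#' patient, so cohorts are identical across runs of the same configuration.
#'
#' @param cfg A [simulation_config()].
#' @return List with `timelines` (list of [patient_timeline()]) and
#'   `ground_truth` (one row per patient).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  n <- as.integer(cfg$n_patients)
  if (n == 0L) {
    return(list(timelines = list(),
                ground_truth = data.frame(patient_id = character(0))))
  }
  set.seed(cfg$seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  sims <- lapply(seq_len(n), function(i) {
    simulate_patient(cfg, sprintf("GB-%04d", i), patient_seeds[i])
  })
  list(
    timelines = lapply(sims, `[[`, "timeline"),
    ground_truth = do.call(rbind, lapply(sims, `[[`, "truth"))
  )
}

#' Diagnostic configuration for ground-truth recovery
#'
#' A noiseless, pseudoprogression-free configuration in which the
#' contrast-enhancing volume steps to a measurable onset volume exactly at
#' the latent progression day, so the radiologically recoverable progression
#' date is well defined (the first scan at or after the latent day) and
#' scan-cadence quantization is the only detection error.  Follow-up is long
#' enough that every suspicion has a confirming scan.
#'
#' @param n_patients,seed Passed through to [simulation_config()].
#' @return A [simulation_config()].
#' @export
recovery_config <- function(n_patients = 137L, seed = 1L) {
  simulation_config(
    n_patients = n_patients, seed = seed,
    psp_prob = 0,
    measurement_noise_sdlog = 0,
    treatment_enhancement_median_cm3 = 0,
    onset_ce_cm3 = 1.2,
    growth_doubling_sdlog = 0,
    followup_jitter_sd_days = 0,
    post_progression_median_months = 30,
    frac_lost_followup = 0,
    reresection_prob = 0, bevacizumab_prob = 0,
    new_lesion_frac = 0,
    max_followup_months = 120
  )
}
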