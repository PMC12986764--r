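# Independent brute-force re-derivation of the criteria state machines, plus
# the quantized-trajectory enumeration used to cross-check them.
#
# The oracle works on plain vectors of per-scan totals and recomputes every
# rule from scratch at each scan (reference minima via min() over explicitly
# tracked values); it shares no code with run_criteria().

oracle_track <- function(day, ce, ne, hn, b_ce, b_ne, guard_end, cfg) {
  n <- length(day)
  labels <- rep(NA_character_, n)
  prog <- NA_integer_
  seen_ce <- b_ce            # totals contributing to the reference minimum
  seen_ne <- b_ne
  i <- 1L
  while (i <= n) {
    nad_ce <- min(seen_ce)
    nad_ne <- min(seen_ne)
    cand <- (ce[i] >= (1 + cfg$pd_increase_frac) * nad_ce &&
               ce[i] >= cfg$measurable_min_cm3 && ce[i] > nad_ce) ||
      (ne[i] >= (1 + cfg$ne_pd_increase_frac) * nad_ne &&
         ne[i] >= cfg$measurable_min_cm3 && ne[i] > nad_ne) ||
      hn[i]
    if (!cand) {
      labels[i] <- if (ce[i] <= cfg$cr_volume_cm3) "CR" else
        if (ce[i] <= (1 - cfg$pr_decrease_frac) * b_ce) "PR" else "SD"
      seen_ce <- c(seen_ce, ce[i])
      seen_ne <- c(seen_ne, ne[i])
      i <- i + 1L
      next
    }
    need <- cfg$confirmation_rule == "always_required" || day[i] <= guard_end
    if (!need) {
      labels[i] <- "PD"
      prog <- day[i]
      break
    }
    if (i == n) {
      labels[i] <- "pPD"
      break
    }
    j <- i + 1L
    conf <- (ce[j] >= (1 + cfg$psp_extra_increase_frac) * ce[i] && ce[j] > ce[i]) ||
      (ne[j] >= (1 + cfg$psp_extra_increase_frac) * ne[i] && ne[j] > ne[i]) ||
      hn[j]
    if (conf) {
      labels[i] <- "PD"
      labels[j] <- "PD"
      prog <- day[i]
      break
    }
    labels[i] <- "PsP"
    seen_ce <- ce[j]          # reference minima restart at the resolving scan
    seen_ne <- ne[j]
    labels[j] <- if (ce[j] <= cfg$cr_volume_cm3) "CR" else
      if (ce[j] <= (1 - cfg$pr_decrease_frac) * b_ce) "PR" else "SD"
    i <- j + 1L               # resume after the resolving scan
  }
  list(labels = labels[!is.na(labels)], prog_day = prog)
}

# Trajectory scaffold: surgery day 5, post-op scan day 6 (CE 1.0 / NE 5.0),
# RT days 30-72 (guard ends day 156), enumerated scans at day 100 (post-RT
# baseline) then every 50 days, so days 100 and 150 fall inside the guard.
TRAJ_DAYS <- c(100L, 150L, 200L, 250L, 300L)
TRAJ_POSTOP <- c(ce = 1.0, ne = 5.0)

make_traj_timeline <- function(ce_levels, new_flags, ne_levels = NULL) {
  m <- length(ce_levels)
  if (is.null(ne_levels)) ne_levels <- rep(5.0, m)
  days <- TRAJ_DAYS[seq_len(m)]
  scans <- vector("list", m + 1L)
  scans[[1L]] <- scan_record(6L, lesion_table(
    c("L1", "T2a"), c("CE", "NE"), c(TRAJ_POSTOP["ce"], TRAJ_POSTOP["ne"])))
  for (k in seq_len(m)) {
    ids <- c("L1", "T2a")
    comp <- c("CE", "NE")
    vol <- c(ce_levels[k], ne_levels[k])
    isnew <- c(FALSE, FALSE)
    if (new_flags[k]) {
      ids <- c(ids, paste0("N", k))
      comp <- c(comp, "CE")
      vol <- c(vol, 1.5)
      isnew <- c(isnew, TRUE)
    }
    scans[[k + 1L]] <- scan_record(days[k], lesion_table(ids, comp, vol, is_new = isnew))
  }
  patient_timeline(
    patient_id = "enum", surgery_day = 5L, rt_start_day = 30L, rt_end_day = 72L,
    scans = scans, last_followup_day = days[m], alive_at_last_followup = TRUE
  )
}

# Expected totals derived directly from the construction (independently of
# total_volume): each enumerated scan's CE total is its level plus 1.5 when a
# new lesion is present.
traj_totals <- function(ce_levels, new_flags, ne_levels = NULL) {
  m <- length(ce_levels)
  if (is.null(ne_levels)) ne_levels <- rep(5.0, m)
  list(day = TRAJ_DAYS[seq_len(m)],
       ce = ce_levels + 1.5 * new_flags,
       ne = ne_levels,
       hn = new_flags)
}

# Run implementation and oracle on one trajectory under one criterion and
# compare labels and the dated call.
compare_impl_oracle <- function(ce_levels, new_flags, criterion, ne_levels = NULL) {
  cfg <- criteria_config(criterion)
  t <- make_traj_timeline(ce_levels, new_flags, ne_levels)
  tr <- run_criteria(t, cfg, apply_events = FALSE)
  tot <- traj_totals(ce_levels, new_flags, ne_levels)
  guard_end <- 72L + 84L
  if (cfg$baseline_rule == "postop") {
    o <- oracle_track(tot$day, tot$ce, tot$ne, tot$hn,
                      b_ce = unname(TRAJ_POSTOP["ce"]), b_ne = unname(TRAJ_POSTOP["ne"]),
                      guard_end = guard_end, cfg = cfg)
  } else {
    m <- length(tot$day)
    if (m < 2L) return(TRUE)
    o <- oracle_track(tot$day[-1], tot$ce[-1], tot$ne[-1], tot$hn[-1],
                      b_ce = tot$ce[1], b_ne = tot$ne[1],
                      guard_end = guard_end, cfg = cfg)
  }
  impl_prog <- if (tr$call$progressed) tr$call$progression_day else NA_integer_
  identical(tr$assessments$label, o$labels) &&
    identical(as.integer(impl_prog), as.integer(o$prog_day))
}

CE_LEVELS <- c(0, 0.6, 1.5, 2.4, 4.2)

# Enumerate every trajectory of `m` scans over the CE grid with per-scan
# new-lesion flags; returns a matrix of case indices.
enum_cases <- function(m) {
  g <- expand.grid(c(rep(list(seq_along(CE_LEVELS)), m),
                     rep(list(c(FALSE, TRUE)), m)))
  list(levels = as.matrix(g[, seq_len(m), drop = FALSE]),
       flags = as.matrix(g[, m + seq_len(m), drop = FALSE]))
}

# Partial log-likelihood for a binary covariate, no ties (oracle for Cox fits)
cox_logpl <- function(beta, time, event, flag) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; flag <- flag[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (!event[i]) next
    risk <- time >= time[i]
    ll <- ll + beta * flag[i] - log(sum(exp(beta * flag[risk])))
  }
  ll
}
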