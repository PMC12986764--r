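---
title: "Volumetric response criteria in neuro-oncology: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric response criteria in neuro-oncology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranovol)
```

## The problem

Radiologic response assessment in newly diagnosed glioblastoma decides, scan
by scan, whether a patient's tumor is responding, stable, or progressing.
Three consensus frameworks dominate: RANO, its modification mRANO, and
RANO 2.0.  On volumetric measurements they share the same thresholds and
differ in exactly two switches:

* **Baseline.** RANO anchors assessment at the post-operative MRI (24-48 h
  after surgery); mRANO and RANO 2.0 anchor at the post-radiotherapy MRI
  (21-35 days after the end of radiotherapy).
* **Confirmation.** mRANO always requires the next scan to confirm a
  suspected progression; RANO and RANO 2.0 require confirmation only when
  the suspicion arises within 12 weeks of the end of radiotherapy (the
  "guard"), the window in which treatment-related pseudoprogression (PsP)
  most often mimics true progression.

The choice matters because progression-free survival (PFS) is a common
surrogate endpoint: criteria that misdate progression weaken its relation to
overall survival (OS).  `ranovol` implements the three criteria as per-scan
state machines over longitudinal lesion volumes, derives PFS /
post-progression survival (PPS) / OS per criterion, and provides the
comparative statistics used to judge them: Spearman PFS-OS correlation,
Kruskal-Wallis with Dunn/Bonferroni post-hoc tests, Mann-Whitney U, and
fixed-landmark Cox models.

## The state machine

Each patient contributes dated scans; each scan carries contrast-enhancing
(CE, post-gadolinium T1) and nonenhancing (NE, T2/FLAIR) lesion volumes in
cm^3^.  Per compartment the target volumes are summed to one total (at most
the 5 largest CE target lesions contribute; the cap is applied per scan, by
volume, with identifier tie-breaks, so totals are a pure deterministic
function of the scan).  Walking the scans after the baseline, the machine
maintains the CE and NE *nadirs* — the smallest totals observed from the
baseline onward, updated only by non-progressive scans — and labels every
scan:

* **Progression candidate** when the CE total reaches `(1 + 0.40) x` the CE
  nadir, or the NE total reaches `(1 + 1.00) x` the NE nadir (in either case
  only if the total is itself measurable, i.e. at least 1 cm^3^, and a
  strict increase), or a new measurable (>= 1 cm^3^) lesion appears.
* otherwise **CR** when the CE total is 0, **PR** when it is at or below
  `(1 - 0.65) x` baseline, else **SD**.  Precedence: candidate > CR > PR >
  SD.

A candidate becomes dated progression immediately when the criterion does
not require confirmation at that scan.  Otherwise it is labelled `pPD` and
the next scan decides: a *further* >= 40% increase in either compartment
(strict growth) or additional new measurable lesions confirm, and the
progression is back-dated to the scan of first suspicion; anything else
relabels the suspicious scan `PsP` and the walk resumes.  Every threshold
and window above is a field of `criteria_config()` and can be tuned; the
named presets fix only the baseline/confirmation switches.

### Numerical and edge-case choices

* **Back-dating** is applied uniformly: confirmed progression is dated to
  the first suspicious scan under every criterion.  The alternative (dating
  to the confirming scan) would make confirmation-bearing criteria look
  systematically later for reasons unrelated to the disease course.
* **After a PsP relabel the nadir restarts at the resolving scan.**  The
  transient peak must never become a reference, and keeping the pre-episode
  low would re-trigger a candidate at the very next scan forever.  A
  consequence worth knowing: across a PsP episode the recorded nadir can
  step *up*; monotone non-increase holds on tracks without PsP relabels.
* **A suspicion pending at the end of follow-up is censored**, not promoted:
  without a confirming scan the machine has no evidence of further growth.
* **Sub-measurable new lesions** (< 1 cm^3^ at first appearance) do not
  raise a candidate; they contribute to totals and trigger when growth makes
  the evidence measurable.
* **The confirmation interval** ideally falls 4-8 weeks after suspicion; a
  next scan outside that window is still used (routine follow-up in practice
  is ~3-monthly) and a diagnostic is recorded.
* **The guard is measured from the end of radiotherapy**, 12 weeks of 7
  days.
* **Degenerate references**: with a zero nadir (common after gross total
  resection) the ratio test alone would fire on any nonzero volume, so the
  measurability floor doubles as the effective threshold.  A flat
  zero-volume trajectory never progresses.

### Dating and censoring of the final call

The date of progression is always a scan date.  Patients stable at their
last scan are censored there.  Two non-imaging overrides apply when no
earlier imaging progression exists: a re-resection or the start of
second-line bevacizumab dates progression to the last scan strictly before
the event (bevacizumab can suppress enhancement; re-resected tissue in this
setting is progressive tumor).  Earlier imaging progression is never
overridden.

## Endpoints

PFS runs from the preoperative MRI (day 0, the date of diagnosis) to
progression or censoring; OS from day 0 to death or last follow-up; PPS from
progression to death or last follow-up, defined only for progressed
patients.  All dates are integer day offsets on this study clock; months use
a fixed 30.4375-day month (one twelfth of a Julian year), so endpoint
arithmetic is exact and reproducible.  Summaries are median and IQR with
linear-interpolation quartiles (R type 7) — stated explicitly because small-n
medians differ across quartile conventions.

Between-criteria comparisons (Kruskal-Wallis, Dunn, and the Spearman PFS-OS
correlation) use observed events only: censored PFS values are not mixed
into rank tests as if they were event times.

## Landmark analysis

At a fixed landmark (8 and 12 months by default) patients still under
observation beyond the landmark are stratified by progression status at the
landmark (CR/PR pooled with SD into the non-progressed stratum) and compared
on residual survival, so that surviving long enough to progress late cannot
masquerade as a survival benefit (immortal-time bias).  Patients censored at
or before the landmark are excluded along with those who died — a censored
patient's status at the landmark is unknown, so this is the defensible
reading of a death-only exclusion rule; the choice is confined to one filter
line and documented here.  The group contrast is a Mann-Whitney test on
observed residual survival plus a Cox model with the single binary
progression covariate (Efron tie handling by default — day-granularity data
produce ties — with Breslow available for cross-checks; Wald 95% CI).
Completely separated strata make the partial likelihood monotone with an
infinite hazard-ratio estimate; the fit flags this (`monotone = TRUE`)
instead of returning a silently divergent coefficient.

## The synthetic cohort generator

No patient data ship with the package; `simulate_cohort()` generates
cohorts with the structure the analysis assumes, so every stage is testable
end to end.  The defaults encode the study conditions being emulated: 137
patients, 87.6% gross total resection, a median 38-day (IQR 12)
surgery-to-radiotherapy interval, a 42-day radiotherapy course, a post-RT
baseline 21-35 days after radiotherapy, ~3-monthly follow-up,
pseudoprogression in 17.5% of patients with onset a median of 19.1 weeks
(IQR 5.7) after radiotherapy, about 14% OS censoring, and post-progression
survival calibrated so the cohort median OS is about 20.7 months.

The CE volume is the sum of three components:

1. the **surgical residual** (zero after gross total resection, log-normal
   around 2.5 cm^3^ otherwise);
2. a **treatment-related enhancement** (log-normal, median 0.85 cm^3^)
   ramping up over the radiotherapy course and persisting.  This is the
   mechanism that separates post-op- from post-RT-anchored criteria: it
   raises the post-RT baseline and nadir above the post-op ones, so the same
   regrowth crosses the post-op-referenced threshold first;
3. after a latent **true-progression day** (log-normal, median 6 months,
   sdlog 0.85 — the spread reproduces the reported PFS dispersion and the
   ~40/60 SD/PD split at the 12-month landmark), an exponentially growing
   tumor component (doubling time log-normal around 55 days).

Pseudoprogression is a single-scan transient bump at least 40% above the
running reference that resolves at the next scan; PsP patients draw their
true progression after the episode resolves, matching the better survival of
pseudoprogressors and making the episode classifiable at 3-monthly cadence.
Post-progression survival is exponential with the patient's median scaled by
`(t_prog / median t_prog)^1.5` (clamped to 0.4-2.2): an aggressiveness
coupling without which progression status would carry no prognostic signal
at a landmark (hazard ratios near 1), contrary to any real glioblastoma
cohort.  A single root seed drives one counter-derived stream per patient,
so cohorts are reproducible and patients independent.

`recovery_config()` is a diagnostic configuration — noiseless, PsP-free,
enhancement-free, with a measurable step at the latent progression day and
long follow-up — under which the radiologically recoverable progression date
is exactly the first scan at or after the latent day, so classifier dating
can be tested with scan-cadence quantization as the only error.

### What the generator does not emulate

Passing tests on this cohort show the *pipeline* is faithful to its rules,
not that the rules fit any particular clinic's data.  Known departures:
volumes are generated, not segmented from images, so there is no reader
variability beyond a 4% log-normal measurement noise; no scan exists between
the post-RT baseline and the first ~3-monthly follow-up, so
pseudoprogression inside the 12-week guard is never observed and measured
PsP timing is quantized to follow-up scans (a median near 28 weeks for a
19.1-week onset median — the delayed-detection pattern seen with real-world
cadences); the OS IQR comes out wider than the emulated cohort's; and
neurological status, corticosteroid dosing and molecular covariates are out
of scope throughout.

## Problem sizes used by the test suite

The oracle-equivalence check enumerates all 3- and 4-scan trajectories over
a 5-level volume grid with per-scan new-lesion flags (11,000 trajectories,
three criteria each) against an independent brute-force re-derivation; the
criterion-ordering and guard properties run over the same enumeration plus
1,000 simulated patients; parameter recovery and the cohort-level checks use
the default 137-patient cohort and a 137-patient recovery configuration.
These sizes were chosen to cover every rule interaction exhaustively at the
grid scale while keeping a full run of the suite in a few minutes.

## Limitations

Two-dimensional (product-of-diameters) assessment is deliberately absent;
the package is volumetric only.  The PR/CR thresholds (65% decrease /
disappearance) follow the volumetric adaptation of the framework and remain
configurable because published variants differ.  Whether confirmed
progression should be dated to the suspicion or the confirming scan is
genuinely ambiguous in the field; the package back-dates uniformly and
exposes the confirmation machinery so the alternative can be studied.  The
landmark exclusion of censored-before-landmark patients and the
observed-events convention for rank tests are documented choices, not
universal practice.
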