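# ranovol

Volumetric RANO, mRANO and RANO 2.0 response assessment for newly diagnosed
glioblastoma, with endpoint derivation and landmark survival analysis.

## The problem

Deciding when a glioblastoma has progressed on MRI is harder than it sounds:
surgery empties the enhancing compartment, radiotherapy produces transient
enhancement that mimics tumor (pseudoprogression, PsP), and the answer
changes with the reference scan.  Three consensus criteria handle this
differently.  On volumetric measurements they share the thresholds

* progressive disease (PD): CE total ≥ (1 + 0.40) × nadir, or NE total
  ≥ (1 + 1.00) × NE nadir, or a new measurable (≥ 1 cm³) lesion,
* partial response (PR): CE total ≤ (1 − 0.65) × baseline; complete
  response (CR): CE total = 0; measurability floor 1 cm³,

and differ in two switches: the baseline scan (post-operative for RANO,
post-radiotherapy for mRANO / RANO 2.0) and when a confirmatory scan is
required before declaring PD (always for mRANO; only within 12 weeks of
radiotherapy for RANO and RANO 2.0).  `ranovol` implements the three
criteria as deterministic per-scan state machines, derives per-criterion
PFS / PPS / OS under explicit dating and censoring rules, and runs the
comparative statistics used to judge criteria against each other: Spearman
PFS–OS correlation, Kruskal–Wallis + Dunn/Bonferroni, Mann–Whitney U, and
8/12-month landmark Cox models (hazard of death for progressed vs
non-progressed patients).  A synthetic cohort generator emulates the
clinical structure of a 137-patient standard-of-care cohort so the whole
pipeline runs without any patient data.

The package is aimed at neuro-oncology imaging researchers comparing
response criteria, and at statisticians who need a reproducible, fully
specified reference implementation of the volumetric rules.

## Worked example

The representative patient (`representative_timeline()`) has a gross total
resection, a new measurable lesion at the second follow-up (day 206, more
than 12 weeks after radiotherapy), shrinkage at the third, stability at the
fourth, and a second new lesion at the fifth, confirmed by growth at the
sixth:

```r
library(ranovol)
t <- representative_timeline()
run_criteria(t, criteria_config("mRANO"))$assessments
#>   scan_day label ce_total reference_nadir      trigger
#> 1      206   PsP      1.6             0.4    retro_psp
#> 2      297    SD      0.8             0.8         none
#> 3      388    SD      0.8             0.8         none
#> 4      479    PD      2.3             0.8  ce_increase
#> 5      570    PD      4.2             0.8 confirmation
```

mRANO treats day 206 as preliminary PD, relabels it PsP when day 297 shows
shrinkage, and dates progression to day 479 (back-dated from the confirming
scan).  RANO and RANO 2.0 both call PD directly at day 206 — RANO because the
new lesion breaks the post-operative reference, RANO 2.0 because no
confirmation is needed beyond the 12-week guard:

```r
run_criteria(t, criteria_config("RANO"))$call$progression_day   #> 206
run_criteria(t, criteria_config("RANO2"))$call$progression_day  #> 206
compute_endpoints(t, run_criteria(t, criteria_config("mRANO"))$call)[
  , c("pfs_months", "os_months")]
#>   pfs_months os_months
#> 1      15.74     21.03
```

So one identical course yields PFS 6.8 months under RANO/RANO 2.0 and 15.7
months under mRANO — the divergence the comparative statistics quantify.

End to end on a synthetic cohort:

```r
sim <- simulate_cohort(simulation_config())        # n = 137, seed 1
write_cohort(sim$timelines, "cohort_meta.csv", "cohort_scans.csv")
run_all("cohort_meta.csv", "cohort_scans.csv", "out")
render_report("out/stats_report.json")
```

`out/` then holds `assessments.csv` (per-scan labels), `calls.csv` (dated
progression calls), `endpoints.csv` (per-patient PFS/PPS/OS per criterion),
`stats_report.json` (all statistics) and `manifest.json` (row counts and
checksums).  A thin command-line wrapper with `simulate`, `run-all` and
`report` subcommands lives at `inst/cli/ranovol.R`.

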