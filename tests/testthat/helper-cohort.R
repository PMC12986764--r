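# Shared, lazily-built cohort fixtures.  The default 137-patient cohort and
# its three criterion runs are expensive enough to build once per session.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

default_sim <- function() {
  cached("sim137", function() simulate_cohort(simulation_config()))
}

default_tracks <- function() {
  cached("tracks137", function() {
    tl <- default_sim()$timelines
    lapply(c(RANO = "RANO", mRANO = "mRANO", RANO2 = "RANO2"), function(cr) {
      cfg <- criteria_config(cr)
      lapply(tl, function(t) suppressWarnings(run_criteria(t, cfg)))
    })
  })
}

default_endpoints <- function() {
  cached("endpoints137", function() {
    calls <- lapply(default_tracks(), function(x) lapply(x, `[[`, "call"))
    cohort_endpoint_table(default_sim()$timelines, calls)
  })
}

# A tiny, fast cohort for structural tests.
small_sim <- function() {
  cached("sim12", function() simulate_cohort(simulation_config(n_patients = 12L, seed = 3L)))
}
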