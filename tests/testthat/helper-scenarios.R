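# shared fixtures: built in code, no stored data

rel_dev <- function(got, want) {
  ifelse(want == 0, abs(got), abs(got - want) / abs(want))
}

# bundled scenarios are deterministic; build once per test run
bundled <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_bundled_scenarios()
    cache
  }
})

# a small hand-specified scenario with simple round numbers
toy_scenario <- function(efficacy = 0.5, coverage = 0.2, unit_cost = 100,
                         severity = 1) {
  cea_scenario(
    "toy",
    condition_params("toy condition",
                     baseline_prevalence = 0.02, rr_pandemic = 1.5,
                     short_term = episode_impact(1000, 0.5),
                     long_term = episode_impact(2000, 1.0),
                     severity_multiplier = severity),
    intervention_params("toy intervention", coverage = coverage,
                        efficacy = efficacy, cost_per_participant = unit_cost))
}
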