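# Shared fixtures, built in code. The anchored synthetic base case is cached
# once per test run.

base_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- base_case_parameters()
    cache
  }
})

# Parameter set in which no treatment does anything (all relative risks 1).
null_effect_params <- function(params = base_params()) {
  for (g in twincua:::PRETERM_LEVELS) {
    params <- override_parameter(params, paste0("rr_progesterone.", g), 1)
    params <- override_parameter(params, paste0("rr_cerclage.", g), 1)
  }
  params
}

# Zero out all screening- and treatment-specific costs.
zero_screening_costs <- function(params) {
  for (nm in c("costs.ultrasound_per_scan", "costs.progesterone_per_week",
               "costs.cerclage_procedure"))
    params <- override_parameter(params, nm, 0)
  params
}

# All numeric leaves of a values list, flattened with stable names.
flatten_values <- function(values) {
  u <- unlist(values)
  u[vapply(u, is.numeric, logical(1L))]
}
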