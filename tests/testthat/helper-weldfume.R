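# shared fixtures built in code

wf_er_table <- function() {
  read_emission_table(weldfume_example("chamber_emission_rates.csv"))
}

wf_predicted <- function() {
  read_exposure_stats(weldfume_example("predicted_longterm_stats.csv"))
}

wf_field <- function() {
  read_exposure_stats(weldfume_example("field_exposure_stats.csv"))
}

wf_measured <- function() {
  read_concentration_table(
    weldfume_example("simulation_measured_concentrations.csv"))
}

# random positive two-zone parameter set
wf_random_params <- function() {
  two_zone_params(Q = runif(1, 1, 100), beta = runif(1, 1, 20),
                  V_N = runif(1, 0.1, 2), V_F = runif(1, 10, 1000))
}
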