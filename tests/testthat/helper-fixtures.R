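# Shared fixtures, built once per test run.
fixture_env <- new.env()

get_mini_net <- function() {
  if (is.null(fixture_env$mini))
    fixture_env$mini <- make_fixture("mini", seed = 42L)
  fixture_env$mini
}

get_unit_net <- function() {
  if (is.null(fixture_env$unit))
    fixture_env$unit <- make_fixture("unit", seed = 42L)
  fixture_env$unit
}

# a cached short background simulation on the mini network
get_mini_sim <- function() {
  if (is.null(fixture_env$mini_sim))
    fixture_env$mini_sim <- run_simulation(get_mini_net(),
                                           grating_spec(contrast = 0),
                                           duration_s = 1.5, seed = 11,
                                           record_from_s = 0.5)
  fixture_env$mini_sim
}
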