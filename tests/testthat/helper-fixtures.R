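# Small constructors shared across tests.

make_person <- function(lambda_work = 16, lambda_night = 42, rho_c = 0.52,
                        anticipation = 0, person_id = 0L) {
  data.frame(person_id = person_id, lambda_work = lambda_work,
             lambda_night = lambda_night, anticipation = anticipation,
             rho_c = rho_c)
}

# A population_result shell for epi functions that only need outcomes.
make_result <- function(onset_day, exposure = seq_along(onset_day),
                        days = 200L) {
  n <- length(onset_day)
  structure(list(people = data.frame(
    person_id = seq_len(n) - 1L,
    lambda_work = exposure, lambda_night = exposure + 8,
    rho_c = rep(0.52, n), mean_work_impulses = exposure,
    final_load = rep(0, n), onset_day = onset_day),
    config = standard_week(), params = dynamics_params(),
    days = days, seed = 0L),
    class = "population_result")
}

table3_scenario <- function(which = "II") {
  scenario_spec(which, work_rate_dist = uniform_spec(1, 50))
}
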