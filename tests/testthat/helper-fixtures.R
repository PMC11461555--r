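# shared fixtures: parameter sets and a cached short-horizon solved pipeline

wm_profile <- demographic_profile("White", "Male")

short_params <- function(end_age = 40, profile = wm_profile) {
  p <- default_parameters(profile)
  p$end_age <- end_age
  p
}

# all hazards and decrements zero; optionally zero accruals too, so a
# quarterly step changes nothing but age
zero_hazard_params <- function(end_age = 40, zero_rewards = TRUE) {
  p <- short_params(end_age)
  p$mortality[] <- 0
  p$proteinuria_onset[] <- 0
  p$esrd_entry <- 0
  p$egfr_decrement[] <- 0
  if (zero_rewards) {
    p$state_costs[] <- 0
    p$screening_cost <- 0
    p$qaly_weights[] <- 0
  }
  p
}

# a one-nonzero-hazard toy world: proteinuria onset only, so the analytic
# quarterly kernel is known in closed form
onset_only_params <- function(annual_onset = 0.08, end_age = 31) {
  p <- zero_hazard_params(end_age = end_age, zero_rewards = FALSE)
  p$proteinuria_onset[] <- annual_onset
  p
}

# short-horizon solved pipeline, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

get_short_solution <- function() {
  if (is.null(.fixture_cache$sol)) {
    p <- short_params(end_age = 40)
    tens <- estimate_transition_tensor(p, n = 8000, seed = 2)
    term <- estimate_terminal_rewards(p, tensor = tens, seed = 2)
    pom <- assemble_pomdp(p, tens, term)
    tree <- solve_pomdp(pom)
    .fixture_cache$sol <- list(params = p, tensor = tens, terminal = term,
                               pomdp = pom, tree = tree)
  }
  .fixture_cache$sol
}
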