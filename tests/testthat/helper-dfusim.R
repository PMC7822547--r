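# Shared fixtures for the test suite. Everything is built in code.

base_params <- function() builtin_basecase()

# small deterministic life table for fast tests
test_lt <- function() make_life_table(max_age = 110)

# parameter set with all stochastic side-channels silenced:
# no background mortality, no state deaths, no hospitalisation
quiet_params <- function(p = base_params()) {
  p$transitions$p_death_uninf <- 0
  p$transitions$p_death_inf <- 0
  p$transitions$p_death_closed <- 0
  p$transitions$p_death_amp <- 0
  p$options$state_death_includes_background <- TRUE
  p$p_hospital$uninfected <- 0
  p$p_hospital$infected <- 0
  p
}

# minimal cohort-result stand-in for economics tests
fake_cohort <- function(ly, qaly, cost, n = 1000, amputations = 0,
                        strategy = "x", horizon = 480) {
  list(n = n, horizon = horizon, strategy = strategy,
       mean = c(ly_wo_dfu = ly, qaly = qaly, cost = cost, months_alive = NA),
       amputation_count = amputations,
       amputation_prob = amputations / n)
}
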