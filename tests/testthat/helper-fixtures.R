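# Fixtures are built in code: constant-rate tables, toy cohorts, and small
# simulated datasets under fixed seeds.

const_table <- function(rate = 0.02, ages = 0:110, years = 2000:2035,
                        sexes = c("male", "female")) {
  rate_table(array(rate, c(length(ages), length(years), length(sexes))),
             ages, years, sexes)
}

zero_table <- function() const_table(rate = 1e-14)

toy_cohort <- function() {
  as_cohort(data.frame(id = 1:3, time = c(1, 2, 3), dead = c(1, 1, 0),
                       age_dx = 50, sex = "male", year_dx = 2009))
}

# random small cohort with events, censoring and varied demographics
random_cohort <- function(n = 20, horizon = 10) {
  age <- runif(n, 40, 90)
  t_ev <- rweibull(n, 0.9, 6)
  t_cs <- runif(n, 0.5, horizon)
  tt <- pmin(t_ev, t_cs)
  as_cohort(data.frame(id = seq_len(n), time = tt,
                       dead = as.integer(t_ev <= t_cs),
                       age_dx = age,
                       sex = sample(c("male", "female"), n, replace = TRUE),
                       year_dx = 2009 + runif(n)))
}

sim_fixture <- function(scenario = 1, n = 300, seed = 42,
                        table = synthetic_ratetable()) {
  set.seed(seed)
  simulate_cohort(sim_scenario(scenario, n = n), table)
}
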