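test_that("transition matrices are row-stochastic with correct structure", {
  m <- two_state_model(p_die = 0.1, horizon = 3)
  P <- transition_matrix_at(m, 0)
  expect_equal(unname(P), rbind(c(0.9, 0.1), c(0, 1)))
  # absorbing row is a unit vector at every cycle
  for (cyc in c(0, 1, 5, 40)) {
    P <- transition_matrix_at(m, cyc)
    expect_equal(unname(P["dead", ]), c(0, 1))
    expect_equal(rowSums(P), c(alive = 1, dead = 1))
  }
})

test_that("carry-forward returns the last specified year's probabilities", {
  # post-stroke mortality schedule: years 1-5, later years reuse year 5
  smort <- c(0.207, 0.067, 0.058, 0.059, 0.059)
  m <- cohort_model(
    states = list(health_state("post_stroke", 0.6),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = "post_stroke", to = "dead", cycle = 0:4, prob = smort),
      carry_forward_cycle = 4),
    initial_distribution = c(1, 0),
    horizon_cycles = 10
  )
  expect_equal(transition_matrix_at(m, 7)["post_stroke", "dead"], 0.059)
  expect_equal(transition_matrix_at(m, 1)["post_stroke", "dead"], 0.067)
  expect_identical(transition_matrix_at(m, 4), transition_matrix_at(m, 100))
})

test_that("residual probability goes to the declared residual target", {
  # two-year tunnel: survivors of y1 advance to y2 rather than staying
  m <- cohort_model(
    states = list(health_state("y1", 0.8, residual_to = "y2"),
                  health_state("y2", 0.9),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = c("y1", "y2"), to = "dead", cycle = 0, prob = c(0.2, 0.1)),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0, 0),
    horizon_cycles = 3
  )
  P <- transition_matrix_at(m, 0)
  expect_equal(P["y1", "y2"], 0.8)
  expect_equal(P["y1", "y1"], 0)
  expect_equal(P["y2", "y2"], 0.9)
})

test_that("model validation rejects malformed structures by name", {
  mk <- function(prob, init = c(1, 0), ...) {
    cohort_model(
      states = list(health_state("alive", 1),
                    health_state("dead", 0, 0, absorbing = TRUE)),
      schedule = transition_schedule(
        data.frame(from = "alive", to = "dead", cycle = 0, prob = prob),
        carry_forward_cycle = 0),
      initial_distribution = init, horizon_cycles = 2, ...)
  }
  expect_error(mk(-0.1), "out of \\[0, 1\\]")
  expect_error(mk(1.4), "out of \\[0, 1\\]")
  expect_error(mk(0.1, init = c(0.7, 0.2)), "sum to 1")
  # competing exits summing over 1 name the state and cycle
  m3 <- cohort_model(
    states = list(health_state("a", 1), health_state("b", 1),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = "a", to = c("b", "dead"), cycle = 0, prob = c(0.7, 0.6)),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0, 0), horizon_cycles = 2, validate = FALSE)
  expect_error(validate_cohort_model(m3), "'a'.*cycle 0")
  # no absorbing state
  expect_error(cohort_model(
    states = list(health_state("a", 1), health_state("b", 0)),
    schedule = transition_schedule(
      data.frame(from = "a", to = "b", cycle = 0, prob = 0.5),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0), horizon_cycles = 1),
    "exactly one absorbing")
  # death state present but undeclared as a destination anywhere
  expect_error(cohort_model(
    states = list(health_state("a", 1), health_state("b", 0.5),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = "a", to = "b", cycle = 0, prob = 0.5),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0, 0), horizon_cycles = 1),
    "unreachable")
})

test_that("discount factors follow the first-year-undiscounted convention", {
  expect_identical(discount_factor(0, c(0, 3, 9)), c(1, 1, 1))
  expect_identical(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 9), 1.03^-9)
  expect_error(discount_factor(-0.01, 1), "non-negative")
})

test_that("run_cohort matches the hand path-enumeration value", {
  # {alive, dead}, p(die) = 0.1, horizon 2, rate 0:
  # cycle 0 all alive (QALY 1), cycle 1 90% alive (QALY 0.9)
  tr <- run_cohort(two_state_model(p_die = 0.1, horizon = 2, rate = 0))
  expect_equal(tr$cum_qaly, 1.9)
  expect_equal(tr$deaths_by_cycle, c(0.1, 0.09))
})

test_that("zero-rate totals equal undiscounted sums of the occupancy trace", {
  m <- random_small_model(31, n_states = 4, n_cycles = 5)
  tr <- run_cohort(m, discount_rate = 0)
  u <- vapply(m$states, function(s) s$utility, numeric(1))
  occ_start <- tr$occupancy[seq_len(m$horizon_cycles), , drop = FALSE]
  expect_equal(tr$cum_qaly, sum(occ_start %*% u))
})

test_that("horizon zero yields the initial occupancy and no rewards", {
  m <- two_state_model(p_die = 0.1, horizon = 0)
  tr <- run_cohort(m)
  expect_equal(nrow(tr$occupancy), 1L)
  expect_equal(tr$cum_qaly, 0)
  expect_equal(tr$cum_cost, 0)
})

test_that("cohort propagation agrees with exhaustive path enumeration", {
  for (seed in c(11, 12, 13)) {
    m <- random_small_model(seed, n_states = 4, n_cycles = 4)
    tr <- run_cohort(m)
    oracle <- enumerate_expected_rewards(m)
    expect_equal(tr$cum_qaly, oracle$cum_qaly, tolerance = 1e-12)
    expect_equal(tr$cum_cost, oracle$cum_cost, tolerance = 1e-12)
  }
})

test_that("one-time transition costs charge the entering mass in its cycle", {
  m <- cohort_model(
    states = list(health_state("alive", 1),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = "alive", to = "dead", cycle = 0, prob = 0.2),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0),
    horizon_cycles = 2, discount_rate = 0,
    transition_costs = data.frame(from = "alive", to = "dead",
                                  cycle = 0:1, cost = c(100, 50)))
  tr <- run_cohort(m)
  # cycle 0: 0.2 dies (cost 100); cycle 1: 0.8 * 0.2 dies (cost 50)
  expect_equal(tr$cum_cost, 0.2 * 100 + 0.16 * 50)
  # the same model agrees with the enumeration oracle
  oracle <- enumerate_expected_rewards(m)
  expect_equal(tr$cum_cost, oracle$cum_cost)
})

test_that("overall mortality is deaths per person-year at risk", {
  # immortal cohort
  tr0 <- run_cohort(two_state_model(p_die = 0, horizon = 5))
  expect_equal(overall_mortality_rate(tr0), 0)
  # single cycle: rate equals the death probability
  tr1 <- run_cohort(two_state_model(p_die = 0.1, horizon = 1))
  expect_equal(overall_mortality_rate(tr1), 0.1)
  # 3-state toy over 5 cycles vs an independent spreadsheet-style tally
  m <- cohort_model(
    states = list(health_state("well", 1), health_state("ill", 0.5),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = c("well", "well", "ill"), to = c("ill", "dead", "dead"),
                 cycle = 0, prob = c(0.3, 0.05, 0.2)),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0, 0), horizon_cycles = 5)
  tr <- run_cohort(m)
  occ <- c(well = 1, ill = 0, dead = 0)
  P <- rbind(c(0.65, 0.3, 0.05), c(0, 0.8, 0.2), c(0, 0, 1))
  person_years <- 0; deaths <- 0
  for (t in 1:5) {
    person_years <- person_years + occ["well"] + occ["ill"]
    nxt <- as.numeric(occ %*% P)
    deaths <- deaths + nxt[3] - occ["dead"]
    occ <- stats::setNames(nxt, names(occ))
  }
  expect_equal(overall_mortality_rate(tr), unname(deaths / person_years))
})
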