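# Independent oracles and small fixture builders shared by the tests.

# Exhaustive path-enumeration oracle: expected discounted cost and QALY of a
# cohort model computed by enumerating every state path, weighting it by its
# exact probability, and accruing start-of-cycle rewards along it. Written
# directly from the reward definition, independently of the engine's
# matrix-propagation code path.
enumerate_expected_rewards <- function(model, discount_rate = model$discount_rate) {
  sn <- model$state_names
  n <- length(sn)
  H <- model$horizon_cycles
  u <- vapply(model$states, function(s) s$utility, numeric(1))
  cst <- vapply(model$states, function(s) s$annual_cost, numeric(1))
  P <- lapply(0:(max(H - 1, 0)), function(t) transition_matrix_at(model, t))
  df <- (1 + discount_rate)^(-(0:max(H - 1, 0)))
  tc <- model$transition_costs
  # all state paths s_0, ..., s_H
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), H + 1)))
  tot_q <- 0
  tot_c <- 0
  for (k in seq_len(nrow(paths))) {
    path <- paths[k, ]
    w <- model$initial_distribution[path[1]]
    if (w == 0) next
    q <- 0; cc <- 0
    for (t in seq_len(H)) {      # cycle t-1, 0-based
      step_p <- P[[t]][path[t], path[t + 1]]
      q <- q + u[path[t]] * df[t]
      cc <- cc + cst[path[t]] * df[t]
      if (!is.null(tc) && nrow(tc)) {
        hit <- tc$from == sn[path[t]] & tc$to == sn[path[t + 1]] & tc$cycle == t - 1
        if (any(hit)) cc <- cc + sum(tc$cost[hit]) * df[t]
      }
      w <- w * step_p
      if (w == 0) break
    }
    tot_q <- tot_q + w * q
    tot_c <- tot_c + w * cc
  }
  list(cum_qaly = tot_q, cum_cost = tot_c)
}

# Exact central moments of a beta(a, b) distribution from raw moments
# E[X^k] = prod_{r<k} (a + r) / (a + b + r); used to get the exact sampling
# standard error of the sample SD without a normality assumption.
beta_central_moments <- function(a, b) {
  raw <- vapply(1:4, function(k) prod((a + 0:(k - 1)) / (a + b + 0:(k - 1))),
                numeric(1))
  m <- raw[1]
  mu2 <- raw[2] - m^2
  mu3 <- raw[3] - 3 * m * raw[2] + 2 * m^3
  mu4 <- raw[4] - 4 * m * raw[3] + 6 * m^2 * raw[2] - 3 * m^4
  list(mean = m, var = mu2, mu3 = mu3, mu4 = mu4)
}

# Two-state alive/dead fixture with constant death probability.
two_state_model <- function(p_die = 0.1, horizon = 2, rate = 0,
                            utility = 1, cost = 0) {
  cohort_model(
    states = list(health_state("alive", utility, cost),
                  health_state("dead", 0, 0, absorbing = TRUE)),
    schedule = transition_schedule(
      data.frame(from = "alive", to = "dead", cycle = 0, prob = p_die),
      carry_forward_cycle = 0),
    initial_distribution = c(1, 0),
    horizon_cycles = horizon,
    discount_rate = rate
  )
}

# Three-state toy whose value of the additional state is exactly linear in
# the sampled well->sick probability: horizon 2, rewards accrue at cycles 0
# (all well) and 1 (occupancy linear in p).
linear_toy_builders <- function(sick_utility = 0.5, sick_cost = 1e6) {
  builder_A <- function(tp) {
    cohort_model(
      states = list(health_state("well", 1), health_state("sick", sick_utility, sick_cost),
                    health_state("dead", 0, 0, absorbing = TRUE)),
      schedule = transition_schedule(
        data.frame(from = c("well", "sick"), to = "dead", cycle = 0, prob = 0),
        carry_forward_cycle = 0),
      initial_distribution = c(1, 0, 0),
      horizon_cycles = 2, discount_rate = 0
    )
  }
  builder_B <- function(tp) {
    cohort_model(
      states = list(health_state("well", 1), health_state("sick", sick_utility, sick_cost),
                    health_state("dead", 0, 0, absorbing = TRUE)),
      schedule = transition_schedule(
        data.frame(from = c("well", "sick"), to = c("sick", "dead"), cycle = 0,
                   prob = c(unname(tp[["p_sick"]]), 0)),
        carry_forward_cycle = 0),
      initial_distribution = c(1, 0, 0),
      horizon_cycles = 2, discount_rate = 0
    )
  }
  list(A = builder_A, B = builder_B)
}
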