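#' Define a health state
#'
#' A health state of a discrete-time Markov cohort model. Rewards (utility and
#' annual cost) are attached per state; time-since-event dependence is
#' expressed with tunnel states (one sub-state per post-event year), so a
#' scalar utility and cost per state suffice.
#'
#' @param name State identifier (unique within a model).
#' @param utility Preference weight in `[0, 1]` accrued per cycle spent in the
#'   state (1 = full health, 0 = death).
#' @param annual_cost Cost in yen accrued per cycle spent in the state.
#'   One-time event costs (e.g. acute-phase hospitalization) are attached to
#'   the year-1 tunnel state of the event, which every entrant occupies for
#'   exactly one cycle.
#' @param absorbing Logical; an absorbing state has self-transition
#'   probability 1 at every cycle. The death state is absorbing with utility 0
#'   and cost 0.
#' @param residual_to State name receiving the residual probability
#'   `1 - sum(specified exits)`. Defaults to the state itself ("stay");
#'   tunnel states point it at the next tunnel year so survivors advance.
#' @return An object of class `health_state`.
#' @export
health_state <- function(name, utility, annual_cost = 0, absorbing = FALSE,
                         residual_to = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(utility) || length(utility) != 1L || utility < 0 || utility > 1)
    stop("utility of state '", name, "' must be a single value in [0, 1]")
  if (!is.numeric(annual_cost) || length(annual_cost) != 1L)
    stop("annual_cost of state '", name, "' must be a single number")
  if (absorbing && (utility != 0 || annual_cost != 0))
    stop("absorbing (death) state '", name, "' must have utility 0 and cost 0")
  structure(
    list(name = name, utility = utility, annual_cost = annual_cost,
         absorbing = absorbing, residual_to = residual_to),
    class = "health_state"
  )
}

#' Define a transition schedule
#'
#' Time-varying transition probabilities as sparse entries keyed by
#' (from, to, cycle). Cycles are 0-based internally; reported tables label
#' years `1..horizon`. Probabilities for cycles beyond `carry_forward_cycle`
#' repeat the value at `carry_forward_cycle` (the carry-forward rule: the last
#' specified annual rate is used for all subsequent years).
#'
#' Only exits are specified. The residual probability of each row is computed
#' as `1 - sum(specified exits)` and assigned to the state's `residual_to`
#' target; it is never read from configuration, which guarantees
#' row-stochasticity of every transition matrix.
#'
#' @param entries `data.frame` with columns `from`, `to` (state names),
#'   `cycle` (0-based integer) and `prob`.
#' @param carry_forward_cycle Cycle index after which the last specified
#'   values repeat.
#' @return An object of class `transition_schedule`.
#' @export
transition_schedule <- function(entries, carry_forward_cycle) {
  stopifnot(is.data.frame(entries),
            all(c("from", "to", "cycle", "prob") %in% names(entries)))
  if (!is.numeric(carry_forward_cycle) || carry_forward_cycle < 0)
    stop("carry_forward_cycle must be a non-negative cycle index")
  entries$from <- as.character(entries$from)
  entries$to <- as.character(entries$to)
  entries$cycle <- as.integer(entries$cycle)
  structure(
    list(entries = entries,
         carry_forward_cycle = as.integer(carry_forward_cycle)),
    class = "transition_schedule"
  )
}

#' Assemble a Markov cohort model
#'
#' @param states List of [health_state()] objects (order fixes the state
#'   indexing of all matrices and traces).
#' @param schedule A [transition_schedule()].
#' @param initial_distribution Probability vector over states (must sum to 1).
#' @param horizon_cycles Number of annual cycles (default 10).
#' @param discount_rate Annual discount fraction (default 0.03); rewards in
#'   the first model year are undiscounted.
#' @param cohort_age_at_start Age in years at cycle 0 (default 55).
#' @param transition_costs Optional `data.frame` (`from`, `to`, `cycle`,
#'   `cost`) of one-time costs charged to the probability mass flowing along a
#'   transition in a given cycle (e.g. productivity loss at death before
#'   retirement). Not carried forward: entries apply to their cycle only.
#' @param name Optional model label.
#' @param validate Run [validate_cohort_model()] on construction (default
#'   `TRUE`).
#' @return An object of class `cohort_model`.
#' @export
cohort_model <- function(states, schedule, initial_distribution,
                         horizon_cycles = 10, discount_rate = 0.03,
                         cohort_age_at_start = 55, transition_costs = NULL,
                         name = "model", validate = TRUE) {
  stopifnot(is.list(states), length(states) >= 2L,
            inherits(schedule, "transition_schedule"))
  state_names <- vapply(states, function(s) s$name, character(1))
  if (anyDuplicated(state_names))
    stop("duplicate state names: ",
         paste(unique(state_names[duplicated(state_names)]), collapse = ", "))
  model <- structure(
    list(states = states,
         state_names = state_names,
         schedule = schedule,
         initial_distribution = as.numeric(initial_distribution),
         horizon_cycles = as.integer(horizon_cycles),
         discount_rate = discount_rate,
         cohort_age_at_start = cohort_age_at_start,
         transition_costs = transition_costs,
         name = name),
    class = "cohort_model"
  )
  if (validate) validate_cohort_model(model)
  model
}

#' Validate a cohort model
#'
#' Checks the structural invariants: initial distribution sums to 1, exactly
#' one absorbing death state exists and is reachable from every non-absorbing
#' state, all referenced states exist, probabilities lie in `[0, 1]`, and no
#' row's specified exits exceed 1 at any cycle within the horizon.
#'
#' @param model A [cohort_model()].
#' @return The model, invisibly; errors name the offending state and cycle.
#' @export
validate_cohort_model <- function(model) {
  sn <- model$state_names
  if (abs(sum(model$initial_distribution) - 1) > 1e-9)
    stop("initial_distribution must sum to 1")
  if (length(model$initial_distribution) != length(sn))
    stop("initial_distribution length differs from number of states")
  if (any(model$initial_distribution < 0))
    stop("initial_distribution has negative entries")
  if (model$horizon_cycles < 0) stop("horizon_cycles must be >= 0")
  if (model$discount_rate < 0) stop("discount_rate must be non-negative")
  absorbing <- vapply(model$states, function(s) s$absorbing, logical(1))
  if (sum(absorbing) != 1L)
    stop("model must have exactly one absorbing (death) state; found ",
         sum(absorbing))
  res_to <- vapply(model$states, function(s) s$residual_to, character(1))
  if (!all(res_to %in% sn))
    stop("residual_to targets missing from state set: ",
         paste(setdiff(res_to, sn), collapse = ", "))
  ent <- model$schedule$entries
  if (nrow(ent)) {
    bad <- !(ent$from %in% sn) | !(ent$to %in% sn)
    if (any(bad))
      stop("schedule references unknown states: ",
           paste(unique(c(ent$from[bad], ent$to[bad])), collapse = ", "))
    if (any(ent$prob < 0 | ent$prob > 1)) {
      i <- which(ent$prob < 0 | ent$prob > 1)[1]
      stop("transition probability out of [0, 1] for ", ent$from[i], " -> ",
           ent$to[i], " at cycle ", ent$cycle[i], ": ", ent$prob[i])
    }
    if (any(ent$from[ent$prob > 0] %in% sn[absorbing]))
      stop("absorbing state '", sn[absorbing],
           "' cannot have outgoing transitions")
  }
  # exit sums per (from, cycle) must not exceed 1 (competing transitions are
  # mutually exclusive and subtracted from the residual)
  for (cyc in unique(pmin(seq_len(max(model$horizon_cycles, 1L)) - 1L,
                          model$schedule$carry_forward_cycle))) {
    sub <- ent[ent$cycle == cyc, , drop = FALSE]
    if (!nrow(sub)) next
    sums <- tapply(sub$prob, sub$from, sum)
    over <- sums > 1 + 1e-12
    if (any(over))
      stop("specified exit probabilities of state '",
           names(sums)[over][1], "' sum to ", max(sums[over]),
           " > 1 at cycle ", cyc)
  }
  # the death state must be reachable from every non-absorbing state through
  # the declared structure (all specified edges, even if currently at
  # probability 0 under a degenerate parameterization, plus residual links)
  reach_edges <- unique(rbind(
    ent[, c("from", "to")],
    data.frame(from = sn[!absorbing], to = res_to[!absorbing])
  ))
  dead <- sn[absorbing]
  reaches <- dead
  repeat {
    add <- unique(reach_edges$from[reach_edges$to %in% reaches])
    add <- setdiff(add, reaches)
    if (!length(add)) break
    reaches <- c(reaches, add)
  }
  if (!all(sn %in% reaches))
    stop("death state unreachable from: ",
         paste(setdiff(sn, reaches), collapse = ", "))
  invisible(model)
}

#' Transition matrix at a cycle
#'
#' Builds the row-stochastic transition matrix for a given (0-based) cycle.
#' Cycles past the schedule's `carry_forward_cycle` return the carry-forward
#' matrix. Rows of absorbing states are unit vectors; each remaining row's
#' residual probability is placed on the state's `residual_to` target.
#'
#' @param model A [cohort_model()].
#' @param cycle 0-based cycle index.
#' @return A row-stochastic matrix with state names on both dimensions.
#' @export
transition_matrix_at <- function(model, cycle) {
  if (!is.numeric(cycle) || length(cycle) != 1L || cycle < 0)
    stop("cycle must be a single non-negative index")
  cyc <- min(as.integer(cycle), model$schedule$carry_forward_cycle)
  sn <- model$state_names
  n <- length(sn)
  P <- matrix(0, n, n, dimnames = list(sn, sn))
  ent <- model$schedule$entries
  sub <- ent[ent$cycle == cyc, , drop = FALSE]
  if (nrow(sub)) {
    # duplicate (from, to) entries at one cycle accumulate
    lin <- (match(sub$to, sn) - 1L) * n + match(sub$from, sn)
    agg <- rowsum(sub$prob, lin)
    P[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (any(P < 0))
    stop("negative transition probability at cycle ", cycle)
  absorbing <- vapply(model$states, function(s) s$absorbing, logical(1))
  res_idx <- match(vapply(model$states, function(s) s$residual_to, character(1)), sn)
  exit_sums <- rowSums(P)
  if (any(absorbing & exit_sums > 0))
    stop("absorbing state '", sn[absorbing & exit_sums > 0][1],
         "' has specified exits at cycle ", cycle)
  abs_i <- which(absorbing)
  P[(abs_i - 1L) * n + abs_i] <- 1
  non <- which(!absorbing)
  resid <- 1 - exit_sums[non]
  if (any(resid < -1e-12)) {
    i <- non[resid < -1e-12][1]
    stop("specified exit probabilities of state '", sn[i],
         "' sum to ", exit_sums[i], " > 1 at cycle ", cycle)
  }
  lin_res <- (res_idx[non] - 1L) * n + non
  P[lin_res] <- P[lin_res] + pmax(resid, 0)
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad))
    stop("row of state '", sn[bad][1], "' not stochastic at cycle ", cycle)
  P
}

#' Discount factor
#'
#' `1 / (1 + rate)^cycle` with cycle 0 the first model year, so first-year
#' rewards are undiscounted. A zero rate returns 1 for every cycle.
#'
#' @param rate Annual discount fraction, `>= 0`.
#' @param cycle 0-based cycle index (vectorized).
#' @return Dimensionless discount factor(s).
#' @export
discount_factor <- function(rate, cycle) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("discount rate must be a single non-negative fraction")
  (1 + rate)^(-cycle)
}

# Internal: propagate the occupancy distribution through the horizon.
# Returns (horizon + 1) x n_states matrix; row t+1 is occupancy at cycle t.
propagate_occupancy <- function(model, matrices = NULL) {
  H <- model$horizon_cycles
  n <- length(model$state_names)
  occ <- matrix(0, H + 1L, n, dimnames = list(NULL, model$state_names))
  occ[1L, ] <- model$initial_distribution
  if (H > 0L) {
    for (t in seq_len(H)) {
      P <- if (is.null(matrices)) transition_matrix_at(model, t - 1L) else matrices[[t]]
      occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% P
    }
  }
  occ
}

# Internal: build all per-cycle matrices once (reuse the carry-forward one).
build_matrices <- function(model) {
  H <- model$horizon_cycles
  if (H == 0L) return(list())
  cf <- model$schedule$carry_forward_cycle
  mats <- vector("list", H)
  for (t in 0:(H - 1L)) {
    mats[[t + 1L]] <- if (t > cf) mats[[cf + 1L]] else transition_matrix_at(model, t)
  }
  mats
}

# Internal: discounted rewards from an occupancy trace at a given rate.
# Rewards accrue on start-of-cycle occupancy for cycles 0..H-1; transition
# costs are charged to the flow occ[t] * P_t[from, to] in cycle t.
accrue_rewards <- function(model, occ, matrices, rate) {
  H <- model$horizon_cycles
  if (H == 0L)
    return(list(cum_qaly = 0, cum_cost = 0,
                qaly_increments = numeric(0), cost_increments = numeric(0)))
  u <- vapply(model$states, function(s) s$utility, numeric(1))
  cst <- vapply(model$states, function(s) s$annual_cost, numeric(1))
  df <- discount_factor(rate, 0:(H - 1L))
  occ_start <- occ[seq_len(H), , drop = FALSE]
  qaly_inc <- as.numeric(occ_start %*% u) * df
  cost_inc <- as.numeric(occ_start %*% cst) * df
  tc <- model$transition_costs
  if (!is.null(tc) && nrow(tc)) {
    sn <- model$state_names
    n <- length(sn)
    keep <- tc$cycle >= 0 & tc$cycle < H
    tc <- tc[keep, , drop = FALSE]
    fi <- match(tc$from, sn)
    ti <- match(tc$to, sn)
    for (t in unique(tc$cycle)) {
      k <- which(tc$cycle == t)
      flow <- occ[t + 1L, fi[k]] * matrices[[t + 1L]][(ti[k] - 1L) * n + fi[k]]
      cost_inc[t + 1L] <- cost_inc[t + 1L] + sum(flow * tc$cost[k]) * df[t + 1L]
    }
  }
  list(cum_qaly = sum(qaly_inc), cum_cost = sum(cost_inc),
       qaly_increments = qaly_inc, cost_increments = cost_inc)
}

#' Run a cohort simulation
#'
#' Propagates the cohort's state-occupancy distribution through the horizon
#' (`occupancy(t + 1) = occupancy(t) %*% P(t)`) and accrues discounted
#' rewards on the start-of-cycle occupancy: the year-t QALY increment is
#' `sum_s occupancy(t, s) * utility(s) / (1 + rate)^t`, costs analogously.
#' One-time transition costs are charged to the mass flowing along their
#' transition in their cycle.
#'
#' @param model A validated [cohort_model()].
#' @param discount_rate Optional override of the model's discount rate.
#' @param validate Re-run structural validation before simulating (default
#'   `TRUE`; repeated probabilistic-sensitivity runs of an already validated
#'   structure may skip it — row-stochasticity is still enforced when each
#'   transition matrix is built).
#' @return A `cohort_trace`: list with `occupancy` (matrix, one row per cycle
#'   0..horizon), `cum_qaly`, `cum_cost` (discounted totals),
#'   `qaly_increments`/`cost_increments` (per-cycle discounted increments),
#'   `deaths_by_cycle` (mass entering the death state per cycle) and
#'   `discount_rate`.
#' @export
run_cohort <- function(model, discount_rate = model$discount_rate,
                       validate = TRUE) {
  if (validate) validate_cohort_model(model)
  mats <- build_matrices(model)
  occ <- propagate_occupancy(model, mats)
  H <- model$horizon_cycles
  absorbing <- vapply(model$states, function(s) s$absorbing, logical(1))
  dead <- which(absorbing)
  deaths <- if (H > 0L) occ[2:(H + 1L), dead] - occ[seq_len(H), dead] else numeric(0)
  rew <- accrue_rewards(model, occ, mats, discount_rate)
  structure(
    list(occupancy = occ,
         cum_qaly = rew$cum_qaly,
         cum_cost = rew$cum_cost,
         qaly_increments = rew$qaly_increments,
         cost_increments = rew$cost_increments,
         deaths_by_cycle = deaths,
         discount_rate = discount_rate,
         state_names = model$state_names,
         death_state = model$state_names[dead],
         horizon_cycles = H),
    class = "cohort_trace"
  )
}

# Internal: compile a model into a fast trial evaluator for repeated
# probabilistic-sensitivity runs. Precomputes per-cycle entry indices,
# residual/absorbing structure, reward vectors and discount weights; the
# returned function takes a probability vector aligned with the schedule's
# entry rows (default: the model's own) and returns discounted cumulative
# cost and QALY at each requested rate. Equivalent to run_cohort() row for
# row; the equivalence is asserted in the test suite.
compile_cohort_runner <- function(model, discount_rates = model$discount_rate) {
  validate_cohort_model(model)
  stopifnot(model$horizon_cycles >= 1L)
  sn <- model$state_names
  n <- length(sn)
  H <- model$horizon_cycles
  cf <- model$schedule$carry_forward_cycle
  ent <- model$schedule$entries
  lin <- (match(ent$to, sn) - 1L) * n + match(ent$from, sn)
  rows_by_t <- lapply(0:(H - 1L), function(t) which(ent$cycle == min(t, cf)))
  grp_by_t <- lapply(rows_by_t, function(r) lin[r])
  ulin_by_t <- lapply(grp_by_t, function(g) sort(unique(g)))
  absorbing <- vapply(model$states, function(s) s$absorbing, logical(1))
  abs_lin <- (which(absorbing) - 1L) * n + which(absorbing)
  non <- which(!absorbing)
  res_idx <- match(vapply(model$states, function(s) s$residual_to, character(1)), sn)
  lin_res <- (res_idx[non] - 1L) * n + non
  u <- vapply(model$states, function(s) s$utility, numeric(1))
  cst <- vapply(model$states, function(s) s$annual_cost, numeric(1))
  df_mat <- t(vapply(discount_rates, function(r) discount_factor(r, 0:(H - 1L)),
                     numeric(H)))
  tc <- model$transition_costs
  tc_by_t <- NULL
  if (!is.null(tc) && nrow(tc)) {
    tc <- tc[tc$cycle >= 0 & tc$cycle < H, , drop = FALSE]
    tc_fi <- match(tc$from, sn)
    tc_lin <- (match(tc$to, sn) - 1L) * n + tc_fi
    tc_by_t <- lapply(0:(H - 1L), function(t) {
      k <- which(tc$cycle == t)
      if (length(k)) list(fi = tc_fi[k], lin = tc_lin[k], cost = tc$cost[k])
    })
  }
  init <- model$initial_distribution
  default_prob <- ent$prob

  function(prob = default_prob) {
    qaly_t <- numeric(H)
    cost_t <- numeric(H)
    occ <- init
    for (t in seq_len(H)) {
      P <- matrix(0, n, n)
      r <- rows_by_t[[t]]
      if (length(r)) P[ulin_by_t[[t]]] <- rowsum(prob[r], grp_by_t[[t]], reorder = TRUE)
      P[abs_lin] <- 1
      resid <- 1 - rowSums(P)[non]
      if (any(resid < -1e-12)) {
        i <- non[resid < -1e-12][1]
        stop("specified exit probabilities of state '", sn[i],
             "' exceed 1 at cycle ", t - 1L)
      }
      P[lin_res] <- P[lin_res] + pmax(resid, 0)
      qaly_t[t] <- sum(occ * u)
      cost_t[t] <- sum(occ * cst)
      k <- if (is.null(tc_by_t)) NULL else tc_by_t[[t]]
      if (!is.null(k)) cost_t[t] <- cost_t[t] + sum(occ[k$fi] * P[k$lin] * k$cost)
      occ <- as.numeric(occ %*% P)
    }
    list(cum_qaly = as.numeric(df_mat %*% qaly_t),
         cum_cost = as.numeric(df_mat %*% cost_t))
  }
}

#' Annualized overall mortality of a trace
#'
#' Cumulative death mass divided by person-years at risk, where person-years
#' are the alive mass at the start of each cycle summed over the horizon.
#' Intended for external-validity comparison against a population life table.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param horizon Number of cycles to include (default: the full trace).
#' @return Annual mortality as a per-year fraction.
#' @export
overall_mortality_rate <- function(trace, horizon = trace$horizon_cycles) {
  stopifnot(inherits(trace, "cohort_trace"))
  H <- min(horizon, trace$horizon_cycles)
  if (H < 1L) stop("horizon must cover at least one cycle")
  dead_col <- match(trace$death_state, trace$state_names)
  alive <- 1 - trace$occupancy[seq_len(H), dead_col]
  person_years <- sum(alive)
  if (person_years <= 0) stop("zero person-years at risk")
  deaths <- trace$occupancy[H + 1L, dead_col] - trace$occupancy[1L, dead_col]
  unname(deaths / person_years)
}

#' @export
print.cohort_model <- function(x, ...) {
  cat("<cohort_model>", x$name, "\n")
  cat("  states:", length(x$state_names), "| horizon:", x$horizon_cycles,
      "cycles | discount:", x$discount_rate,
      "| start age:", x$cohort_age_at_start, "\n")
  invisible(x)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", x$horizon_cycles, "cycles, rate", x$discount_rate, "\n")
  cat(sprintf("  cum QALY: %.6f | cum cost: %.2f\n", x$cum_qaly, x$cum_cost))
  invisible(x)
}
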