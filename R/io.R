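#' Write a cohort model to JSON
#'
#' Serializes states (with rewards and residual targets), the sparse
#' transition schedule, initial distribution, horizon, discounting, start age
#' and any transition costs. [read_model_json()] round-trips the model
#' bit-exactly for all numeric fields.
#'
#' @param model A [cohort_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    name = model$name,
    states = lapply(model$states, function(s)
      list(name = s$name, utility = s$utility, annual_cost = s$annual_cost,
           absorbing = s$absorbing, residual_to = s$residual_to)),
    schedule = list(
      carry_forward_cycle = model$schedule$carry_forward_cycle,
      entries = model$schedule$entries
    ),
    initial_distribution = model$initial_distribution,
    horizon_cycles = model$horizon_cycles,
    discount_rate = model$discount_rate,
    cohort_age_at_start = model$cohort_age_at_start,
    transition_costs = model$transition_costs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort model from JSON
#'
#' @param path Model-definition file written by [write_model_json()] or by
#'   hand in the same schema.
#' @return A validated [cohort_model()].
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  states <- lapply(seq_len(nrow(obj$states)), function(i) {
    s <- obj$states[i, ]
    health_state(s$name, s$utility, s$annual_cost, s$absorbing, s$residual_to)
  })
  tc <- obj$transition_costs
  if (!is.null(tc) && !nrow(tc)) tc <- NULL
  cohort_model(
    states = states,
    schedule = transition_schedule(obj$schedule$entries,
                                   obj$schedule$carry_forward_cycle),
    initial_distribution = obj$initial_distribution,
    horizon_cycles = obj$horizon_cycles,
    discount_rate = obj$discount_rate,
    cohort_age_at_start = obj$cohort_age_at_start,
    transition_costs = tc,
    name = if (is.null(obj$name)) "model" else obj$name
  )
}

#' Export a cohort trace as CSV
#'
#' One row per cycle: occupancy of every state, the cycle's discounted QALY
#' and cost increments, and running cumulative totals. Cycle 0 is the first
#' model year; the final row carries the end-of-horizon occupancy with no
#' further accrual.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param path Output CSV file.
#' @return The exported `data.frame`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  H <- trace$horizon_cycles
  inc_q <- c(trace$qaly_increments, 0)
  inc_c <- c(trace$cost_increments, 0)
  out <- data.frame(cycle = 0:H, trace$occupancy,
                    qaly_increment = inc_q, cost_increment = inc_c,
                    cum_qaly = cumsum(inc_q), cum_cost = cumsum(inc_c),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Format EVAS results as a wide per-complication table
#'
#' Mirrors the case study's presentation: one row per complication and
#' discount rate, the cumulative value column, then an
#' (uncertainty, EVAS) pair per SD range. The value column is the cumulative
#' value at the narrowest SD range (the ranges share underlying draws, so
#' their cumulative values agree up to Monte-Carlo noise).
#'
#' @param results Long results from [run_hypertension_evas()].
#' @param digits Rounding for display; `NULL` keeps full precision (the long
#'   `results` object is the full-precision record).
#' @param value_method `"sum"` (default) prints the cumulative sum of trial
#'   values; `"deterministic"` prints trials times the mean-parameter value
#'   (requires the `deterministic` attribute that
#'   [run_hypertension_evas()] attaches).
#' @return Wide `data.frame`.
#' @export
evas_table <- function(results, digits = NULL,
                       value_method = c("sum", "deterministic")) {
  value_method <- match.arg(value_method)
  det <- attr(results, "deterministic")
  if (value_method == "deterministic" && is.null(det))
    stop("results carry no deterministic values")
  fracs <- sort(unique(results$sd_fraction))
  combos <- unique(results[, c("state", "discount_rate")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    st <- combos$state[i]; r <- combos$discount_rate[i]
    sub <- results[results$state == st & results$discount_rate == r, ]
    val <- if (value_method == "deterministic")
      det$value[det$state == st & det$discount_rate == r] * sub$n_trials[1]
    else sub$cumulative_value[sub$sd_fraction == fracs[1]]
    row <- data.frame(state = st, discount_rate = r, value = val)
    for (f in fracs) {
      fs <- sub[sub$sd_fraction == f, ]
      row[[paste0("uncertainty_sd", f * 100)]] <- fs$cumulative_uncertainty
      row[[paste0("evas_sd", f * 100)]] <- fs$evas
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "discount_rate"
    out[num] <- lapply(out[num], round, digits = digits)
  }
  rownames(out) <- NULL
  out
}

#' Write a reproducibility manifest
#'
#' Records the seed, package version, run settings, all parameter values and
#' which inputs are synthetic stand-ins, so no output can silently
#' masquerade as a reproduction of published absolute values.
#'
#' @param path Output JSON file.
#' @param seed Root seed of the run.
#' @param settings Named list of run settings (trials, SD ranges, rates...).
#' @param params Parameter list actually used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, settings, params) {
  synthetic <- names(Filter(function(x)
    is.list(x) && isTRUE(x$synthetic), params))
  obj <- list(
    package = "evas",
    version = as.character(utils::packageVersion("evas")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    settings = settings,
    synthetic_inputs = synthetic,
    parameters = params
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
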