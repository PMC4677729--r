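#' Value of an additional state
#'
#' Net-benefit change attributable to augmenting the basic model A with a
#' complication state (model B), expressed on the QALY scale:
#' `(C_B - C_A) / lambda + (E_A - E_B)`. Positive when the added state raises
#' cost and/or lowers effectiveness. Vectorized over trials.
#'
#' @param C_A,C_B Discounted cumulative cost (yen) of models A and B.
#' @param E_A,E_B Discounted cumulative effectiveness (QALY) of A and B.
#' @param lambda Willingness-to-pay threshold in yen per QALY
#'   (default 5,000,000 yen, the value of 1 QALY).
#' @return QALY-equivalent value(s) of the additional state.
#' @export
value_of_additional_state <- function(C_A, C_B, E_A, E_B, lambda = 5e6) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive yen-per-QALY threshold")
  (C_B - C_A) / lambda + (E_A - E_B)
}

#' Cumulative value over Monte-Carlo trials
#'
#' Plain sum of per-trial values of the additional state (the case-study
#' tables report cumulative values of 10,000 Monte-Carlo simulations; the
#' per-trial mean is the sum divided by the number of trials).
#'
#' @param trial_values Non-empty numeric vector of per-trial values.
#' @return The sum over trials.
#' @export
cumulative_value <- function(trial_values) {
  if (length(trial_values) == 0L) stop("trial_values must be non-empty")
  sum(trial_values)
}

#' Cumulative Monte-Carlo uncertainty of an additional state
#'
#' Summed absolute deviation of the per-trial values from the average value
#' of the additional state: `sum(|v_i - reference|)`, with the reference
#' defaulting to the mean of the trial values.
#'
#' @param trial_values Non-empty numeric vector of per-trial values.
#' @param reference Central value the deviations are taken from (default:
#'   `mean(trial_values)`).
#' @return Non-negative QALY-equivalent sum.
#' @export
cumulative_uncertainty <- function(trial_values, reference = mean(trial_values)) {
  if (length(trial_values) == 0L) stop("trial_values must be non-empty")
  sum(abs(trial_values - reference))
}

#' Expected value of the additional state (EVAS)
#'
#' `EVAS = value of the additional state - uncertainty of that additional
#' state`, exactly. A state whose value is large but whose uncertainty is
#' also large may rank below a smaller, more robust state.
#'
#' @param cumulative_value Cumulative (or per-trial mean) value.
#' @param cumulative_uncertainty Matching non-negative uncertainty.
#' @return `cumulative_value - cumulative_uncertainty` (vectorized).
#' @export
evas <- function(cumulative_value, cumulative_uncertainty) {
  if (any(cumulative_uncertainty < 0))
    stop("cumulative_uncertainty must be non-negative")
  cumulative_value - cumulative_uncertainty
}

#' Summarize one complication's trials into an EVAS record
#'
#' @param trial_values Per-trial values of the additional state.
#' @param state_name Complication label.
#' @param sd_fraction,discount_rate Conditions the trials were run under.
#' @return One-row `data.frame` with `state`, `discount_rate`, `sd_fraction`,
#'   `n_trials`, `cumulative_value`, `cumulative_uncertainty`, `evas`,
#'   `mean_value`.
#' @export
evas_record <- function(trial_values, state_name, sd_fraction,
                        discount_rate = NA_real_) {
  cv <- cumulative_value(trial_values)
  cu <- cumulative_uncertainty(trial_values)
  data.frame(
    state = state_name,
    discount_rate = discount_rate,
    sd_fraction = sd_fraction,
    n_trials = length(trial_values),
    cumulative_value = cv,
    cumulative_uncertainty = cu,
    evas = evas(cv, cu),
    mean_value = cv / length(trial_values),
    stringsAsFactors = FALSE
  )
}

#' Rank candidate additional states by EVAS
#'
#' Orders the complications by descending EVAS at one SD range (and discount
#' rate, if the table carries several); rank 1 is the state the model can
#' least afford to drop. Ties break alphabetically by state name and are
#' flagged. The result also reports whether ordering by raw cumulative value
#' differs from ordering by EVAS — the situation where uncertainty reverses a
#' value-based ranking.
#'
#' @param results `data.frame` of EVAS records (e.g. rows of
#'   [evas_record()] or the table from [run_hypertension_evas()]).
#' @param sd_fraction SD-range fraction to rank at; every state in `results`
#'   must have a row at this fraction.
#' @param discount_rate Discount rate to rank at (default: the first rate
#'   present).
#' @return `data.frame` sorted by rank with columns of `results` plus
#'   `rank`, `tie` and attribute `order_changed_by_uncertainty`.
#' @export
rank_states <- function(results, sd_fraction,
                        discount_rate = results$discount_rate[1]) {
  stopifnot(is.data.frame(results), "evas" %in% names(results))
  sub <- results[results$sd_fraction == sd_fraction &
                   (is.na(discount_rate) |
                      results$discount_rate == discount_rate), , drop = FALSE]
  missing <- setdiff(unique(results$state), unique(sub$state))
  if (length(missing))
    stop("no result at sd_fraction ", sd_fraction, " for state(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(sub)) stop("no results at sd_fraction ", sd_fraction)
  ord <- order(-sub$evas, sub$state)
  sub <- sub[ord, , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  sub$tie <- duplicated(sub$evas) | duplicated(sub$evas, fromLast = TRUE)
  by_value <- sub$state[order(-sub$cumulative_value, sub$state)]
  attr(sub, "order_changed_by_uncertainty") <- !identical(by_value, sub$state)
  rownames(sub) <- NULL
  sub
}
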