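#' Load the grade-I hypertension case-study parameters
#'
#' Reads the frozen human-readable parameters fixture: published transition
#' probabilities and utilities of the case study, plus synthetic stand-ins
#' (flagged `"synthetic": true`) for the cost table, wages, background life
#' table and mRS discharge allocation. Every quantity can be overridden.
#'
#' @param path Parameters file (default: the bundled fixture).
#' @param overrides Named list merged recursively over the file's contents
#'   (e.g. `list(costs_yen = list(esrd = list(dialysis_annual = 6e6)))`).
#' @return Nested list of parameters.
#' @export
hypertension_parameters <- function(path = system.file("extdata",
                                                       "hypertension_parameters.json",
                                                       package = "evas"),
                                    overrides = list()) {
  if (!nzchar(path) || !file.exists(path)) stop("parameters fixture not found")
  params <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(overrides)) params <- utils::modifyList(params, overrides)
  params
}

#' Productivity loss at death before retirement
#'
#' Sum of annual wages from the age at death up to the year before the
#' retirement age (65 by default); zero at or beyond retirement.
#'
#' @param age_at_death Age in whole years when death occurs.
#' @param wage_table `data.frame` with columns `age` and `wage` (yen/year),
#'   covering working ages, or a single flat annual wage.
#' @param retirement_age First age with no wage (default 65).
#' @return Yen lost (vectorized over `age_at_death`).
#' @export
work_lost_cost <- function(age_at_death, wage_table, retirement_age = 65) {
  if (is.numeric(wage_table) && is.null(dim(wage_table)) && length(wage_table) == 1L) {
    return(pmax(retirement_age - age_at_death, 0) * wage_table)
  }
  stopifnot(is.data.frame(wage_table), all(c("age", "wage") %in% names(wage_table)))
  vapply(age_at_death, function(a) {
    yrs <- wage_table$age >= a & wage_table$age < retirement_age
    sum(wage_table$wage[yrs])
  }, numeric(1))
}

# State-name helpers for the case-study models.
stroke_state_name <- function(mrs, year) paste0("stroke_mrs", mrs, "_y", year)

# Internal: parametric skeleton of a case-study model. Every schedule entry's
# probability has the form  w * probs[pname] + bg * q(age at cycle), so the
# entry probabilities of a whole model are one vectorized expression of the
# sampled parameter vector — the repeated-trial machinery reuses the skeleton
# and recomputes only that expression.
hypertension_skeleton <- function(complication = "none",
                                  esrd_mode = "dialysis",
                                  params = hypertension_parameters(),
                                  life_table = NULL,
                                  mrs_dist = NULL) {
  stopifnot(complication %in% c("none", "recurrence", "chd", "esrd"))
  if (is.null(life_table))
    life_table <- generate_life_table(params$life_table$a, params$life_table$b,
                                      params$life_table$age_min:params$life_table$age_max)
  if (is.null(mrs_dist)) mrs_dist <- params$mrs_discharge_distribution$proportions
  if (abs(sum(mrs_dist) - 1) > 1e-9) stop("mRS discharge proportions must sum to 1")
  u <- params$utilities
  cs <- params$costs_yen
  H <- params$cohort$horizon_years
  start_age <- params$cohort$start_age
  cycles <- 0:(H - 1L)
  n_c <- length(cycles)
  q_bg <- life_table_qx(life_table, start_age + cycles)
  mrs_idx <- 0:5

  # states: well, 6 mRS bands x 5 tunnel years, dead (+ complication states)
  stroke_names <- as.vector(t(outer(mrs_idx, 1:5, stroke_state_name)))
  states <- list(health_state("well", utility = u$healthy, annual_cost = 0))
  for (m in mrs_idx) {
    nursing <- if (m >= 2) cs$stroke$nursing_care_annual_mrs2_5 else 0
    for (y in 1:5) {
      onetime <- if (y == 1) cs$stroke$acute_phase_hospital + cs$stroke$recovery_phase_care else 0
      states[[length(states) + 1L]] <- health_state(
        stroke_state_name(m, y),
        utility = u$stroke_mrs[m + 1L],
        annual_cost = onetime + cs$stroke$ambulant_treatment_annual + nursing,
        residual_to = stroke_state_name(m, min(y + 1L, 5L))
      )
    }
  }
  if (complication == "chd") {
    states <- c(states, list(
      health_state("chd_y1", utility = u$chd_year1,
                   annual_cost = cs$chd$acute_phase_hospital +
                     cs$chd$ambulant_treatment_annual,
                   residual_to = "chd_later"),
      health_state("chd_later", utility = u$chd_later,
                   annual_cost = cs$chd$ambulant_treatment_annual)
    ))
  } else if (complication == "esrd") {
    stopifnot(esrd_mode %in% c("dialysis", "conservative"))
    mode_cost <- if (esrd_mode == "dialysis") cs$esrd$dialysis_annual else
      cs$esrd$conservative_annual
    states <- c(states, list(
      health_state("esrd", utility = u$esrd,
                   annual_cost = mode_cost + cs$esrd$ambulant_treatment_annual)
    ))
  }
  states <- c(states, list(health_state("dead", 0, 0, absorbing = TRUE)))

  # entry skeleton, one block per exit family, all cycles vectorized
  skel <- list(
    # hypertensive-well: first stroke, allocated over discharge mRS bands
    data.frame(from = "well",
               to = rep(stroke_state_name(mrs_idx, 1L), each = n_c),
               cycle = rep(cycles, 6),
               pname = "stroke_incidence",
               w = rep(mrs_dist, each = n_c), bg = 0),
    # background all-cause mortality from well
    data.frame(from = "well", to = "dead", cycle = cycles,
               pname = NA_character_, w = 0, bg = 1),
    # post-stroke mortality: year-since-stroke schedule plus background
    data.frame(from = rep(stroke_names, each = n_c),
               to = "dead",
               cycle = rep(cycles, length(stroke_names)),
               pname = rep(paste0("stroke_mortality_year", rep(1:5, 6)), each = n_c),
               w = 1, bg = 1)
  )
  if (complication == "recurrence") {
    # re-entry into the year-1 tunnel of the same mRS band; the mortality
    # clock restarts and acute-phase costs are charged again
    skel <- c(skel, list(
      data.frame(from = rep(stroke_names, each = n_c),
                 to = rep(stroke_state_name(rep(mrs_idx, each = 5), 1L), each = n_c),
                 cycle = rep(cycles, length(stroke_names)),
                 pname = rep(ifelse(rep(1:5, 6) == 1L, "stroke_recurrence_year1",
                                    "stroke_recurrence_later"), each = n_c),
                 w = 1, bg = 0)
    ))
  } else if (complication == "chd") {
    skel <- c(skel, list(
      data.frame(from = "well", to = "chd_y1", cycle = cycles,
                 pname = "chd_incidence", w = 1, bg = 0),
      data.frame(from = "chd_y1", to = "dead", cycle = cycles,
                 pname = "chd_inhospital_mortality", w = 1, bg = 1),
      data.frame(from = "chd_later", to = "dead", cycle = cycles,
                 pname = "chd_annual_mortality", w = 1, bg = 1)
    ))
  } else if (complication == "esrd") {
    skel <- c(skel, list(
      data.frame(from = "well", to = "esrd", cycle = cycles,
                 pname = "esrd_incidence", w = 1, bg = 0),
      data.frame(from = "esrd", to = "dead", cycle = cycles,
                 pname = "esrd_annual_mortality", w = 1, bg = 1)
    ))
  }
  skel <- do.call(rbind, skel)

  # productivity loss: deaths out of post-stroke states before retirement
  wl <- work_lost_cost(start_age + cycles, params$wages$annual_wage_yen,
                       params$wages$retirement_age)
  tc <- data.frame(from = rep(stroke_names, each = n_c),
                   to = "dead",
                   cycle = rep(cycles, length(stroke_names)),
                   cost = rep(wl, length(stroke_names)))
  tc <- tc[tc$cost > 0, , drop = FALSE]

  label <- if (complication == "esrd") paste0("esrd_", esrd_mode) else complication
  list(complication = complication, esrd_mode = esrd_mode, params = params,
       states = states, skeleton = skel, transition_costs = tc,
       horizon = H, start_age = start_age, q_bg = q_bg,
       life_table = life_table, mrs_dist = mrs_dist,
       name = paste0("hypertension-", if (complication == "none") "base" else label))
}

# Internal: evaluate a skeleton's entry probabilities at a parameter vector.
hypertension_entry_probs <- function(skel, probs) {
  s <- skel$skeleton
  p <- ifelse(is.na(s$pname), 0, s$w * unname(probs[s$pname]))
  p + s$bg * skel$q_bg[s$cycle + 1L]
}

# Internal workhorse: assemble the basic stroke model, optionally augmented
# with exactly one complication branch.
build_hypertension_model_ <- function(complication = "none",
                                      esrd_mode = "dialysis",
                                      params = hypertension_parameters(),
                                      tp = NULL,
                                      discount_rate = 0.03,
                                      life_table = NULL,
                                      mrs_dist = NULL,
                                      validate = TRUE,
                                      skeleton = NULL) {
  if (is.null(skeleton))
    skeleton <- hypertension_skeleton(complication, esrd_mode, params,
                                      life_table, mrs_dist)
  probs <- unlist(skeleton$params$transition_probabilities)
  if (!is.null(tp)) {
    unknown <- setdiff(names(tp), names(probs))
    if (length(unknown))
      stop("unknown transition parameters: ", paste(unknown, collapse = ", "))
    probs[names(tp)] <- unlist(tp)
  }
  ent <- skeleton$skeleton[, c("from", "to", "cycle")]
  ent$prob <- hypertension_entry_probs(skeleton, probs)
  sn <- vapply(skeleton$states, function(s) s$name, character(1))
  model <- cohort_model(
    states = skeleton$states,
    schedule = transition_schedule(ent, carry_forward_cycle = skeleton$horizon - 1L),
    initial_distribution = as.numeric(sn == "well"),
    horizon_cycles = skeleton$horizon,
    discount_rate = discount_rate,
    cohort_age_at_start = skeleton$start_age,
    transition_costs = skeleton$transition_costs,
    name = skeleton$name,
    validate = validate
  )
  attr(model, "blueprint") <- list(
    complication = skeleton$complication, esrd_mode = skeleton$esrd_mode,
    params = skeleton$params, tp = tp, discount_rate = discount_rate,
    life_table = skeleton$life_table, mrs_dist = skeleton$mrs_dist
  )
  model
}

#' Build the basic stroke model
#'
#' The basic model of grade-I hypertension: a hypertensive-well state, a
#' first-stroke branch split over modified Rankin Scale (mRS) disability
#' bands at hospital discharge, and death. Time-since-stroke mortality
#' (years 1-5, then carry-forward) is realized with tunnel states — one
#' sub-state per post-stroke year per mRS band — whose residual survivor mass
#' advances to the next tunnel year. Background all-cause mortality from the
#' life table applies to every alive state, competing (mutually exclusively)
#' with event probabilities. Disability is assumed constant over time.
#'
#' @param params Parameter list from [hypertension_parameters()].
#' @param tp Optional named vector overriding individual transition
#'   probabilities (names as in `params$transition_probabilities`).
#' @param discount_rate Annual discount rate (default 3\%).
#' @param life_table Background-mortality table (default: the synthetic
#'   [generate_life_table()] parameterized by `params`).
#' @param mrs_dist Discharge allocation over mRS 0-5 (default: the synthetic
#'   fixture proportions).
#' @param validate Validate the assembled model (default `TRUE`).
#' @return A [cohort_model()] with a `blueprint` attribute the augmentation
#'   helpers rebuild from.
#' @export
build_base_model <- function(params = hypertension_parameters(), tp = NULL,
                             discount_rate = 0.03, life_table = NULL,
                             mrs_dist = NULL, validate = TRUE) {
  build_hypertension_model_("none", params = params, tp = tp,
                            discount_rate = discount_rate,
                            life_table = life_table, mrs_dist = mrs_dist,
                            validate = validate)
}

# Internal: rebuild an augmented model from a base model's blueprint.
augment_from <- function(base, complication, esrd_mode = "dialysis") {
  bp <- attr(base, "blueprint")
  if (is.null(bp)) stop("base model lacks a blueprint; build it with build_base_model()")
  if (bp$complication != "none")
    stop("model already carries complication '", bp$complication,
         "'; complications are compared one addition at a time")
  build_hypertension_model_(complication, esrd_mode = esrd_mode,
                            params = bp$params, tp = bp$tp,
                            discount_rate = bp$discount_rate,
                            life_table = bp$life_table, mrs_dist = bp$mrs_dist)
}

#' Augment the basic model with one complication
#'
#' Each helper adds exactly one complication branch to the basic stroke
#' model; applying a second augmentation errors, since candidate states are
#' valued one addition at a time.
#'
#' * `with_recurrence()`: post-stroke states gain a recurrence transition
#'   (first post-stroke year vs later years) back into the year-1 tunnel of
#'   the same mRS band, so recurrent strokes reuse the first-stroke mortality
#'   schedule and are recharged acute-phase costs. No new states are added:
#'   the tunnel already encodes time since the (latest) stroke.
#' * `with_chd()`: a coronary heart disease branch from the well state —
#'   entry-year state (in-hospital mortality, acute cost, utility 0.68) then
#'   a chronic state (annual mortality carried forward, utility 0.72).
#' * `with_esrd()`: an end-stage renal disease state from the well state,
#'   with annual mortality and a treatment-mode-dependent annual cost
#'   (dialysis or conservative management).
#'
#' @param base Basic model from [build_base_model()].
#' @param mode ESRD treatment mode, `"dialysis"` or `"conservative"`.
#' @return An augmented [cohort_model()].
#' @export
with_recurrence <- function(base) augment_from(base, "recurrence")

#' @rdname with_recurrence
#' @export
with_chd <- function(base) augment_from(base, "chd")

#' @rdname with_recurrence
#' @export
with_esrd <- function(base, mode = c("dialysis", "conservative")) {
  mode <- match.arg(mode)
  augment_from(base, "esrd", esrd_mode = mode)
}

# Complication labels of the case study, in fixture order.
hypertension_complications <- function() {
  c("recurrence", "chd", "esrd_dialysis", "esrd_conservative")
}

# Internal: which sampled parameters a model variant actually uses.
hypertension_param_names <- function(complication = "all") {
  shared <- c("stroke_incidence", paste0("stroke_mortality_year", 1:5))
  extra <- switch(complication,
    none = character(),
    recurrence = c("stroke_recurrence_year1", "stroke_recurrence_later"),
    chd = c("chd_incidence", "chd_inhospital_mortality", "chd_annual_mortality"),
    esrd_dialysis = ,
    esrd_conservative = c("esrd_incidence", "esrd_annual_mortality"),
    all = c("stroke_recurrence_year1", "stroke_recurrence_later",
            "chd_incidence", "chd_inhospital_mortality", "chd_annual_mortality",
            "esrd_incidence", "esrd_annual_mortality")
  )
  c(shared, extra)
}

#' Model factory for probabilistic sensitivity analysis
#'
#' Returns a builder `function(tp)` mapping a named vector of sampled
#' transition probabilities to the corresponding case-study model, for use
#' with [run_psa()]. The structure is validated once when the factory is
#' created; per-trial rebuilds skip re-validation (row-stochasticity is still
#' enforced in every transition matrix).
#'
#' @param complication One of `"none"`, `"recurrence"`, `"chd"`,
#'   `"esrd_dialysis"`, `"esrd_conservative"`.
#' @param params Parameter list from [hypertension_parameters()].
#' @param discount_rate Discount rate baked into built models (rewards can be
#'   re-accrued at other rates by the PSA driver).
#' @return Function of a named probability vector returning a
#'   [cohort_model()].
#' @export
hypertension_builder <- function(complication, params = hypertension_parameters(),
                                 discount_rate = 0.03) {
  stopifnot(complication %in% c("none", hypertension_complications()))
  comp <- sub("^esrd_.*$", "esrd", complication)
  mode <- if (comp == "esrd") sub("^esrd_", "", complication) else "dialysis"
  skel <- hypertension_skeleton(comp, esrd_mode = mode, params = params)
  # validate the structure once at the mean parameter values
  build_hypertension_model_(discount_rate = discount_rate, skeleton = skel,
                            validate = TRUE)
  function(tp) {
    build_hypertension_model_(tp = tp, discount_rate = discount_rate,
                              skeleton = skel, validate = FALSE)
  }
}

#' Run the full case-study EVAS analysis
#'
#' For each SD range, samples the Table-of-clinical-parameters transition
#' probabilities from method-of-moments beta distributions (SD = fraction
#' times mean), rebuilds the basic model and each singly-augmented model from
#' the same sampled values (paired design; the basic model is simulated once
#' per trial and shared across complications), and summarizes each
#' complication's per-trial value of the additional state into cumulative
#' value, cumulative uncertainty and EVAS at every discount rate.
#'
#' @param sd_fractions SD ranges as fractions of the mean
#'   (default `c(0.0625, 0.125, 0.25, 0.50)`).
#' @param n_trials Monte-Carlo trials per SD range (default 10000).
#' @param seed Integer root seed.
#' @param params Case-study parameters ([hypertension_parameters()]).
#' @param complications Subset of
#'   `c("recurrence", "chd", "esrd_dialysis", "esrd_conservative")`.
#' @param discount_rates Rates rewards are accrued at (default 3\% and 0\%).
#' @param lambda Willingness-to-pay threshold (yen/QALY).
#' @param return_trials Also return the per-trial value matrices (list
#'   attribute `trials`, one `n_trials x n_complications` matrix per
#'   (rate, sd_fraction)).
#' @param progress Print a line per SD range to standard error.
#' @return `data.frame` with one row per (complication, discount rate, SD
#'   fraction): `state`, `discount_rate`, `sd_fraction`, `n_trials`,
#'   `cumulative_value`, `cumulative_uncertainty`, `evas`, `mean_value`.
#'   Attribute `deterministic` holds the no-sampling value of each
#'   complication at each rate; attribute `seed` the root seed.
#' @export
run_hypertension_evas <- function(sd_fractions = c(0.0625, 0.125, 0.25, 0.50),
                                  n_trials = 10000, seed = 1L,
                                  params = hypertension_parameters(),
                                  complications = hypertension_complications(),
                                  discount_rates = c(0.03, 0),
                                  lambda = params$lambda_yen_per_qaly,
                                  return_trials = FALSE,
                                  progress = FALSE) {
  stopifnot(all(complications %in% hypertension_complications()),
            n_trials >= 1, all(sd_fractions > 0))
  probs <- unlist(params$transition_probabilities)
  pnames <- hypertension_param_names("all")
  variants <- c("none", complications)
  skels <- stats::setNames(lapply(variants, function(cc) {
    comp <- sub("^esrd_.*$", "esrd", cc)
    mode <- if (comp == "esrd") sub("^esrd_", "", cc) else "dialysis"
    hypertension_skeleton(comp, esrd_mode = mode, params = params)
  }), variants)
  models <- lapply(skels, function(sk)
    build_hypertension_model_(skeleton = sk, validate = TRUE))
  runners <- lapply(models, compile_cohort_runner,
                    discount_rates = discount_rates)
  U <- psa_uniforms(n_trials, pnames, seed)
  nr <- length(discount_rates)

  # deterministic (mean-parameter) runs
  det_base <- runners$none()
  det_val <- do.call(rbind, lapply(complications, function(cc) {
    d <- runners[[cc]]()
    data.frame(state = cc, discount_rate = discount_rates,
               value = value_of_additional_state(det_base$cum_cost, d$cum_cost,
                                                 det_base$cum_qaly, d$cum_qaly,
                                                 lambda))
  }))

  results <- list()
  trials_out <- list()
  for (f in sd_fractions) {
    if (progress) message("sd_fraction ", f, ": ", n_trials, " trials")
    specs <- make_specs(probs[pnames], f)
    vals <- sample_trial_params(specs, n_trials, uniforms = U)
    v <- array(NA_real_, c(n_trials, length(complications), nr),
               dimnames = list(NULL, complications, NULL))
    for (i in seq_len(n_trials)) {
      p <- vals[i, ]
      outA <- runners$none(hypertension_entry_probs(skels$none, p))
      for (cc in seq_along(complications)) {
        nm <- complications[cc]
        outB <- runners[[nm]](hypertension_entry_probs(skels[[nm]], p))
        for (r in seq_len(nr)) {
          v[i, cc, r] <- value_of_additional_state(outA$cum_cost[r], outB$cum_cost[r],
                                                   outA$cum_qaly[r], outB$cum_qaly[r],
                                                   lambda)
        }
      }
    }
    for (r in seq_len(nr)) {
      for (cc in seq_along(complications)) {
        results[[length(results) + 1L]] <- evas_record(
          v[, cc, r], complications[cc], f, discount_rates[r])
      }
      if (return_trials)
        trials_out[[paste0("rate", discount_rates[r], "_sd", f)]] <- v[, , r, drop = FALSE]
    }
  }
  res <- do.call(rbind, results)
  rownames(res) <- NULL
  attr(res, "deterministic") <- det_val
  attr(res, "seed") <- seed
  attr(res, "lambda") <- lambda
  if (return_trials) attr(res, "trials") <- trials_out
  res
}
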