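#' Beta shape parameters from mean and standard deviation
#'
#' Method-of-moments parameterization of the beta distribution used for
#' probabilistic sensitivity analysis of transition probabilities:
#' `alpha = mean * (mean (1 - mean) / sd^2 - 1)`,
#' `beta = (1 - mean) * (mean (1 - mean) / sd^2 - 1)`.
#' The resulting distribution has exactly the requested mean and SD.
#'
#' @param mean Mean probability, strictly inside (0, 1).
#' @param sd Probability-scale standard deviation; must satisfy the beta
#'   feasibility bound `sd^2 < mean * (1 - mean)`.
#' @param name Parameter name used in error messages.
#' @return Named numeric vector `c(alpha =, beta =)`, both positive.
#' @export
beta_from_mean_sd <- function(mean, sd, name = "parameter") {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0 || mean >= 1)
    stop("mean of '", name, "' must lie strictly in (0, 1); got ", mean)
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("sd of '", name, "' must be positive; got ", sd)
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop("infeasible SD for '", name, "': sd^2 = ", signif(v, 6),
         " >= mean(1-mean) = ", signif(mean * (1 - mean), 6),
         " (SD range too wide for this probability)")
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Specify a sampled transition parameter
#'
#' @param name Parameter identifier.
#' @param mean Mean probability in (0, 1).
#' @param sd_fraction SD expressed as a fraction of the mean (the SD ranges
#'   used in the case study are 0.0625, 0.125, 0.25 and 0.50, i.e.
#'   \eqn{\pm}6.25\% to \eqn{\pm}50\% of the mean); any positive fraction is
#'   accepted. A fraction of 0 marks the parameter as fixed at its mean.
#' @return An object of class `parameter_spec` with fields `name`, `mean`,
#'   `sd_fraction`, `sd = sd_fraction * mean` and, when `sd_fraction > 0`,
#'   the beta shapes `alpha` and `beta`.
#' @export
parameter_spec <- function(name, mean, sd_fraction) {
  stopifnot(is.character(name), length(name) == 1L)
  if (sd_fraction < 0) stop("sd_fraction of '", name, "' must be >= 0")
  sd <- sd_fraction * mean
  shapes <- if (sd_fraction > 0) beta_from_mean_sd(mean, sd, name) else
    c(alpha = NA_real_, beta = NA_real_)
  structure(
    list(name = name, mean = mean, sd_fraction = sd_fraction, sd = sd,
         alpha = unname(shapes["alpha"]), beta = unname(shapes["beta"])),
    class = "parameter_spec"
  )
}

#' Build parameter specs for a set of transition probabilities
#'
#' One [parameter_spec()] per parameter, all at the same SD-range fraction
#' (`sd = sd_fraction * mean`). Parameters listed in `fixed` are excluded
#' from sampling.
#'
#' @param base_params Named numeric vector or list of mean probabilities.
#' @param sd_fraction Common SD fraction of the mean.
#' @param fixed Character vector of parameter names to leave unsampled.
#' @return Named list of `parameter_spec` objects.
#' @export
make_specs <- function(base_params, sd_fraction, fixed = character()) {
  base_params <- unlist(base_params)
  stopifnot(!is.null(names(base_params)), all(nzchar(names(base_params))))
  keep <- setdiff(names(base_params), fixed)
  specs <- lapply(keep, function(nm)
    parameter_spec(nm, unname(base_params[[nm]]), sd_fraction))
  names(specs) <- keep
  specs
}

#' Uniform substreams for paired Monte-Carlo sampling
#'
#' Draws one uniform variate per (trial, parameter) from a single root seed.
#' Sampled parameter values are obtained by pushing these uniforms through
#' the beta quantile function of each spec, so the same underlying draws are
#' reused (common random numbers) across paired models and across SD-range
#' sweeps: a trial's parameter value at a wider range is the same quantile of
#' a wider beta.
#'
#' @param n_trials Number of Monte-Carlo trials.
#' @param param_names Character vector of parameter names (column order is
#'   part of the reproducibility contract).
#' @param seed Integer root seed.
#' @return `n_trials x length(param_names)` matrix of uniforms in (0, 1).
#' @export
psa_uniforms <- function(n_trials, param_names, seed) {
  stopifnot(n_trials >= 1, length(param_names) >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  matrix(stats::runif(n_trials * length(param_names)),
         nrow = n_trials, ncol = length(param_names),
         dimnames = list(NULL, param_names))
}

#' Sample trial parameter sets
#'
#' Transforms uniform substreams through each spec's beta quantile function.
#' Specs with `sd_fraction = 0` are degenerate and return their mean in every
#' trial. Identical `(seed, n_trials, specs)` reproduce identical values
#' bit-for-bit.
#'
#' @param specs Named list of [parameter_spec()] objects.
#' @param n_trials Number of trials.
#' @param seed Integer root seed (ignored when `uniforms` is supplied).
#' @param uniforms Optional pre-drawn matrix from [psa_uniforms()]; must
#'   contain a column per spec name.
#' @return `n_trials x n_params` matrix of sampled probabilities in (0, 1).
#' @export
sample_trial_params <- function(specs, n_trials, seed = 1L, uniforms = NULL) {
  nms <- vapply(specs, function(s) s$name, character(1))
  if (is.null(uniforms)) uniforms <- psa_uniforms(n_trials, nms, seed)
  if (!all(nms %in% colnames(uniforms)))
    stop("uniforms matrix lacks columns: ",
         paste(setdiff(nms, colnames(uniforms)), collapse = ", "))
  vals <- matrix(NA_real_, nrow(uniforms), length(specs),
                 dimnames = list(NULL, nms))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    vals[, j] <- if (s$sd_fraction > 0)
      stats::qbeta(uniforms[, s$name], s$alpha, s$beta)
    else rep(s$mean, nrow(uniforms))
  }
  vals
}

#' Run a paired probabilistic sensitivity analysis
#'
#' Repeatedly samples the transition parameters, rebuilds the basic model A
#' and the augmented model B from the same sampled values (shared parameters
#' take identical values in both models within a trial — a paired,
#' common-random-numbers design, so sampling noise in shared states cancels
#' in the value of the additional state), and records both models' discounted
#' cumulative cost and QALY at each requested discount rate.
#'
#' @param builder_A,builder_B Functions taking a named vector of sampled
#'   parameter values and returning a valid [cohort_model()].
#' @param specs Named list of [parameter_spec()] covering the union of both
#'   models' sampled parameters.
#' @param n_trials Number of Monte-Carlo trials (default 10000).
#' @param seed Integer root seed.
#' @param discount_rates Numeric vector of annual discount rates at which
#'   rewards are accrued from the same occupancy traces (default 3\% and 0\%).
#' @param uniforms Optional pre-drawn uniform matrix (see [psa_uniforms()]).
#' @return `data.frame` with one row per (trial, discount rate):
#'   `trial`, `discount_rate`, `C_A`, `C_B`, `E_A`, `E_B`.
#' @export
run_psa <- function(builder_A, builder_B, specs, n_trials = 10000, seed = 1L,
                    discount_rates = c(0.03, 0), uniforms = NULL) {
  stopifnot(is.function(builder_A), is.function(builder_B), n_trials >= 1)
  vals <- sample_trial_params(specs, n_trials, seed, uniforms)
  n_trials <- nrow(vals)
  nr <- length(discount_rates)
  out_CA <- out_CB <- out_EA <- out_EB <- matrix(NA_real_, n_trials, nr)
  for (i in seq_len(n_trials)) {
    p <- vals[i, ]
    res <- tryCatch({
      mA <- builder_A(p)
      mB <- builder_B(p)
      matsA <- build_matrices(mA)
      matsB <- build_matrices(mB)
      occA <- propagate_occupancy(mA, matsA)
      occB <- propagate_occupancy(mB, matsB)
      list(mA = mA, mB = mB, matsA = matsA, matsB = matsB,
           occA = occA, occB = occB)
    }, error = function(e) {
      stop("PSA trial ", i, " failed (",
           paste(sprintf("%s=%.6g", names(p), p), collapse = ", "),
           "): ", conditionMessage(e), call. = FALSE)
    })
    for (r in seq_len(nr)) {
      rA <- accrue_rewards(res$mA, res$occA, res$matsA, discount_rates[r])
      rB <- accrue_rewards(res$mB, res$occB, res$matsB, discount_rates[r])
      out_CA[i, r] <- rA$cum_cost; out_EA[i, r] <- rA$cum_qaly
      out_CB[i, r] <- rB$cum_cost; out_EB[i, r] <- rB$cum_qaly
    }
  }
  data.frame(
    trial = rep(seq_len(n_trials), times = nr),
    discount_rate = rep(discount_rates, each = n_trials),
    C_A = as.numeric(out_CA), C_B = as.numeric(out_CB),
    E_A = as.numeric(out_EA), E_B = as.numeric(out_EB)
  )
}
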