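#' Generate a synthetic annual life table
#'
#' Deterministic parametric stand-in for a national life table: annual
#' all-cause death probability rising exponentially with age,
#' `q(age) = min(a * exp(b * (age - min(ages))), 0.99)`. This is a synthetic
#' background-mortality fixture, not population data.
#'
#' @param a Baseline annual death probability at the youngest age (`> 0`).
#' @param b Log-linear increase per year of age (`>= 0`).
#' @param ages Integer ages covered (default 55 to 64, the case-study
#'   horizon).
#' @return `data.frame` of class `synthetic_life_table` with columns `age`
#'   and `qx`, and attribute `synthetic = TRUE`.
#' @export
generate_life_table <- function(a = 0.005, b = 0.08, ages = 55:64) {
  stopifnot(a > 0, b >= 0, length(ages) >= 1)
  qx <- pmin(a * exp(b * (ages - min(ages))), 0.99)
  lt <- data.frame(age = as.integer(ages), qx = qx)
  attr(lt, "synthetic") <- TRUE
  class(lt) <- c("synthetic_life_table", "data.frame")
  lt
}

# Internal: look up q(age), clamping to the table's age range.
life_table_qx <- function(life_table, age) {
  age <- pmin(pmax(age, min(life_table$age)), max(life_table$age))
  life_table$qx[match(age, life_table$age)]
}

#' Generate a random small cohort model
#'
#' Valid random models (row-stochastic schedule, one absorbing death state
#' reachable from everywhere, random utilities and costs) used by the
#' path-enumeration equivalence tests. Deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_states Number of states including death (2 to 4).
#' @param n_cycles Horizon in cycles (1 to 5).
#' @return A [cohort_model()].
#' @export
random_small_model <- function(seed, n_states = 4, n_cycles = 5) {
  stopifnot(n_states >= 2, n_states <= 4, n_cycles >= 1, n_cycles <= 5)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  alive_n <- n_states - 1L
  sn <- c(paste0("s", seq_len(alive_n)), "dead")
  states <- c(
    lapply(seq_len(alive_n), function(i)
      health_state(sn[i], utility = stats::runif(1),
                   annual_cost = stats::runif(1, 0, 1000))),
    list(health_state("dead", 0, 0, absorbing = TRUE))
  )
  ent <- do.call(rbind, lapply(0:(n_cycles - 1L), function(cyc) {
    do.call(rbind, lapply(seq_len(alive_n), function(i) {
      # random exit mass (capped so a residual stay remains), spread over the
      # other states with a guaranteed positive slice to death
      targets <- setdiff(sn, sn[i])
      w <- stats::runif(length(targets))
      w <- w / sum(w)
      total_exit <- stats::runif(1, 0.1, 0.9)
      p <- w * total_exit
      p[targets == "dead"] <- p[targets == "dead"] + 0.01
      data.frame(from = sn[i], to = targets, cycle = cyc, prob = p)
    }))
  }))
  init <- stats::runif(alive_n)
  init <- c(init / sum(init), 0)
  cohort_model(
    states = states,
    schedule = transition_schedule(ent, carry_forward_cycle = n_cycles - 1L),
    initial_distribution = init,
    horizon_cycles = n_cycles,
    discount_rate = sample(c(0, 0.03, 0.05), 1),
    name = paste0("random-", seed)
  )
}

# Internal: canonical checksum string of the printed-table fixture, so a
# silently edited transcription is caught at load time.
table4_checksum <- function(cells) {
  canon <- paste(
    cells$state, cells$discount_rate, cells$sd_fraction,
    cells$value, cells$uncertainty, cells$evas, as.integer(cells$inconsistent),
    sep = ":", collapse = ";"
  )
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}

#' Load the transcribed printed results table
#'
#' The case study's printed per-complication results: cumulative value of the
#' additional state over 10,000 Monte-Carlo trials and, for each SD range
#' (\eqn{\pm}6.25\%, 12.5\%, 25\%, 50\% of the mean), the cumulative
#' uncertainty and EVAS, at a 3\% discount rate and undiscounted. One printed
#' cell (ESRD-dialysis, \eqn{\pm}25\%, discounted) violates the
#' value-minus-uncertainty identity by 10 and is flagged `inconsistent`; it
#' is excluded from identity checks rather than silently corrected.
#'
#' @param path Fixture path (default: the copy bundled with the package).
#' @return `data.frame` with columns `state`, `discount_rate`, `sd_fraction`,
#'   `value`, `uncertainty`, `evas`, `inconsistent`; attributes `n_trials`
#'   and `lambda`. The transcription is checksummed and an edited file
#'   errors on load.
#' @export
load_table4_fixture <- function(path = system.file("extdata", "table4.json",
                                                   package = "evas")) {
  if (!nzchar(path) || !file.exists(path)) stop("table4 fixture not found")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cells <- raw$cells
  cells$state <- as.character(cells$state)
  cells <- cells[order(cells$state, -cells$discount_rate, cells$sd_fraction), ]
  rownames(cells) <- NULL
  if (!identical(table4_checksum(cells), raw$checksum))
    stop("table4 fixture checksum mismatch: transcription has been altered")
  attr(cells, "n_trials") <- raw$n_trials
  attr(cells, "lambda") <- raw$lambda_yen_per_qaly
  cells
}

#' Check the value-minus-uncertainty identity on the printed table
#'
#' Recomputes EVAS from each unflagged cell's printed cumulative value and
#' uncertainty via [evas()] and compares with the printed EVAS, allowing the
#' \eqn{\pm}1 slack of integer-printed cells.
#'
#' @param fixture Output of [load_table4_fixture()].
#' @return `data.frame` of the checked cells with `evas_recomputed` and
#'   `identity_ok`; attribute `all_ok`.
#' @export
check_table4_identities <- function(fixture = load_table4_fixture()) {
  chk <- fixture[!fixture$inconsistent, , drop = FALSE]
  chk$evas_recomputed <- evas(chk$value, chk$uncertainty)
  chk$identity_ok <- abs(chk$evas_recomputed - chk$evas) <= 1
  attr(chk, "all_ok") <- all(chk$identity_ok)
  chk
}
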