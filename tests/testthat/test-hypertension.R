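# frozen clinical constants the bundled fixture must reproduce bit-exactly
CLINICAL_CONSTANTS <- c(
  stroke_incidence = 0.0049, chd_incidence = 0.00117,
  esrd_incidence = 0.00021,
  stroke_recurrence_year1 = 0.129, stroke_recurrence_later = 0.082,
  stroke_mortality_year1 = 0.207, stroke_mortality_year2 = 0.067,
  stroke_mortality_year3 = 0.058, stroke_mortality_year4 = 0.059,
  stroke_mortality_year5 = 0.059,
  chd_inhospital_mortality = 0.07, chd_annual_mortality = 0.0204,
  esrd_annual_mortality = 0.097
)

test_that("the parameters fixture carries the clinical constants bit-exactly", {
  p <- hypertension_parameters()
  tp <- unlist(p$transition_probabilities)
  expect_identical(tp[names(CLINICAL_CONSTANTS)], CLINICAL_CONSTANTS)
  expect_identical(p$utilities$stroke_mrs, c(1, 0.83, 0.67, 0.45, 0.24, 0.09))
  expect_identical(p$utilities$chd_year1, 0.68)
  expect_identical(p$utilities$chd_later, 0.72)
  expect_identical(p$utilities$esrd, 0.75)
  expect_identical(p$utilities$death, 0)
  expect_true(all(diff(p$utilities$stroke_mrs) < 0))
  expect_identical(p$cohort$start_age, 55L)
  expect_identical(p$cohort$horizon_years, 10L)
  expect_identical(p$lambda_yen_per_qaly, 5000000L)
  # synthetic stand-ins are flagged as such
  expect_true(p$costs_yen$synthetic)
  expect_true(p$life_table$synthetic)
  expect_true(p$mrs_discharge_distribution$synthetic)
  expect_true(p$wages$synthetic)
  expect_equal(sum(p$mrs_discharge_distribution$proportions), 1)
})

test_that("parameters survive a write/read round trip bit-exactly", {
  p <- hypertension_parameters()
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p, f, auto_unbox = TRUE, digits = NA)
  p2 <- hypertension_parameters(f)
  expect_identical(unlist(p2$transition_probabilities),
                   unlist(p$transition_probabilities))
  expect_equal(p2$utilities, p$utilities)
  expect_equal(p2$costs_yen, p$costs_yen)
})

test_that("base model structure: well, 30 stroke tunnel states, dead", {
  m <- build_base_model()
  expect_equal(length(m$state_names), 32L)
  expect_true("well" %in% m$state_names)
  expect_equal(sum(grepl("^stroke_mrs", m$state_names)), 30L)
  # tunnel wiring: year k advances to year k+1, year 5 is steady-state
  s <- m$states[[match("stroke_mrs3_y2", m$state_names)]]
  expect_equal(s$residual_to, "stroke_mrs3_y3")
  s5 <- m$states[[match("stroke_mrs3_y5", m$state_names)]]
  expect_equal(s5$residual_to, "stroke_mrs3_y5")
})

test_that("augmentations add exactly their complication sub-states", {
  m <- build_base_model()
  expect_equal(length(with_recurrence(m)$state_names), 32L)
  expect_setdiff_equal <- function(a, b, d) expect_equal(setdiff(a, b), d)
  expect_setdiff_equal(with_chd(m)$state_names, m$state_names,
                       c("chd_y1", "chd_later"))
  expect_setdiff_equal(with_esrd(m, "dialysis")$state_names, m$state_names,
                       "esrd")
  expect_setdiff_equal(with_esrd(m, "conservative")$state_names,
                       m$state_names, "esrd")
  # one complication at a time
  expect_error(with_chd(with_recurrence(m)), "one addition at a time")
})

test_that("zeroing a complication branch recovers the base model's trace", {
  m <- build_base_model()
  tr <- run_cohort(m)
  # rebuild augmented models with the complication entry probabilities at 0
  p <- hypertension_parameters()
  bA <- hypertension_builder("chd", p)
  trA <- run_cohort(bA(c(chd_incidence = 0)), validate = FALSE)
  expect_equal(trA$cum_qaly, tr$cum_qaly, tolerance = 1e-14)
  expect_equal(trA$cum_cost, tr$cum_cost, tolerance = 1e-14)
  bR <- hypertension_builder("recurrence", p)
  trR <- run_cohort(bR(c(stroke_recurrence_year1 = 0,
                         stroke_recurrence_later = 0)), validate = FALSE)
  expect_equal(trR$cum_qaly, tr$cum_qaly, tolerance = 1e-14)
  expect_equal(trR$cum_cost, tr$cum_cost, tolerance = 1e-14)
})

test_that("first-cycle event masses match the annual incidences", {
  m <- build_base_model()
  tr <- run_cohort(m)
  stroke_y1 <- grepl("^stroke_mrs[0-5]_y1$", m$state_names)
  expect_equal(sum(tr$occupancy[2, stroke_y1]), 0.0049)
  # CHD entrants equal the annual incidence, and their entry-year death
  # probability composes in-hospital mortality with background mortality
  mc <- with_chd(m)
  trc <- run_cohort(mc)
  expect_equal(unname(trc$occupancy[2, "chd_y1"]), 0.00117)
  p <- hypertension_parameters()
  lt <- generate_life_table(p$life_table$a, p$life_table$b, 55:64)
  q56 <- lt$qx[lt$age == 56]
  P1 <- transition_matrix_at(mc, 1)
  expect_equal(P1["chd_y1", "dead"], 0.07 + q56)
  expect_equal(unname(trc$occupancy[2, "chd_y1"]) * 0.07, 0.00117 * 0.07)
})

test_that("year-one death mass composes background and event mortality", {
  p <- hypertension_parameters()
  lt <- generate_life_table(p$life_table$a, p$life_table$b, 55:64)
  m <- build_base_model(p)
  tr <- run_cohort(m)
  q55 <- lt$qx[lt$age == 55]
  expect_equal(unname(tr$occupancy[2, "dead"]), q55)
  # second cycle: survivors' background deaths + year-1 stroke fatalities
  q56 <- lt$qx[lt$age == 56]
  expected <- q55 +
    (1 - q55 - 0.0049) * q56 +          # still well
    0.0049 * (0.207 + q56)              # first post-stroke year
  expect_equal(unname(tr$occupancy[3, "dead"]), expected, tolerance = 1e-12)
})

test_that("complications are pure harms under the default fixtures", {
  m <- build_base_model()
  tr <- run_cohort(m)
  for (aug in list(with_recurrence(m), with_chd(m),
                   with_esrd(m, "dialysis"), with_esrd(m, "conservative"))) {
    ta <- run_cohort(aug)
    expect_gte(ta$cum_cost, tr$cum_cost)
    expect_lte(ta$cum_qaly, tr$cum_qaly)
    expect_gte(value_of_additional_state(tr$cum_cost, ta$cum_cost,
                                         tr$cum_qaly, ta$cum_qaly), 0)
  }
})

test_that("work-lost cost sums wages from death age to retirement", {
  expect_equal(work_lost_cost(65, 4e6), 0)
  expect_equal(work_lost_cost(70, 4e6), 0)
  expect_equal(work_lost_cost(64, 4e6), 4e6)
  wages <- data.frame(age = 55:64, wage = c(rep(4e6, 5), rep(3e6, 5)))
  expect_equal(work_lost_cost(60, wages), 5 * 3e6)
  expect_equal(work_lost_cost(58, wages), 2 * 4e6 + 5 * 3e6)
  expect_equal(work_lost_cost(c(64, 65), wages), c(3e6, 0))
})

test_that("overall model mortality sits at life-table scale", {
  # sanity on the synthetic stand-ins: annualized mortality of the base
  # cohort should be within a factor ~2 of the mid-horizon background rate
  tr <- run_cohort(build_base_model())
  rate <- overall_mortality_rate(tr)
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.02)
})
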