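{
  "note": "Case-study constants for the grade-I hypertension cohort of 55-year-old men over a 10-year horizon. Transition probabilities and utilities are published clinical parameters; every block carrying 'synthetic': true is a documented stand-in (costs, wages, background life table, mRS discharge allocation) and no absolute cost reproduction is claimed.",
  "cohort": {
    "start_age": 55,
    "horizon_years": 10,
    "sex": "male"
  },
  "discount_rates": [0.03, 0.0],
  "lambda_yen_per_qaly": 5000000,
  "transition_probabilities": {
    "stroke_incidence": 0.0049,
    "chd_incidence": 0.00117,
    "esrd_incidence": 0.00021,
    "stroke_recurrence_year1": 0.129,
    "stroke_recurrence_later": 0.082,
    "stroke_mortality_year1": 0.207,
    "stroke_mortality_year2": 0.067,
    "stroke_mortality_year3": 0.058,
    "stroke_mortality_year4": 0.059,
    "stroke_mortality_year5": 0.059,
    "chd_inhospital_mortality": 0.07,
    "chd_annual_mortality": 0.0204,
    "esrd_annual_mortality": 0.097
  },
  "carry_forward": "stroke mortality and recurrence reuse the fifth-year value from year six onward; CHD annual mortality reuses its one-year value; recurrent strokes reuse the first-stroke mortality schedule",
  "utilities": {
    "healthy": 1.0,
    "death": 0.0,
    "stroke_mrs": [1.0, 0.83, 0.67, 0.45, 0.24, 0.09],
    "chd_year1": 0.68,
    "chd_later": 0.72,
    "esrd": 0.75
  },
  "costs_yen": {
    "synthetic": true,
    "stroke": {
      "acute_phase_hospital": 1500000,
      "recovery_phase_care": 2000000,
      "ambulant_treatment_annual": 200000,
      "nursing_care_annual_mrs2_5": 1200000
    },
    "chd": {
      "acute_phase_hospital": 3500000,
      "ambulant_treatment_annual": 400000
    },
    "esrd": {
      "dialysis_annual": 5000000,
      "conservative_annual": 600000,
      "ambulant_treatment_annual": 100000
    }
  },
  "wages": {
    "synthetic": true,
    "annual_wage_yen": 4000000,
    "retirement_age": 65
  },
  "life_table": {
    "synthetic": true,
    "a": 0.005,
    "b": 0.08,
    "age_min": 55,
    "age_max": 64
  },
  "mrs_discharge_distribution": {
    "synthetic": true,
    "proportions": [0.15, 0.25, 0.20, 0.15, 0.15, 0.10]
  }
}
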