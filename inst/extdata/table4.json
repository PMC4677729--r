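{
  "note": "Transcribed printed cumulative results of the grade-I hypertension case study: per complication and discount rate, the cumulative value of the additional state over 10,000 Monte-Carlo trials and the cumulative uncertainty / EVAS at each SD range. The flagged cell violates the value-minus-uncertainty identity as printed.",
  "n_trials": 10000,
  "lambda_yen_per_qaly": 5000000,
  "units": "QALY-equivalent, cumulative over 10,000 trials",
  "cells": [
    {
      "state": "chd",
      "discount_rate": 0.03,
      "sd_fraction": 0.0625,
      "value": 295,
      "uncertainty": 15,
      "evas": 280,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0.03,
      "sd_fraction": 0.125,
      "value": 295,
      "uncertainty": 30,
      "evas": 265,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0.03,
      "sd_fraction": 0.25,
      "value": 295,
      "uncertainty": 60,
      "evas": 235,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0.03,
      "sd_fraction": 0.5,
      "value": 295,
      "uncertainty": 117,
      "evas": 178,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0,
      "sd_fraction": 0.0625,
      "value": 356,
      "uncertainty": 18,
      "evas": 338,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0,
      "sd_fraction": 0.125,
      "value": 356,
      "uncertainty": 36,
      "evas": 320,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0,
      "sd_fraction": 0.25,
      "value": 356,
      "uncertainty": 72,
      "evas": 284,
      "inconsistent": false
    },
    {
      "state": "chd",
      "discount_rate": 0,
      "sd_fraction": 0.5,
      "value": 356,
      "uncertainty": 142,
      "evas": 214,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0.03,
      "sd_fraction": 0.0625,
      "value": 53,
      "uncertainty": 3,
      "evas": 50,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0.03,
      "sd_fraction": 0.125,
      "value": 53,
      "uncertainty": 6,
      "evas": 47,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0.03,
      "sd_fraction": 0.25,
      "value": 53,
      "uncertainty": 12,
      "evas": 41,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0.03,
      "sd_fraction": 0.5,
      "value": 53,
      "uncertainty": 23,
      "evas": 30,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0,
      "sd_fraction": 0.0625,
      "value": 65,
      "uncertainty": 4,
      "evas": 61,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0,
      "sd_fraction": 0.125,
      "value": 65,
      "uncertainty": 7,
      "evas": 58,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0,
      "sd_fraction": 0.25,
      "value": 65,
      "uncertainty": 15,
      "evas": 50,
      "inconsistent": false
    },
    {
      "state": "esrd_conservative",
      "discount_rate": 0,
      "sd_fraction": 0.5,
      "value": 65,
      "uncertainty": 28,
      "evas": 37,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0.03,
      "sd_fraction": 0.0625,
      "value": 137,
      "uncertainty": 7,
      "evas": 130,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0.03,
      "sd_fraction": 0.125,
      "value": 137,
      "uncertainty": 14,
      "evas": 123,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0.03,
      "sd_fraction": 0.25,
      "value": 137,
      "uncertainty": 27,
      "evas": 120,
      "inconsistent": true
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0.03,
      "sd_fraction": 0.5,
      "value": 137,
      "uncertainty": 53,
      "evas": 84,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0,
      "sd_fraction": 0.0625,
      "value": 167,
      "uncertainty": 8,
      "evas": 159,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0,
      "sd_fraction": 0.125,
      "value": 167,
      "uncertainty": 16,
      "evas": 151,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0,
      "sd_fraction": 0.25,
      "value": 167,
      "uncertainty": 33,
      "evas": 134,
      "inconsistent": false
    },
    {
      "state": "esrd_dialysis",
      "discount_rate": 0,
      "sd_fraction": 0.5,
      "value": 167,
      "uncertainty": 64,
      "evas": 103,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0.03,
      "sd_fraction": 0.0625,
      "value": 116,
      "uncertainty": 7,
      "evas": 109,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0.03,
      "sd_fraction": 0.125,
      "value": 116,
      "uncertainty": 13,
      "evas": 102,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0.03,
      "sd_fraction": 0.25,
      "value": 116,
      "uncertainty": 26,
      "evas": 89,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0.03,
      "sd_fraction": 0.5,
      "value": 116,
      "uncertainty": 52,
      "evas": 64,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0,
      "sd_fraction": 0.0625,
      "value": 140,
      "uncertainty": 8,
      "evas": 132,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0,
      "sd_fraction": 0.125,
      "value": 140,
      "uncertainty": 16,
      "evas": 124,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0,
      "sd_fraction": 0.25,
      "value": 140,
      "uncertainty": 32,
      "evas": 108,
      "inconsistent": false
    },
    {
      "state": "recurrence",
      "discount_rate": 0,
      "sd_fraction": 0.5,
      "value": 140,
      "uncertainty": 60,
      "evas": 80,
      "inconsistent": false
    }
  ],
  "checksum": "c27175a6703bd2c56c6f34c507b598ea"
}
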