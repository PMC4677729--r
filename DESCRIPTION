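Package: evas
Title: Expected Value of an Additional State in Markov Cohort Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much a candidate complication state contributes
    to a Markov cohort disease model. The value of an additional state is the
    net-benefit change between the basic model and the augmented model,
    converted to a single QALY-equivalent scale with a willingness-to-pay
    threshold; its uncertainty is the summed absolute deviation of that value
    over Monte-Carlo draws of beta-distributed transition probabilities; the
    expected value of the additional state (EVAS) is value minus uncertainty
    and is used to rank candidate states. Ships a discrete-time Markov cohort
    engine with tunnel states, time-varying transitions and discounting, a
    probabilistic sensitivity analysis layer, and a runnable grade-I
    hypertension case study (stroke base model plus stroke recurrence,
    coronary heart disease and end-stage renal disease augmentations) built
    from published clinical parameters together with clearly labelled
    synthetic cost, wage and life-table stand-ins.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
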