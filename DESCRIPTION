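Package: twincua
Title: Cost-Utility Analysis of Universal Cervical-Length Screening in Twin Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-analytic cost-utility model comparing no screening,
    one-step and two-step universal cervical-length screening strategies for
    dichorionic twin pregnancies. Couples a screening/treatment decision tree
    (vaginal progesterone for cervical length <= 25 mm, cerclage plus
    progesterone for <= 15 mm) to a two-state annual-cycle cohort state
    transition model over ages 0-100, and computes discounted lifetime costs
    (2023 CAD) and quality-adjusted life years, incremental
    cost-effectiveness ratios, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and one- and two-way
    deterministic sensitivity analysis with threshold location. Includes a
    synthetic parameter generator and a per-individual microsimulation oracle
    for model verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
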