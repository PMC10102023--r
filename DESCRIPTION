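Package: todclock
Title: Time-of-Death Estimation from Cardiac Clock-Gene Expression Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for biological-clock-based estimation of the time of
    death from the antiphase circadian expression of BMAL1 and NR1D1 in
    postmortem heart tissue. Implements the NR1D1/BMAL1 and BMAL1/NR1D1
    expression ratios and their assignment to four 6-hour time domains,
    per-domain summary statistics with Scheffe post-hoc multiple
    comparisons and unpaired t-tests, subgroup analyses (sex, age group,
    postmortem-interval group, cause of death, brain-injury course), and a
    threshold-based classifier mapping ratio values to predicted
    clock-time windows. A seeded synthetic-cohort generator with a
    log-scale cosinor model of the two genes stands in for restricted
    autopsy data and drives end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
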