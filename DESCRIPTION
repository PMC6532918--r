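Package: stratscreen
Title: Micro-Simulation of Risk-Stratified Breast Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time micro-simulation of breast cancer screening in a
    population of women aged 50 and over, with routine (annual, biennial,
    triennial) and relative-risk-stratified screening strategies under full
    and reduced adherence. Screening benefit acts through the stage
    distribution at diagnosis; harms include false-positive work-up,
    unnecessary biopsies and overdiagnosis. Includes an economic evaluation
    layer from the payer perspective: discounted costs and quality-adjusted
    life years, incremental comparisons against a no-screening comparator,
    incremental cost-effectiveness ratios, efficiency frontiers with
    extended dominance, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, expected value of perfect
    information, and one-way tornado analyses. Common random numbers are
    used across strategies so that incremental results are matched at the
    individual level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
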