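Package: pancscreen
Title: Microsimulation of Pancreatic Cancer Screening in High-Risk Individuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level microsimulation of pancreatic cancer natural
    history and screening in high-risk populations. Simulates life histories
    through graded preinvasive stages (low-, intermediate- and high-grade
    dysplasia) and preclinical TNM stages under two contrasting progression
    hypotheses (progressive-only versus indolent-included), overlays
    EUS/MRI-like screening with six-monthly surveillance, resection and
    palliative management, and reports screening effectiveness: mortality
    reduction, number needed to screen/surveil/treat, life-years gained and
    interval-cancer rates, together with a sensitivity-analysis grid over
    risk level, test characteristics and surgical mortality. Paired arms
    share common random numbers via counter-based per-person streams, and a
    compiled engine is cross-checked against an interpreted reference
    implementation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
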