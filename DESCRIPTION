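Package: granrisk
Title: Size-Resolved, Bioaccessibility-Adjusted Health Risk Assessment
    for Soil Heavy Metals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing children's oral exposure to soil heavy
    metals when both contamination and exposure are particle-size
    selective.  Represents laser-diffraction particle-size distributions
    of hand-loaded dust and soil, derives normalized size-fraction
    exposure weights and fine-particle enrichment ratios, computes
    gastric/intestinal bioaccessibility from physiologically based
    extraction test (PBET) measurements with the usual analytical QC
    rules (blank deduction, LOD/sqrt(2) substitution, recovery, RSD),
    builds per-fraction average daily doses, hazard quotients and the
    hazard index with contribution decompositions, and propagates input
    uncertainty through a seeded Monte Carlo layer with
    Anderson-Darling-based distribution selection.  A synthetic-data
    generator produces study-like soil panels, PBET extracts and
    children's hand-dust size distributions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    tidyr,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
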