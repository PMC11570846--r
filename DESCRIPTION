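Package: brachyaudit
Title: Postal Dosimetry Audit Toolkit for HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computation for postal dosimetry audits of high
    dose rate (HDR) brachytherapy sources. Implements the AAPM TG-43
    dose formalism for point and line sources, the standardized
    two-catheter audit phantom plan with a uniform dwell-time solve to a
    2 Gy prescription, estimation and combination of scatter,
    material-equivalence and beam-quality correction factors from
    paired radiophotoluminescent dosimeter (RPLD) measurement sets,
    GUM-style quadrature uncertainty budgeting, radiochromic film track
    analysis for source-position verification, multicentre audit cohort
    aggregation, and seeded synthetic generators for every input so the
    whole chain can be exercised without physical data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
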