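Package: aquarisk
Title: Groundwater Quality Indices and Human Health-Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Assessment of groundwater suitability for drinking and of the
    ecological and human health risks posed by potentially toxic elements
    (Fe, Mn, Cr, Pb). Implements charge-balance quality control and
    milliequivalent conversion, hydrochemical facies and process
    classification (Piper, Gibbs, Sulin, chloro-alkaline indices, Davies
    activity based mineral saturation indices), an integrated-weight water
    quality index combining entropy and CRITIC objective weights,
    heavy-metal pollution indices (HPI, HMI) and the Hakanson ecological
    risk index, deterministic USEPA chronic-daily-intake exposure risk
    (HQ, HI, CR) for adult and child receptors by oral and dermal routes,
    and Monte Carlo propagation of concentration and exposure-factor
    uncertainty. A seeded synthetic-sample generator reproduces the
    statistical structure of a 45-well survey of a deep desert aquifer so
    the full pipeline is testable without the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
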