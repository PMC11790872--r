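Package: coastrisk
Title: Environmental and Human-Health Risk Assessment for Coastal Seawater
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for contaminant risk assessment in coastal
    seawater surveys. Aggregates polycyclic aromatic hydrocarbon (PAH)
    concentrations and computes diagnostic source ratios and risk quotients
    against negligible and maximum-permissible quality values; computes the
    heavy-metal pollution index (HPI), metal index (MI) and potential
    ecological risk index (RI) with their classification scales; runs the
    USEPA deterministic health-risk chain (chronic daily intake, hazard
    quotient, hazard index and carcinogenic risk) for oral and dermal routes
    in adults and children; propagates input uncertainty through the same
    chain with a seeded Monte Carlo engine; and identifies pollution sources
    with Ward hierarchical clustering and principal component analysis with
    KMO and Bartlett adequacy tests. Includes a synthetic multi-site survey
    generator with correlated lognormal analytes, hotspot samples and
    detection-limit censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
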