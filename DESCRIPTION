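Package: relkin
Title: Release Kinetics Modelling for Sustained-Release Microparticles
Version: 0.1.0
Authors@R: person("relkin", "maintainers", email = "relkin@example.org", role = c("aut", "cre"))
Description: Tools for in vitro drug-release kinetics of sustained-release
    polymeric microparticles. Builds cumulative release profiles from
    sample-and-replace dissolution assays, quantifies burst release and
    interval release rates, fits and ranks kinetic release models
    (zero/first order, Higuchi, Korsmeyer-Peppas, Baker-Lonsdale, Weibull,
    and the biphasic Gallagher-Corrigan model with the Gorrasi burst
    correction) by adjusted R-squared, compares dissolution profiles with
    the f2 similarity factor, and simulates replicate-level release assays
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
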