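Package: benthoscape
Title: Rule-Based Habitat Classification and Predictive Biotope Mapping for
    Baltic Seascapes
Version: 0.1.0
Authors@R:
    person("Benthoscape", "Developers", email = "benthoscape@example.org",
           role = c("aut", "cre"))
Description: Tools for grid-based mapping of benthic habitats and biotopes in
    brackish shelf seas such as the Baltic. Classifies grain-size compositions
    into BSH/Folk and EUNIS substrate categories, bins boulder detections into
    density classes and applies geogenic hard-substrate rules, labels
    ground-truth stations with HELCOM HUB communities via biomass and cover
    dominance criteria, fits out-of-bag-tuned random-forest models predicting
    community classes over a grid, and composes broad habitat type (BHT),
    other habitat type (OHT) and HELCOM HUB map layers with area accounting.
    Includes a seeded synthetic seascape generator with a known
    community-generating rule so the whole pipeline is testable end to end
    without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
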