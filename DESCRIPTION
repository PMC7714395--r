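Package: rubiflux
Title: Rubisco-Coupled Strain Design and 13C Flux Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing rubisco-dependent bacterial
    strains. Implements flux balance analysis and flux variability analysis on
    small stoichiometric models, an OptSlope-style screen for knockouts whose
    growth is coupled to a heterologous rubisco/phosphoribulokinase detour,
    rubisco carboxylation and oxygenation kinetics under competitive O2
    inhibition, inference of the rubisco-derived fraction of 3-phosphoglycerate
    synthesis from 13C isotopologue distributions and serine MRM fragment data,
    and bootstrap effect-size statistics on growth curves. Includes seeded
    generators for a toy rubisco-coupled network, labeling data with known
    ground truth, and replicate growth curves, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
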