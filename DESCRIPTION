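Package: wetlandDiv
Title: Waterbird Community Diversity and Wetland Habitat Projection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing waterbird community diversity in restored
    wetlands and projecting habitat change. Implements Berger-Parker dominance
    classification, Shannon-Wiener, Pielou, Simpson and G-F (genus-family)
    taxonomic diversity indices over taxonomic checklists and survey-derived
    community matrices; habitat, guild and threatened-species summaries; guild
    response curves along a water-level gradient with optimal-level detection;
    and a Markov land-cover transition model with scenario modification,
    quota-based spatial allocation and Cohen's kappa accuracy assessment. A
    synthetic-data generator with known ground truth supports parameter-recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, vegan, e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
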