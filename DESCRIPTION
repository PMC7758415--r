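Package: tomatoflavor
Title: Flavor Evaluation of Tomato Accessions from Volatile and Taste Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for evaluating tomato fruit flavor
    from gas chromatography-mass spectrometry (GC-MS) volatile profiles,
    taste-compound chemistry, and hedonic sensory panels. Implements Kovats
    retention-index computation against an n-alkane ladder, identification
    filtering on spectral match scores, internal-standard relative
    quantification with calibration-curve correction, odor activity values
    (OAV) and odor-category aggregation, sugar-acid taste metrics, TOPSIS
    multi-criteria flavor ranking with benefit/cost criteria, and
    compound-sensory association statistics. Ships the printed reference
    tables of a 71-accession tomato panel as plain-text fixtures, and a
    synthetic-data generator that forward-simulates GC-MS runs and panel
    scores with known ground truth so every stage is testable end to end.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyselect,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
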