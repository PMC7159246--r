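Package: tendonmech
Title: Mechanical and Crosslink-Distribution Analysis for Ex Vivo Tendon Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo tendon mechanical-augmentation
    experiments. Extracts ultimate point, max-gradient stiffness, elastic
    modulus, work to failure and cyclic stress relaxation from raw tensile-test
    force-displacement traces; compares treatment groups with Kruskal-Wallis
    and Dunn's rank tests; models the spatial distribution of crosslink-induced
    fluorescence and absorption with dummy-variable regression; and estimates
    intratendinous crosslinker concentration by inverting a log-linear
    calibration curve. A synthetic-data generator emulating the loading
    protocol and assay design provides a parameter-recovery test surface for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
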