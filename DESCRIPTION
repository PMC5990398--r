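Package: sevcargo
Title: Selective Secretion Analysis of Small Extracellular Vesicle miRNA Cargo
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality control, normalization and donor-blocked differential
    analysis for paired vesicular qPCR-panel (Ct) and intracellular
    small-RNA-seq (count) miRNA data from senescence secretion experiments,
    together with the dual rank-difference / abundance-ratio scoring that
    classifies miRNAs as selectively secreted into, or retained from, small
    extracellular vesicles. Includes spike-in robustness checks, global-mean
    (MCR) and per-cell Ct normalization, TPM filtering, an empirical-Bayes
    moderated linear-model test with Benjamini-Hochberg FDR, nanoparticle
    tracking summaries, and a synthetic-data generator with planted ground
    truth so the whole pipeline is testable without external data.
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
    limma,
    withr
Config/testthat/edition: 3
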