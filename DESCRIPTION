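Package: partpool
Title: Modular Rule-Based Design and Simulation of Eukaryotic Gene Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compiles declarative descriptions of synthetic eukaryotic gene
    circuits -- promoters with combinatorial operator occupancy, coding
    regions with spliceosome processing, riboswitch- and RNA-interference-
    regulated cytoplasmic mRNA pools, siRNA genes, and pools of the five
    signal carriers (RNA polymerase, ribosome, transcription factor, small
    RNA, chemical) -- into full mass-action reaction networks via a generic
    rule-based expansion engine. Part and pool models are wired across
    nucleus and cytoplasm compartments through typed flux terminals,
    simulated deterministically as ODE systems, and evaluated against
    Boolean truth tables. Includes fixture builders for example logic
    evaluator circuits, an SBML Level 3 exporter, a plain-text circuit
    description format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
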