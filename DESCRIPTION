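Package: mucaflux
Title: Constraint-Based Analysis of Alginate Production in Pseudomonas fluorescens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stoichiometric analysis of alginate-producing
    Pseudomonas fluorescens SBW25. Provides a curated core model of central
    carbon and alginate metabolism with proton-explicit respiration, flux
    balance analysis with switchable terminal-oxidase (P/O ratio) modes and
    maintenance ATP, theoretical biomass and alginate yield calculators,
    chemostat steady-state physiology arithmetic (yields, carbon balances,
    alginate efficiencies), microarray-style expression preprocessing
    (quantile normalization, ANOVA screening, PCA, gene-to-reaction mapping
    through GPR rules), hit-and-run random sampling of constrained flux
    spaces with transcriptional-regulation evidence scoring, reaction-level
    comparison of metabolic models, and synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
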