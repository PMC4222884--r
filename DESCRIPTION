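Package: acetoflux
Title: Constraint-Based Modeling of Acetogenic Metabolism in Clostridium ljungdahlii
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Flux balance analysis engine and a curated core reconstruction of
    the acetogen Clostridium ljungdahlii. Implements stoichiometric model
    construction with elemental and charge balance auditing, gene-protein-
    reaction logic, linear-programming flux balance analysis with flux
    variability and parsimonious variants, single-gene deletion screens, and
    SMILEY-style gap-filling. Ships an executable core model of the
    Wood-Ljungdahl pathway, flavin-based electron bifurcation (Nfn, bifurcating
    hydrogenase and methylene-THF reductase), Rnf/ATP-synthase energy
    conservation, fermentation branches and the nitrate reduction pathway,
    together with scenario analyses of reducing-equivalent demand, ATP yields
    at the Rnf complex, acetate-kinase knockout phenotypes and nitrate as an
    electron sink.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'model-build.R'
    'balance.R'
    'lp-solver.R'
    'fba.R'
    'core-model.R'
    'gapfill.R'
    'gpr.R'
    'io.R'
    'scenarios.R'
    'synthetic.R'
    'utils-formula.R'
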