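Package: npflux
Title: Natural-Product Prioritisation on Constraint-Based Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A four-step in silico workflow for prioritising natural products
    (or any compound set with partial target annotation) on constraint-based
    metabolic models. The package builds flux-consistent, medium-constrained,
    expression-driven context-specific models from a genome-scale
    reconstruction; simulates single, combination and per-gene target
    knockouts with growth-ratio readouts via flux balance analysis; scores
    treated models against a control by reaction-content Jaccard
    dissimilarity and by flux-range overlap similarity computed from flux
    variability analysis; quantifies per-pathway presence-rate alteration;
    and aggregates the four evidence streams into a candidate table with a
    configurable selection rule. A seeded toy-network generator with planted
    signals makes every stage testable without external data, and a small
    command-line front end exposes the stages as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Matrix, xml2, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Metabolomics, Network, Software, SystemsBiology
RoxygenNote: 7.3.3
Collate:
    'lp.R'
    'gpr.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'model-build.R'
    'io-json.R'
    'io-sbml.R'
    'io-tables.R'
    'medium.R'
    'fba.R'
    'deletion.R'
    'consistency.R'
    'context.R'
    'scoring.R'
    'pathways.R'
    'selection.R'
    'synthetic.R'
    'cli.R'
    'npflux-package.R'
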