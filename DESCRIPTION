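Package: secflux
Title: Secretion Flux Maps and Metabolic Feedback Inhibition Analysis for
    Gut-Symbiont Fermentation Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of metabolite secretion by anaerobic gut symbionts
    (Bacteroides thetaiotaomicron) grown on glucose: carbon-normalized
    secretion flux maps with an inferred CO2 term, quantification of
    acetate/formate feedback inhibition via fold-variance regression
    against an additive null model (suppression coefficients),
    discrimination among five theoretical secretion-response scenarios,
    doubling-time and dose-response growth analysis, and a self-contained
    flux-balance-analysis engine on a curated central-carbon network
    reproducing the high/low-glucose x acetate/formate in-silico
    experiment grid. Includes a seeded synthetic-data generator emulating
    the 5x5-replicate acetate titration design so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Metabolomics, Software, SystemsBiology, GraphAndNetwork
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'utils.R'
    'AllGenerics.R'
    'SecretionExperiment.R'
    'fba-solve.R'
    'fba.R'
    'fluxmap.R'
    'growth.R'
    'inhibition.R'
    'io.R'
    'network.R'
    'pipeline.R'
    'registry.R'
    'scenarios.R'
    'simplex.R'
    'synthetic.R'
    'validation.R'
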