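Package: MetaboRain
Title: Rain Plots and Companion Visualizations for Metabolite-Phenotype
    Association Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns a metabolite abundance matrix and a phenotype table into
    a complete grid of multi-outcome association results and renders them as
    rain plots (bubble heatmaps whose fill encodes effect size and direction
    and whose droplet radius encodes statistical significance), faceted
    Manhattan plots ordered by mass-to-charge ratio, paired beta/P heatmaps,
    and bar-and-scatter plots. Includes the canonical LC-MS preprocessing
    chain (quarter-minimum imputation, natural-log transform, per-metabolite
    standardization), from-first-principles linear and logistic regression
    across a clinically ordered outcome panel, three reproducible row
    orderings (P value, m/z, hierarchical clustering with deterministic leaf
    order), a synthetic-study generator with planted effects, and a
    configuration-driven end-to-end pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grid,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'core_io.R'
    'preprocess.R'
    'association.R'
    'ordering.R'
    'plotmodel.R'
    'render.R'
    'synth_fixtures.R'
    'pipeline.R'
    'utils.R'
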