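# MetaboRain

Multi-outcome association analysis and visualization for metabolomics
studies. Given a samples × metabolites abundance matrix (LC-MS feature
intensities, with missing values), an m/z annotation table, and a
phenotype table of clinical traits, MetaboRain computes the complete
metabolites × outcomes grid of regression results and renders it as:

* **rain plots** — one circle per (metabolite, outcome) cell; fill color
  encodes the signed effect size *β* (per 1 SD of log abundance; log-odds
  for binary outcomes) on a symmetric diverging scale, droplet radius
  encodes −log10(*P*) up to a Bonferroni-level cap — magnitude,
  direction, and significance for a whole panel in one figure;
* **faceted Manhattan plots** — −log10(*P*) against m/z, one facet per
  outcome with a shared y axis and an α/m threshold line;
* **paired heatmaps** — aligned *β* and −log10(*P*) matrices;
* **bar-and-scatter plots** — signed *β* bars with aligned *P*-value dots
  for one outcome.

Under the hood it implements the standard metabolomics preprocessing
chain (missing intensities imputed at 0.25 × the per-metabolite observed
minimum, natural-log transform, per-metabolite standardization),
from-first-principles OLS and IRLS-logistic fits of
`outcome ~ metabolite + covariates` over a clinically ordered
eight-outcome panel, three reproducible row orderings (summary *P* value,
m/z, hierarchical clustering of β profiles with a deterministic leaf
order), top-k selection (default 50), a seeded synthetic-study generator
with planted effects, and a YAML-driven end-to-end pipeline. Data live in
Bioconductor containers: studies extend `SummarizedExperiment`
(metabolites × samples), results are S4 objects with enforced invariants.

## Worked example

```r
library(MetaboRain)

design <- SyntheticDesign(
  nSamples = 200, nMetabolites = 50, seed = 8,
  plantedEffects = data.frame(
    metabolite = c("met_001", "met_001", "met_002"),
    outcome    = c("age", "framingham_risk_score", "bmi"),
    beta       = c(0.5, 0.4, -0.45)))
study <- preprocessStudy(generateStudy(design))
grid  <- buildGrid(study, skipFailures = TRUE)
grid
#> AssociationGrid: 50 metabolites x 8 outcomes (400 records)
#>   outcomes: age, female_sex, bmi, metabolic_syndrome, prevalent_diabetes,
#>             incident_diabetes, framingham_risk_score, incident_hard_cvd

rec <- gridRecords(grid)
subset(rec, metabolite_id %in% c("met_001", "met_002") &
            outcome %in% c("age", "bmi"))[, 1:5]
#>    metabolite_id outcome    beta     se        p
#> 1        met_001     age  0.4485 0.0769 2.21e-08
#> 3        met_001     bmi  0.0213 0.0859 8.04e-01
#> 9        met_002     age -0.1166 0.0830 1.62e-01
#> 11       met_002     bmi -0.2485 0.0779 1.65e-03
```

The planted age effect of metabolite 1 (β = 0.5) is recovered at 0.45 ±
0.08 — slightly attenuated because the 5% missing intensities are imputed
at the quarter-minimum, which inflates the column SD (see the methods
vignette); its bmi association is null, as planted. Metabolite 2 shows
the planted negative bmi effect and nothing on age. Rendering the top 20
metabolites, cluster-ordered:

```r
top   <- selectTopK(grid, k = 20)
model <- buildRainPlotModel(top, rowOrder = orderByCluster(top))
model
#> RainPlotModel: 20 metabolites x 8 outcomes, 160 droplets
#>   fill in [-0.499, 0.499]; radius 0.08-0.45 (radius mode),
#>   cap -log10(P) = 2.6
renderPlot(model, "rainplot.svg")   # one <circle> per droplet, countable
```

`buildManhattanModel()`, `buildPairedHeatmapModel()` and
`buildBarScatterModel()` work the same way, and `runPipeline(config)`
(or the CLI below) runs matrix → grid → all four figures in one call with
a manifest of versions, seed, and checksums.

## Command line

A thin Rscript front end ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rainplot.R", package = "MetaboRain"))')
Rscript $CLI synth      --design design.yaml --out-prefix study_
Rscript $CLI preprocess --abundance study_abundance.csv --out std.csv --report report.json
Rscript $CLI associate  --abundance std.csv --phenotypes study_phenotypes.csv \
                        --annotations study_annotations.csv --out grid.csv
Rscript $CLI plot rain  --grid grid.csv --order cluster --top-k 50 --out fig.svg
Rscript $CLI pipeline   --config run.yaml
```

Exit codes: 0 success, 2 validation error, 1 runtime error.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the desk-scale synthetic study from the given seed and runs
the installed package's complete pipeline — preprocessing, all 4000
regression fits of the 500 × 8 grid, top-50 selection, and all four
renderers — writing its JSON report to `--out`.
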