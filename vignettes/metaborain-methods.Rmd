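---
title: "Models, encodings, and design choices in MetaboRain"
author: "MetaboRain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, encodings, and design choices in MetaboRain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboRain)
```

# The problem

Metabolome-wide association studies relate hundreds of LC-MS metabolite
features to a panel of clinical traits at once. Each (metabolite, outcome)
pair yields three numbers — an effect estimate, its standard error, and a
P value — and the analytic challenge is mostly one of display: how to show
magnitude, direction, and significance for, say, 500 metabolites times 8
outcomes without losing between-metabolite and between-outcome patterns.
MetaboRain computes the full association grid from a raw abundance matrix
and renders it four ways: a *rain plot* (one circle per cell; fill color =
signed effect size, droplet radius = significance), a faceted Manhattan
plot, paired beta/P heatmaps, and per-outcome bar-and-scatter plots. All
encoding rules live in renderer-independent model objects so they can be
tested without parsing images.

# Preprocessing

Three steps, in a fixed order:

1. **Quarter-minimum imputation.** A missing LC-MS feature intensity most
   plausibly reflects a value below the observed range, so each missing
   entry is replaced by 0.25 × the minimum *observed* value of that
   metabolite, computed per metabolite across all samples. Columns with no
   observed value, or with a non-positive minimum, are errors.
2. **Natural-log transform**, elementwise, requiring strictly positive
   values (guaranteed after imputation of positive intensities).
3. **Per-metabolite standardization** to mean 0, SD 1, so that effect
   estimates are "per 1 SD of log abundance" and comparable across
   metabolites. The default SD uses the sample (n − 1) denominator — the
   convention of the statistical software families used in epidemiology —
   with a `denominator = "n"` switch for the population form.

The pipeline is scale-equivariant (multiplying a raw column by any c > 0
leaves the z-scores unchanged, because the log turns scaling into a shift
that centering removes) and rank-preserving within each metabolite; both
are enforced by property tests.

A consequence worth knowing: under heavy missingness the imputation
constant is far in the lower tail of a log-normal intensity column, so the
column SD inflates and true effect sizes attenuate. At 15% missingness the
attenuation can approach a factor of two. The package reports per-column
missing fractions and the count above a 10% threshold
(`PreprocessReport`); by default metabolites are imputed, never dropped,
but an explicit `maxMissingFrac` cutoff is available. Whether
standardization should precede or follow per-model sample exclusions is
not determined by the method itself; MetaboRain standardizes once on the
full matrix, which keeps a single interpretable unit per metabolite across
the whole panel.

# The association grid

For each outcome model in the panel and each metabolite, the package fits
`outcome ~ intercept + metabolite + covariates`, with the metabolite as the
exposure. Continuous outcomes use ordinary least squares solved on the
normal equations by Cholesky factorization, classical homoskedastic
standard errors, and t-based two-sided P values on n − k degrees of
freedom. Binary outcomes use maximum-likelihood logistic regression via
iteratively reweighted least squares (convergence: maximum absolute
coefficient change < 1e-8 within 100 iterations), observed-information
standard errors, and Wald P values. Fits that fail to converge — including
(quasi-)complete separation, which IRLS cannot distinguish from slow
convergence — keep their place in the grid as flagged records with missing
estimates, and plots exclude them with a warning. The fitters are written
from first principles; `lm()`/`glm()` and a direct numerical maximizer of
the log-likelihood serve as independent oracles in the test suite only.

The packaged default panel (`framinghamPanel()`) contains eight models in
a fixed clinical display order: age, female sex, body mass index,
metabolic syndrome, prevalent diabetes, incident diabetes, Framingham Risk
Score, and incident hard cardiovascular disease. Age, BMI and the risk
score are continuous; the other five are binary. Design choices that the
underlying method leaves open, resolved here as documented defaults:

* **Covariates.** Every model adjusts for age and female sex, except the
  age and female-sex models, which adjust for each other. This is the
  conventional minimal adjustment set in cardiometabolic epidemiology and
  is fully configurable per `ModelSpec`.
* **Incident outcomes** are modeled as logistic regressions on the event
  indicator. Time-to-event (Cox) modeling is out of scope; the
  `family` field leaves room for extension.
* **Complete cases per model**, not globally: a sample missing one
  outcome still contributes to every other model, maximizing n per model.
* **Classical standard errors**, not robust ones — the simplest
  defensible default.

The grid object (`AssociationGrid`) enforces completeness — exactly one
record per (metabolite, outcome) pair — P values in (0, 1], positive
standard errors, and panel-ordered outcomes. It serializes to a tidy
long-format CSV at 17 significant digits, which round-trips doubles
bit-identically; display order travels in the panel's `displayIndex`, never
in file column order.

# Row orderings

Three reproducible orderings, matching how rain plots are usually read:

* **By P value** — ascending summary P. With eight P values per
  metabolite, "the" P value is ambiguous; the default summary is the
  minimum across outcomes (a metabolite ranks by its strongest
  association), with an anchor-outcome mode to rank by one named outcome
  instead. Sorts are stable: ties keep input order.
* **By m/z** — ascending mass-to-charge, the same coordinate that orders
  the Manhattan x axis.
* **By hierarchical clustering** — agglomerative clustering of the
  per-metabolite beta vectors across outcomes, Euclidean distance and
  average linkage by default (both configurable; Ward and correlation
  distance available). Clustering acts on betas rather than P values
  because the point of the clustered ordering is to group metabolites by
  *effect profile* — significance is carried by droplet size regardless.
  Dendrogram leaf order is made deterministic by a fixed child-ordering
  rule: at each merge, the subtree containing the lexicographically
  smallest metabolite id comes first. Because ids travel with their rows,
  this rule makes the leaf sequence invariant to input row order whenever
  merge distances are distinct — a property a merge-index-based tie-break
  would not have — and it is what makes clustered figures reproducible.

`selectTopK()` (default k = 50, the conventional display size) keeps the k
metabolites with the smallest summary P under the same summary rule, so
the selected set always equals the first k of the full P-value ordering.

# Visual encodings

All four builders take a complete grid and emit a model object whose
invariants are machine-checkable.

**Rain plot.** One circle per cell. Fill value = beta clipped to symmetric
limits ±L (default L = max |beta| over the displayed grid, so the diverging
scale midpoint is exactly zero and ±b are equidistant from it). Radius
interpolates between `radiusRange` (default 0.08–0.45 cell units) as
−log10(P) grows toward a cap. The cap defaults to the Bonferroni threshold
−log10(0.05 / m) over the m displayed metabolites, floored at 2: beyond
study-wide significance, larger droplets would only compress the rest of
the scale. Two size modes are offered because the choice changes
perception: `"radius"` (default) makes the radius proportional to capped
significance, `"area"` makes the circle area proportional. Only
monotonicity of size in −log10(P) is treated as normative; equal P implies
equal radius in both modes. Reordering rows moves cells but never changes
any cell's encoded values.

**Faceted Manhattan plot.** One facet per outcome in panel order, shared y
axis (the shared axis is what makes between-outcome significance
differences visible), x = actual m/z value (not rank), y = −log10(P),
point direction from the beta sign. The model deliberately carries *no*
magnitude channel — that omission is the documented weakness of Manhattan
plots, and the introspection tests assert it. The threshold line defaults
to Bonferroni α/m, configurable to a raw α.

**Paired heatmaps.** Two matrices constrained to identical row/column
orders: betas on the symmetric diverging scale, capped −log10(P) on a
sequential scale.

**Bar-and-scatter.** For one outcome: signed bars for betas, aligned dots
for −log10(P).

−log10(P) is capped at 300 by default so double-underflow P values remain
drawable. Color maps are diverging blue–white–red for betas and a
light-to-dark sequential blue for significance, chosen for
color-vision-deficiency safety.

Rendering is deliberately thin: each model lays out a scene of primitives,
written either as literal SVG elements (every droplet is one `<circle>`,
so figures are countable by tests) or drawn identically through `grid` for
PNG/PDF.

# The synthetic-study generator

`generateStudy()` draws log abundances as Gaussians (per-metabolite
location in log(1e4)–log(1e6), scale 0.3–0.8, exponentiated to raw
intensities), builds outcomes from planted (metabolite, outcome, beta)
effects applied to the *standardized* log abundances — continuous outcomes
add Gaussian noise (`noiseSd`, default 1); binary outcomes pass the same
linear predictor through a logistic link around a baseline prevalence —
and finally injects missingness per metabolite. All draws come from one
seeded stream consumed in a fixed order (m/z, metabolite parameters,
abundances metabolite by metabolite, missingness masks, outcome noise in
panel order), so studies are reproducible byte for byte.

`fixtureCohortShape()` is the desk-scale default mirroring a large
population-based lipidomics study: 500 metabolites × 300 samples, m/z in
the 225–650 negative-mode acquisition window, the eight-outcome panel with
plausible baseline prevalences (sex 0.5, metabolic syndrome 0.3, prevalent
diabetes 0.10, incident diabetes 0.08, incident hard CVD 0.10), 16% of
metabolites at 15% missingness (the rest 2%), and twelve metabolites with
planted effects of magnitude 0.25–0.9 scattered across the panel. The
high-missingness block (metabolites 101–180) intentionally does not
overlap the planted metabolites, so the showcase signal is not confounded
with imputation attenuation.

What the generator emulates — and what it does not:

* Missingness is **completely at random** by default. Real LC-MS
  missingness is largely intensity-dependent; a `left_censored` mode
  (values below the rate-quantile go missing) is included precisely to
  stress the quarter-minimum rule, but no attempt is made to model the
  true censoring mechanism. A green recovery test therefore establishes
  the correctness of the estimator and its intervals under the stated
  generative model, not robustness to informative missingness.
* Metabolites are generated independently; real lipid panels are strongly
  co-regulated. Clustered orderings on synthetic data exercise the
  machinery, not biological block structure.
* Parameter-recovery and coverage tests use `missingRate = 0`: with no
  missingness the fitted model coincides exactly with the generative one,
  so 95% intervals must cover at their nominal rate and null P values must
  be uniform — that is the calibration being tested. With missingness the
  model is (deliberately, realistically) misspecified and attenuation is
  expected, as documented above.

# Numerical choices

* OLS via Cholesky on X′X; rank checked beforehand via the QR
  decomposition so collinear designs fail with a clear error rather than a
  factorization error.
* IRLS tolerance 1e-8 on the maximum coefficient change, cap 100
  iterations; weights floored at 1e-12 to survive fitted probabilities at
  0/1 during intermediate steps.
* Standardization asserts mean 0 / SD 1 to 1e-12; zero-variance columns
  are errors naming the metabolite.
* Grid CSVs print 17 significant digits (`%.17g`), the minimum that
  round-trips IEEE doubles exactly.
* Stable sorts everywhere; clustering tie-break as above.

# Limitations

* No survival models for incident outcomes; no robust or clustered
  standard errors; no interaction terms; no alternative imputations
  (kNN, MICE) or batch correction — all deliberate non-goals.
* The rain plot's exact droplet-size-to-P mapping is a display convention;
  only monotonicity is contractual, and radius- vs area-proportional modes
  will be perceived differently.
* Grids with many non-converged logistic fits (rare outcomes in small
  studies) lose those cells from plots; the grid object keeps the flagged
  records so the omission is visible.
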