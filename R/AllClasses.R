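#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## ModelSpec / ModelPanel
## ---------------------------------------------------------------------------

#' One outcome's regression definition
#'
#' A `ModelSpec` describes a single model in a multi-outcome panel: the
#' outcome variable, the regression family (`"linear"` for continuous
#' outcomes, `"logistic"` for binary ones), the adjustment covariates, and
#' the fixed position of the outcome in every figure (`displayIndex`,
#' 0-based). Display order is a property of the panel, never of file column
#' order, so it survives serialization.
#'
#' @slot outcome outcome variable name.
#' @slot family `"linear"` or `"logistic"`.
#' @slot covariates character vector of covariate variable names (may be
#'   empty).
#' @slot displayIndex non-negative integer; unique within a panel.
#' @export
setClass("ModelSpec",
  representation(
    outcome = "character",
    family = "character",
    covariates = "character",
    displayIndex = "integer"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (length(object@outcome) != 1L || !nzchar(object@outcome))
    msg <- c(msg, "'outcome' must be a single non-empty name")
  if (!(object@family %in% c("linear", "logistic")))
    msg <- c(msg, "'family' must be \"linear\" or \"logistic\"")
  if (object@outcome %in% object@covariates)
    msg <- c(msg, sprintf("outcome '%s' may not appear among its covariates",
                          object@outcome))
  if (length(object@displayIndex) != 1L || is.na(object@displayIndex) ||
      object@displayIndex < 0L)
    msg <- c(msg, "'displayIndex' must be a single integer >= 0")
  if (length(msg)) msg else TRUE
})

#' @param outcome,family,covariates,displayIndex see slots.
#' @rdname ModelSpec-class
#' @export
ModelSpec <- function(outcome, family = c("linear", "logistic"),
                      covariates = character(), displayIndex = 0L) {
  family <- match.arg(family)
  new("ModelSpec", outcome = outcome, family = family,
      covariates = as.character(covariates),
      displayIndex = as.integer(displayIndex))
}

#' An ordered panel of outcome models
#'
#' A `ModelPanel` holds the [ModelSpec-class] objects of a study, kept
#' sorted by `displayIndex`. The display order is fixed at panel
#' construction and used by every downstream figure (columns of the rain
#' plot and paired heatmaps, facets of the Manhattan plot).
#'
#' @slot specs list of [ModelSpec-class] objects, sorted by display index.
#' @seealso [framinghamPanel()] for the packaged default eight-outcome panel.
#' @export
setClass("ModelPanel", representation(specs = "list"))

setValidity("ModelPanel", function(object) {
  msg <- character()
  if (!length(object@specs))
    msg <- c(msg, "panel must contain at least one ModelSpec")
  if (!all(vapply(object@specs, is, logical(1), "ModelSpec")))
    msg <- c(msg, "all panel entries must be ModelSpec objects")
  else {
    idx <- vapply(object@specs, slot, integer(1), "displayIndex")
    out <- vapply(object@specs, slot, character(1), "outcome")
    if (anyDuplicated(idx))
      msg <- c(msg, "display indices must be unique within a panel")
    if (anyDuplicated(out))
      msg <- c(msg, "outcome names must be unique within a panel")
    if (is.unsorted(idx))
      msg <- c(msg, "panel specs must be sorted by displayIndex")
  }
  if (length(msg)) msg else TRUE
})

#' @param specs list of [ModelSpec-class] objects (any order; sorted by
#'   display index on construction).
#' @rdname ModelPanel-class
#' @export
ModelPanel <- function(specs) {
  idx <- vapply(specs, slot, integer(1), "displayIndex")
  new("ModelPanel", specs = specs[order(idx)])
}

#' @rdname accessors
setMethod("outcomeNames", "ModelPanel", function(x)
  vapply(x@specs, slot, character(1), "outcome"))

setMethod("length", "ModelPanel", function(x) length(x@specs))

setMethod("[[", "ModelPanel", function(x, i) {
  if (is.character(i)) i <- match(i, outcomeNames(x))
  x@specs[[i]]
})

setMethod("show", "ModelPanel", function(object) {
  cat(sprintf("ModelPanel with %d outcome models\n", length(object@specs)))
  for (s in object@specs)
    cat(sprintf("  [%d] %-24s %-8s ~ metabolite%s\n", s@displayIndex,
                s@outcome, s@family,
                if (length(s@covariates))
                  paste0(" + ", paste(s@covariates, collapse = " + "))
                else ""))
})

## ---------------------------------------------------------------------------
## PhenotypeTable
## ---------------------------------------------------------------------------

#' Per-sample outcomes and covariates
#'
#' Holds the phenotype table of a study: one row per sample, one column per
#' variable, each variable tagged `"continuous"` or `"binary"`. Binary
#' variables must be coded 0/1 (missing allowed). Sample ids are the row
#' names and must be unique; alignment with an abundance matrix happens via
#' an explicit inner join in [MetaboliteStudy()].
#'
#' @slot data data.frame of variables, sample ids as row names.
#' @slot types named character vector, one of `"continuous"`/`"binary"` per
#'   column of `data`.
#' @export
setClass("PhenotypeTable",
  representation(data = "data.frame", types = "character"))

setValidity("PhenotypeTable", function(object) {
  msg <- character()
  d <- object@data
  if (anyDuplicated(rownames(d)))
    msg <- c(msg, "duplicate sample ids in phenotype table")
  if (!identical(sort(names(object@types)), sort(colnames(d))))
    msg <- c(msg, "'types' must name every phenotype column exactly once")
  else {
    bad <- setdiff(unique(object@types), c("continuous", "binary"))
    if (length(bad))
      msg <- c(msg, sprintf("unknown variable type(s): %s",
                            paste(bad, collapse = ", ")))
    for (v in names(object@types)[object@types == "binary"]) {
      vals <- d[[v]]
      if (!all(vals %in% c(0, 1) | is.na(vals)))
        msg <- c(msg, sprintf(
          "binary variable '%s' contains values outside {0, 1}", v))
    }
    for (v in colnames(d)) if (!is.numeric(d[[v]]))
      msg <- c(msg, sprintf("phenotype column '%s' is not numeric", v))
  }
  if (length(msg)) msg else TRUE
})

#' @param data data.frame with sample ids as row names (or in a
#'   `sample_id` column, which is promoted to row names).
#' @param types named character vector of `"continuous"`/`"binary"` tags;
#'   when omitted, columns whose non-missing values all lie in \{0, 1\} are
#'   tagged binary and the rest continuous.
#' @rdname PhenotypeTable-class
#' @export
PhenotypeTable <- function(data, types = NULL) {
  if ("sample_id" %in% colnames(data)) {
    rownames(data) <- as.character(data$sample_id)
    data$sample_id <- NULL
  }
  if (is.null(types)) {
    types <- vapply(data, function(v)
      if (all(v %in% c(0, 1) | is.na(v))) "binary" else "continuous",
      character(1))
  }
  new("PhenotypeTable", data = data, types = types[colnames(data)])
}

#' @rdname accessors
setMethod("sampleIds", "PhenotypeTable", function(x) rownames(x@data))

#' @rdname accessors
setMethod("variableTypes", "PhenotypeTable", function(x) x@types)

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d samples x %d variables\n",
              nrow(object@data), ncol(object@data)))
  cat(sprintf("  continuous: %s\n", paste(
    names(object@types)[object@types == "continuous"], collapse = ", ")))
  cat(sprintf("  binary:     %s\n", paste(
    names(object@types)[object@types == "binary"], collapse = ", ")))
})

#' Extract the phenotype data.frame
#' @param x a [PhenotypeTable-class].
#' @param ... unused.
#' @return data.frame with sample ids as row names.
#' @export
setMethod("as.data.frame", "PhenotypeTable", function(x, ...) x@data)

## ---------------------------------------------------------------------------
## MetaboliteStudy
## ---------------------------------------------------------------------------

#' A joined metabolomics study container
#'
#' `MetaboliteStudy` extends `SummarizedExperiment`: rows are metabolites,
#' columns are samples (the Bioconductor convention; on-disk abundance
#' tables are samples x metabolites and the readers transpose). The
#' `"abundance"` assay holds raw intensities with missing values as `NA`;
#' preprocessing adds a `"zscore"` assay. `rowData` carries the
#' mass-to-charge value `mz`; `colData` carries the phenotypes, with the
#' continuous/binary tags and (for synthetic studies) the planted-effect
#' truth table stored in `metadata()`.
#'
#' Construction performs an explicit inner join of abundance and phenotype
#' sample ids; samples present in only one input are dropped (the join
#' semantics are this package's documented choice).
#'
#' @slot .. see `SummarizedExperiment`.
#' @export
setClass("MetaboliteStudy", contains = "SummarizedExperiment")

setValidity("MetaboliteStudy", function(object) {
  msg <- character()
  if (!("abundance" %in% assayNames(object)))
    return("'abundance' assay is required")
  a <- assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "abundance intensities must be non-negative")
  if (nrow(a) && ncol(a) && any(rowSums(!is.na(a)) == 0L))
    msg <- c(msg, "at least one metabolite has no observed values")
  if (!("mz" %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain an 'mz' column")
  else {
    mz <- rowData(object)$mz
    if (any(!is.finite(mz) | mz <= 0))
      msg <- c(msg, "all mz values must be finite and positive")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' @param abundance samples x metabolites numeric matrix (dimnames
#'   required), e.g. from [readAbundance()].
#' @param phenotypes a [PhenotypeTable-class].
#' @param annotations data.frame with columns `metabolite_id` and `mz`.
#' @rdname MetaboliteStudy-class
#' @export
MetaboliteStudy <- function(abundance, phenotypes, annotations) {
  stopifnot(is.matrix(abundance), is(phenotypes, "PhenotypeTable"))
  mids <- colnames(abundance)
  miss <- setdiff(mids, annotations$metabolite_id)
  if (length(miss))
    stop("metabolites without annotation: ", paste(head(miss, 5), collapse = ", "))
  common <- intersect(rownames(abundance), sampleIds(phenotypes))
  if (!length(common))
    stop("no samples shared between abundance matrix and phenotype table")
  ann <- annotations[match(mids, annotations$metabolite_id), , drop = FALSE]
  pd <- as.data.frame(phenotypes)[common, , drop = FALSE]
  se <- SummarizedExperiment(
    assays = list(abundance = t(abundance[common, , drop = FALSE])),
    rowData = DataFrame(mz = ann$mz, row.names = mids),
    colData = DataFrame(pd))
  obj <- new("MetaboliteStudy", se)
  metadata(obj)$variableTypes <- variableTypes(phenotypes)
  obj
}

#' @rdname accessors
setMethod("metaboliteIds", "MetaboliteStudy", function(x) rownames(x))

#' @rdname accessors
setMethod("sampleIds", "MetaboliteStudy", function(x) colnames(x))

#' @rdname accessors
setMethod("mzValues", "MetaboliteStudy", function(x)
  setNames(rowData(x)$mz, rownames(x)))

#' @rdname accessors
setMethod("variableTypes", "MetaboliteStudy", function(x)
  metadata(x)$variableTypes)

## ---------------------------------------------------------------------------
## AssociationGrid
## ---------------------------------------------------------------------------

#' A complete metabolites x outcomes grid of association results
#'
#' The central result object: exactly one record per (metabolite, outcome)
#' pair, each carrying the effect estimate `beta` (per 1 SD of log
#' metabolite; log-odds scale for logistic models), its standard error `se`,
#' and the two-sided P value `p`. Records from fits that failed to converge
#' keep their place in the grid with `beta`/`se`/`p` set to `NA` and are
#' excluded from plots with a warning. Outcome order always follows the
#' panel's display indices.
#'
#' @slot records data.frame with columns `metabolite_id`, `outcome`,
#'   `beta`, `se`, `p`, `n_used`, `converged`, sorted metabolite-major in
#'   annotation order then panel order.
#' @slot annotations data.frame with columns `metabolite_id`, `mz`; one row
#'   per metabolite, defining the grid's canonical metabolite order.
#' @slot panel a [ModelPanel-class].
#' @export
setClass("AssociationGrid",
  representation(records = "data.frame", annotations = "data.frame",
                 panel = "ModelPanel"))

setValidity("AssociationGrid", function(object) {
  msg <- character()
  r <- object@records
  ann <- object@annotations
  need <- c("metabolite_id", "outcome", "beta", "se", "p")
  if (!all(need %in% colnames(r)))
    return(sprintf("records must contain columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(ann$metabolite_id))
    msg <- c(msg, "duplicate metabolite ids in annotations")
  if (any(!is.finite(ann$mz) | ann$mz <= 0))
    msg <- c(msg, "all mz values must be finite and positive")
  outs <- outcomeNames(object@panel)
  nm <- nrow(ann); no <- length(outs)
  if (nrow(r) != nm * no)
    msg <- c(msg, sprintf(
      "grid is incomplete: %d records but %d metabolites x %d outcomes",
      nrow(r), nm, no))
  else {
    key <- paste(r$metabolite_id, r$outcome, sep = "\r")
    want <- paste(rep(ann$metabolite_id, each = no),
                  rep(outs, nm), sep = "\r")
    if (!setequal(key, want) || anyDuplicated(key))
      msg <- c(msg, "records do not cover each (metabolite, outcome) pair exactly once")
  }
  ok <- !is.na(r$p)
  if (any(r$p[ok] <= 0 | r$p[ok] > 1))
    msg <- c(msg, "P values must lie in (0, 1]")
  if (any(r$se[!is.na(r$se)] <= 0))
    msg <- c(msg, "standard errors must be positive")
  if (any(is.infinite(r$beta), na.rm = TRUE))
    msg <- c(msg, "beta estimates must be finite")
  if (any(is.na(r$p) != is.na(r$beta)))
    msg <- c(msg, "beta and p must be missing together (failed fits only)")
  if (length(msg)) msg else TRUE
})

#' @param records,annotations,panel see slots. Records may arrive in any
#'   row order; they are sorted into canonical (annotation-order
#'   metabolite-major, panel-order outcome) order.
#' @rdname AssociationGrid-class
#' @export
AssociationGrid <- function(records, annotations, panel) {
  if (!all(c("n_used", "converged") %in% colnames(records))) {
    records$n_used <- if (is.null(records$n_used)) NA_integer_ else records$n_used
    records$converged <- if (is.null(records$converged)) !is.na(records$p)
                         else records$converged
  }
  mi <- match(records$metabolite_id, annotations$metabolite_id)
  oi <- match(records$outcome, outcomeNames(panel))
  records <- records[order(mi, oi), , drop = FALSE]
  rownames(records) <- NULL
  rownames(annotations) <- NULL
  new("AssociationGrid", records = records,
      annotations = annotations[, c("metabolite_id", "mz"), drop = FALSE],
      panel = panel)
}

#' @rdname accessors
setMethod("gridRecords", "AssociationGrid", function(x) x@records)

#' @rdname accessors
setMethod("gridAnnotations", "AssociationGrid", function(x) x@annotations)

#' @rdname accessors
setMethod("modelPanel", "AssociationGrid", function(x) x@panel)

#' @rdname accessors
setMethod("metaboliteIds", "AssociationGrid", function(x)
  x@annotations$metabolite_id)

#' @rdname accessors
setMethod("outcomeNames", "AssociationGrid", function(x)
  outcomeNames(x@panel))

#' @rdname accessors
setMethod("mzValues", "AssociationGrid", function(x)
  setNames(x@annotations$mz, x@annotations$metabolite_id))

setMethod("dim", "AssociationGrid", function(x)
  c(nrow(x@annotations), length(x@panel)))

setMethod("show", "AssociationGrid", function(object) {
  d <- dim(object)
  cat(sprintf("AssociationGrid: %d metabolites x %d outcomes (%d records)\n",
              d[1], d[2], nrow(object@records)))
  nf <- sum(!object@records$converged)
  if (nf) cat(sprintf("  %d non-converged fit(s) flagged\n", nf))
  cat("  outcomes:", paste(outcomeNames(object), collapse = ", "), "\n")
})

#' Extract the beta (or -log10 P) matrix of a grid
#'
#' Utility used by the ordering and plotting layers: reshapes the long
#' records into a metabolites x outcomes matrix in canonical order.
#'
#' @param grid an [AssociationGrid-class].
#' @param what `"beta"`, `"p"`, or `"se"`.
#' @return numeric matrix, metabolite ids as rownames, outcomes as colnames.
#' @export
gridMatrix <- function(grid, what = c("beta", "p", "se")) {
  what <- match.arg(what)
  r <- gridRecords(grid)
  mids <- metaboliteIds(grid)
  outs <- outcomeNames(grid)
  m <- matrix(NA_real_, length(mids), length(outs),
              dimnames = list(mids, outs))
  m[cbind(match(r$metabolite_id, mids), match(r$outcome, outs))] <- r[[what]]
  m
}

## ---------------------------------------------------------------------------
## OrderingSpec
## ---------------------------------------------------------------------------

#' Row-ordering specification
#'
#' Describes how metabolite rows are ordered in figures: by summary P value,
#' by mass-to-charge ratio, by hierarchical clustering of effect profiles,
#' or left as given. For multi-outcome grids the summary P is, by default,
#' the minimum across outcomes; `anchor_outcome` mode sorts on a single
#' named outcome instead.
#'
#' @slot method `"pvalue"`, `"mz"`, `"cluster"`, or `"given"`.
#' @slot pvalueSummary `"min_across_outcomes"` or `"anchor_outcome"`.
#' @slot anchor outcome name; required iff `pvalueSummary` is
#'   `"anchor_outcome"`.
#' @slot linkage hierarchical clustering linkage: `"average"`, `"complete"`,
#'   `"single"`, or `"ward"`.
#' @slot distance `"euclidean"` or `"correlation"` distance between
#'   per-metabolite beta profiles.
#' @export
setClass("OrderingSpec",
  representation(method = "character", pvalueSummary = "character",
                 anchor = "character", linkage = "character",
                 distance = "character"))

setValidity("OrderingSpec", function(object) {
  msg <- character()
  if (!(object@method %in% c("pvalue", "mz", "cluster", "given")))
    msg <- c(msg, "unknown ordering method")
  if (!(object@pvalueSummary %in% c("min_across_outcomes", "anchor_outcome")))
    msg <- c(msg, "unknown pvalueSummary")
  if (object@pvalueSummary == "anchor_outcome" && is.na(object@anchor))
    msg <- c(msg, "anchor outcome required when pvalueSummary = \"anchor_outcome\"")
  if (object@pvalueSummary != "anchor_outcome" && !is.na(object@anchor))
    msg <- c(msg, "anchor given but pvalueSummary is not \"anchor_outcome\"")
  if (!(object@linkage %in% c("average", "complete", "single", "ward")))
    msg <- c(msg, "unknown linkage")
  if (!(object@distance %in% c("euclidean", "correlation")))
    msg <- c(msg, "unknown distance")
  if (length(msg)) msg else TRUE
})

#' @param method,pvalueSummary,anchor,linkage,distance see slots.
#' @rdname OrderingSpec-class
#' @export
OrderingSpec <- function(method = c("pvalue", "mz", "cluster", "given"),
                         pvalueSummary = c("min_across_outcomes",
                                           "anchor_outcome"),
                         anchor = NA_character_,
                         linkage = c("average", "complete", "single", "ward"),
                         distance = c("euclidean", "correlation")) {
  if (!is.na(anchor) && missing(pvalueSummary)) pvalueSummary <- "anchor_outcome"
  new("OrderingSpec", method = match.arg(method),
      pvalueSummary = match.arg(pvalueSummary), anchor = anchor,
      linkage = match.arg(linkage), distance = match.arg(distance))
}

## ---------------------------------------------------------------------------
## PreprocessReport
## ---------------------------------------------------------------------------

#' Report of the preprocessing pipeline
#'
#' Records, per metabolite, the fraction of missing intensities and the
#' imputation constant used (0.25 x the minimum observed value; `NA` where
#' nothing was missing), plus the count of metabolites whose missingness
#' exceeds a reporting threshold (default 10%). The threshold is reported,
#' not used as a filter, unless an exclusion cutoff is explicitly requested.
#'
#' @slot missingFraction named numeric in \[0, 1\] per metabolite.
#' @slot imputationConstant named numeric; `NA` for fully observed columns.
#' @slot threshold the reporting threshold on the missing fraction.
#' @slot nAboveThreshold number of metabolites above `threshold`.
#' @slot excluded metabolite ids dropped by an explicit exclusion cutoff
#'   (empty by default).
#' @export
setClass("PreprocessReport",
  representation(missingFraction = "numeric", imputationConstant = "numeric",
                 threshold = "numeric", nAboveThreshold = "integer",
                 excluded = "character"))

setValidity("PreprocessReport", function(object) {
  msg <- character()
  if (any(object@missingFraction < 0 | object@missingFraction >= 1))
    msg <- c(msg, "missing fractions must lie in [0, 1)")
  if (length(object@imputationConstant) != length(object@missingFraction))
    msg <- c(msg, "one imputation constant per metabolite required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PreprocessReport", function(object) {
  cat(sprintf(
    "PreprocessReport: %d metabolites; %d (%.1f%%) with > %.0f%% missing\n",
    length(object@missingFraction), object@nAboveThreshold,
    100 * object@nAboveThreshold / max(1L, length(object@missingFraction)),
    100 * object@threshold))
  if (length(object@excluded))
    cat(sprintf("  excluded by cutoff: %d metabolite(s)\n",
                length(object@excluded)))
})

## ---------------------------------------------------------------------------
## Plot models
## ---------------------------------------------------------------------------

#' Renderer-independent rain plot model
#'
#' One mark ("droplet") per (metabolite, outcome) cell. The fill value is
#' the beta coefficient clipped to symmetric color limits, so color encodes
#' both magnitude and direction; the droplet radius grows monotonically with
#' -log10(P) up to a significance cap, so size encodes significance. All
#' encoding decisions live here, testable without rendering an image.
#'
#' @slot rows ordered metabolite labels (top to bottom).
#' @slot cols ordered outcome labels (left to right, panel display order).
#' @slot cells data.frame with one row per cell: `row`, `col` (1-based
#'   positions), `metabolite_id`, `outcome`, `fill_value` (clipped beta),
#'   `radius_value` (-log10 P, capped), `radius` (display radius in cell
#'   units).
#' @slot colorLimits symmetric `c(-L, L)` fill limits.
#' @slot radiusRange `c(r_min, r_max)` display radii in cell units.
#' @slot cap the -log10(P) ceiling mapped to `r_max`.
#' @slot sizeMode `"radius"` (radius proportional to capped -log10 P) or
#'   `"area"` (circle area proportional).
#' @export
setClass("RainPlotModel",
  representation(rows = "character", cols = "character",
                 cells = "data.frame", colorLimits = "numeric",
                 radiusRange = "numeric", cap = "numeric",
                 sizeMode = "character"))

setValidity("RainPlotModel", function(object) {
  msg <- character()
  if (nrow(object@cells) > length(object@rows) * length(object@cols))
    msg <- c(msg, "more cells than rows x cols")
  key <- paste(object@cells$row, object@cells$col)
  if (anyDuplicated(key))
    msg <- c(msg, "at most one cell per (row, col)")
  if (length(object@colorLimits) != 2 ||
      !isTRUE(all.equal(object@colorLimits[1], -object@colorLimits[2])))
    msg <- c(msg, "color limits must be symmetric about 0")
  if (length(object@radiusRange) != 2 ||
      object@radiusRange[1] < 0 || diff(object@radiusRange) <= 0)
    msg <- c(msg, "radiusRange must be increasing and non-negative")
  if (!(object@sizeMode %in% c("radius", "area")))
    msg <- c(msg, "sizeMode must be \"radius\" or \"area\"")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RainPlotModel", function(object) {
  cat(sprintf(
    "RainPlotModel: %d metabolites x %d outcomes, %d droplets\n",
    length(object@rows), length(object@cols), nrow(object@cells)))
  cat(sprintf("  fill in [%.3g, %.3g]; radius %.2f-%.2f (%s mode), cap -log10(P) = %.3g\n",
              object@colorLimits[1], object@colorLimits[2],
              object@radiusRange[1], object@radiusRange[2],
              object@sizeMode, object@cap))
})

#' Renderer-independent faceted Manhattan plot model
#'
#' One facet per outcome in panel order, sharing a single y axis. Points sit
#' at (m/z, -log10 P) with a direction flag from the beta sign; the model
#' intentionally carries no magnitude channel. A horizontal threshold line
#' marks the (by default Bonferroni-corrected) significance cutoff.
#'
#' @slot facets ordered outcome names.
#' @slot points data.frame: `outcome`, `metabolite_id`, `mz`, `y`
#'   (-log10 P), `direction` (sign of beta: -1, 0, +1).
#' @slot thresholdLine -log10 of the significance cutoff.
#' @slot yLimits shared `c(0, ymax)` across facets.
#' @export
setClass("ManhattanModel",
  representation(facets = "character", points = "data.frame",
                 thresholdLine = "numeric", yLimits = "numeric"))

setMethod("show", "ManhattanModel", function(object) {
  cat(sprintf(
    "ManhattanModel: %d facets, %d points/facet, threshold -log10(P) = %.3g\n",
    length(object@facets),
    nrow(object@points) / max(1L, length(object@facets)),
    object@thresholdLine))
})

#' Renderer-independent bar-and-scatter model for one outcome
#'
#' Signed bars encode the magnitude and direction of the beta estimates;
#' scatter dots aligned on the same metabolite axis encode -log10(P).
#'
#' @slot outcome the displayed outcome.
#' @slot data data.frame per metabolite: `metabolite_id`, `beta`, `neglogp`.
#' @export
setClass("BarScatterModel",
  representation(outcome = "character", data = "data.frame"))

setMethod("show", "BarScatterModel", function(object) {
  cat(sprintf("BarScatterModel: outcome '%s', %d metabolites\n",
              object@outcome, nrow(object@data)))
})

#' Renderer-independent paired heatmaps model
#'
#' Two aligned matrices over identical row and column orders: `fillsBeta`
#' on a symmetric diverging scale (magnitude + direction) and `fillsP`
#' (-log10 P, capped) on a sequential scale (significance). Together they
#' convey what a rain plot conveys in a single panel.
#'
#' @slot rows,cols shared orderings.
#' @slot fillsBeta,fillsP aligned numeric matrices.
#' @slot colorLimits symmetric beta fill limits.
#' @slot pLimits `c(0, cap)` significance fill limits.
#' @export
setClass("PairedHeatmapModel",
  representation(rows = "character", cols = "character",
                 fillsBeta = "matrix", fillsP = "matrix",
                 colorLimits = "numeric", pLimits = "numeric"))

setValidity("PairedHeatmapModel", function(object) {
  msg <- character()
  if (!identical(dim(object@fillsBeta), dim(object@fillsP)))
    msg <- c(msg, "the paired matrices must have identical shape")
  if (!identical(dimnames(object@fillsBeta), dimnames(object@fillsP)))
    msg <- c(msg, "the paired matrices must share row/column orders")
  if (!isTRUE(all.equal(object@colorLimits[1], -object@colorLimits[2])))
    msg <- c(msg, "beta color limits must be symmetric about 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairedHeatmapModel", function(object) {
  cat(sprintf("PairedHeatmapModel: %d x %d beta and -log10(P) matrices\n",
              nrow(object@fillsBeta), ncol(object@fillsBeta)))
})

## ---------------------------------------------------------------------------
## SyntheticDesign
## ---------------------------------------------------------------------------

#' Design of a synthetic metabolomics study
#'
#' Describes everything the generator needs: study size, the m/z
#' acquisition window (default 225-650, the negative-mode lipidomics full
#' scan range), per-metabolite missingness rates and mechanism, planted
#' (metabolite, outcome, beta) effects, outcome noise, the outcome panel,
#' and the seed that fixes every downstream draw.
#'
#' @slot nSamples,nMetabolites study dimensions.
#' @slot mzRange `c(low, high)` m/z window.
#' @slot missingRate per-metabolite missingness rate(s) in \[0, 1);
#'   length 1 or `nMetabolites`.
#' @slot missingMode `"mcar"` (completely at random) or `"left_censored"`
#'   (values below the rate-quantile of each metabolite go missing).
#' @slot plantedEffects data.frame `metabolite`, `outcome`, `beta`.
#' @slot noiseSd residual SD of continuous outcomes.
#' @slot panel the [ModelPanel-class] whose outcomes are generated.
#' @slot seed integer seed.
#' @export
setClass("SyntheticDesign",
  representation(nSamples = "integer", nMetabolites = "integer",
                 mzRange = "numeric", missingRate = "numeric",
                 missingMode = "character", plantedEffects = "data.frame",
                 noiseSd = "numeric", panel = "ModelPanel", seed = "integer"))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  if (object@nSamples < 2L) msg <- c(msg, "need at least 2 samples")
  if (object@nMetabolites < 1L) msg <- c(msg, "need at least 1 metabolite")
  if (any(object@missingRate < 0 | object@missingRate >= 1))
    msg <- c(msg, "missing rates must lie in [0, 1)")
  if (!(length(object@missingRate) %in% c(1L, object@nMetabolites)))
    msg <- c(msg, "missingRate must have length 1 or nMetabolites")
  if (!(object@missingMode %in% c("mcar", "left_censored")))
    msg <- c(msg, "missingMode must be \"mcar\" or \"left_censored\"")
  if (length(object@mzRange) != 2 || diff(object@mzRange) <= 0 ||
      object@mzRange[1] <= 0)
    msg <- c(msg, "mzRange must be an increasing positive pair")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (nrow(object@plantedEffects) &&
      !all(c("metabolite", "outcome", "beta") %in%
           colnames(object@plantedEffects)))
    msg <- c(msg, "plantedEffects needs columns metabolite, outcome, beta")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticDesign", function(object) {
  cat(sprintf(
    "SyntheticDesign: %d samples x %d metabolites, %d outcomes, seed %d\n",
    object@nSamples, object@nMetabolites, length(object@panel), object@seed))
  cat(sprintf("  m/z in (%g, %g); %d planted effect(s); missingness %s\n",
              object@mzRange[1], object@mzRange[2],
              nrow(object@plantedEffects), object@missingMode))
})
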