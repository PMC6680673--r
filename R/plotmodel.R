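## Builders of the four renderer-independent plot models. Every visual
## encoding rule (fill clipping, radius mapping, shared axes, threshold
## lines) is decided here so it can be tested without producing an image;
## render.R only draws what these models state.

#' Significance transform -log10(P)
#'
#' The transform underlying every significance channel in the package.
#' Values are capped (default 300) so that P values at the double-underflow
#' level still map to a finite display value.
#'
#' @param p numeric vector of P values in (0, 1].
#' @param cap ceiling applied to -log10(p).
#' @return non-negative numeric vector.
#' @examples
#' negLog10P(c(0.01, 1))  # 2 0
#' @export
negLog10P <- function(p, cap = 300) {
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad))
    stop(sprintf("P value out of (0, 1]: %g", p[bad[1]]), call. = FALSE)
  pmin(-log10(p), cap)
}

.checkPermutation <- function(perm, n) {
  if (!identical(sort(as.integer(perm)), seq_len(n)))
    stop("row order must be a permutation of 1..", n, call. = FALSE)
  as.integer(perm)
}

## Default significance cap: -log10 of the Bonferroni threshold over the
## grid's metabolites, floored at 2 so tiny grids keep a sensible scale.
.defaultCap <- function(grid, alpha = 0.05) {
  max(2, -log10(alpha / nrow(gridAnnotations(grid))))
}

.dropFailed <- function(r) {
  bad <- !r$converged | is.na(r$p)
  if (any(bad)) {
    warning(sum(bad), " non-converged record(s) excluded from the plot",
            call. = FALSE)
    r <- r[!bad, , drop = FALSE]
  }
  r
}

#' Build a rain plot model
#'
#' Lays out one droplet per (metabolite, outcome) cell: rows follow
#' `rowOrder` top to bottom, columns follow the panel display order left to
#' right. The fill value is the beta coefficient clipped to symmetric color
#' limits (default: the grid's max |beta|), so color carries magnitude and
#' direction; the display radius interpolates between `radiusRange` as
#' -log10(P) grows toward `cap` (default: the Bonferroni threshold of the
#' grid), so droplet size carries significance. `sizeMode = "radius"`
#' (default) makes the radius proportional to capped significance;
#' `"area"` makes the circle area proportional instead.
#'
#' @param grid a complete [AssociationGrid-class].
#' @param rowOrder 1-based permutation of the grid's metabolites (e.g. from
#'   [orderMetabolites()]).
#' @param colorLimit positive half-width `L` of the symmetric fill limits;
#'   default max |beta| over the grid.
#' @param radiusRange `c(r_min, r_max)` display radii in cell units (a cell
#'   is 1 x 1).
#' @param cap significance value (-log10 P) mapped to `r_max`.
#' @param sizeMode `"radius"` or `"area"`.
#' @return a [RainPlotModel-class].
#' @export
buildRainPlotModel <- function(grid, rowOrder = seq_len(dim(grid)[1]),
                               colorLimit = NULL,
                               radiusRange = c(0.08, 0.45),
                               cap = NULL, sizeMode = c("radius", "area")) {
  sizeMode <- match.arg(sizeMode)
  ann <- gridAnnotations(grid)
  rowOrder <- .checkPermutation(rowOrder, nrow(ann))
  rows <- ann$metabolite_id[rowOrder]
  cols <- outcomeNames(grid)
  r <- .dropFailed(gridRecords(grid))
  if (is.null(cap)) cap <- .defaultCap(grid)
  if (is.null(colorLimit)) {
    colorLimit <- max(abs(r$beta), na.rm = TRUE)
    if (!is.finite(colorLimit) || colorLimit == 0) colorLimit <- 1
  }
  nlp <- negLog10P(r$p)
  t <- pmin(nlp, cap) / cap
  radius <- if (sizeMode == "radius")
    radiusRange[1] + diff(radiusRange) * t
  else
    sqrt(radiusRange[1]^2 + (radiusRange[2]^2 - radiusRange[1]^2) * t)
  cells <- data.frame(
    row = match(r$metabolite_id, rows),
    col = match(r$outcome, cols),
    metabolite_id = r$metabolite_id,
    outcome = r$outcome,
    fill_value = pmin(pmax(r$beta, -colorLimit), colorLimit),
    radius_value = pmin(nlp, cap),
    radius = radius,
    stringsAsFactors = FALSE)
  new("RainPlotModel", rows = rows, cols = cols, cells = cells,
      colorLimits = c(-colorLimit, colorLimit),
      radiusRange = radiusRange, cap = cap, sizeMode = sizeMode)
}

#' Build a faceted Manhattan plot model
#'
#' One facet per outcome in panel display order; within each facet,
#' metabolites sit at their actual m/z on the x axis and -log10(P) on a
#' y axis shared across facets, with the point direction taken from the
#' beta sign. The horizontal threshold line defaults to the Bonferroni
#' cutoff alpha / m over the grid's m metabolites; `bonferroni = FALSE`
#' draws the raw alpha instead.
#'
#' @param grid a complete [AssociationGrid-class].
#' @param alpha significance level for the threshold line.
#' @param bonferroni divide `alpha` by the number of metabolites (default).
#' @return a [ManhattanModel-class].
#' @export
buildManhattanModel <- function(grid, alpha = 0.05, bonferroni = TRUE) {
  ann <- gridAnnotations(grid)
  if (anyNA(ann$mz)) stop("missing m/z value(s)", call. = FALSE)
  r <- .dropFailed(gridRecords(grid))
  r$mz <- ann$mz[match(r$metabolite_id, ann$metabolite_id)]
  pts <- data.frame(
    outcome = r$outcome, metabolite_id = r$metabolite_id, mz = r$mz,
    y = negLog10P(r$p), direction = sign(r$beta),
    stringsAsFactors = FALSE)
  thr <- -log10(if (bonferroni) alpha / nrow(ann) else alpha)
  ymax <- max(c(pts$y, thr))
  new("ManhattanModel", facets = outcomeNames(grid), points = pts,
      thresholdLine = thr, yLimits = c(0, ymax))
}

#' Build a bar-and-scatter model for one outcome
#'
#' Bars encode the signed beta estimates (magnitude and direction), dots
#' aligned on the same metabolite axis encode -log10(P), for a single
#' outcome of the panel.
#'
#' @param grid a complete [AssociationGrid-class].
#' @param outcome outcome name; must be in the panel.
#' @param rowOrder optional 1-based permutation of the metabolites.
#' @return a [BarScatterModel-class].
#' @export
buildBarScatterModel <- function(grid, outcome,
                                 rowOrder = seq_len(dim(grid)[1])) {
  if (!(outcome %in% outcomeNames(grid)))
    stop("outcome '", outcome, "' is not in the panel", call. = FALSE)
  ann <- gridAnnotations(grid)
  rowOrder <- .checkPermutation(rowOrder, nrow(ann))
  r <- .dropFailed(gridRecords(grid))
  r <- r[r$outcome == outcome, , drop = FALSE]
  r <- r[match(ann$metabolite_id[rowOrder], r$metabolite_id), , drop = FALSE]
  r <- r[!is.na(r$metabolite_id), , drop = FALSE]
  new("BarScatterModel", outcome = outcome,
      data = data.frame(metabolite_id = r$metabolite_id, beta = r$beta,
                        neglogp = negLog10P(r$p), stringsAsFactors = FALSE))
}

#' Build a paired heatmaps model
#'
#' Two aligned matrices over identical row and column orders: betas on
#' symmetric diverging limits and capped -log10(P) on `[0, cap]` sequential
#' limits — together carrying the information a rain plot carries in one
#' panel.
#'
#' @inheritParams buildRainPlotModel
#' @return a [PairedHeatmapModel-class].
#' @export
buildPairedHeatmapModel <- function(grid, rowOrder = seq_len(dim(grid)[1]),
                                    colorLimit = NULL, cap = NULL) {
  ann <- gridAnnotations(grid)
  rowOrder <- .checkPermutation(rowOrder, nrow(ann))
  rows <- ann$metabolite_id[rowOrder]
  B <- gridMatrix(grid, "beta")[rows, , drop = FALSE]
  P <- gridMatrix(grid, "p")[rows, , drop = FALSE]
  if (is.null(cap)) cap <- .defaultCap(grid)
  if (is.null(colorLimit)) {
    colorLimit <- max(abs(B), na.rm = TRUE)
    if (!is.finite(colorLimit) || colorLimit == 0) colorLimit <- 1
  }
  nlP <- P
  ok <- !is.na(P)
  nlP[ok] <- pmin(negLog10P(P[ok]), cap)
  new("PairedHeatmapModel", rows = rows, cols = colnames(B),
      fillsBeta = pmin(pmax(B, -colorLimit), colorLimit), fillsP = nlP,
      colorLimits = c(-colorLimit, colorLimit), pLimits = c(0, cap))
}
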