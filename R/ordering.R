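## The three reproducible row orderings of rain plots / heatmaps (summary
## P value, m/z, hierarchical clustering of beta profiles) and top-k
## metabolite selection. All orderings are stable: ties keep input order.

.summaryPvalues <- function(grid, spec) {
  P <- gridMatrix(grid, "p")
  if (spec@pvalueSummary == "anchor_outcome") {
    if (!(spec@anchor %in% colnames(P)))
      stop("anchor outcome '", spec@anchor, "' is not in the panel",
           call. = FALSE)
    s <- P[, spec@anchor]
  } else {
    s <- apply(P, 1, function(p)
      if (all(is.na(p))) Inf else min(p, na.rm = TRUE))
  }
  s[is.na(s)] <- Inf
  s
}

#' Order metabolites by summary P value
#'
#' Sorts metabolites from smallest to largest summary P value. With the
#' default `min_across_outcomes` summary a metabolite is ranked by its
#' strongest association across the whole panel; `anchor_outcome` mode
#' ranks by a single named outcome instead. The sort is stable: equal
#' summaries keep their input (annotation) order. Records from
#' non-converged fits contribute no P value.
#'
#' @param grid a complete [AssociationGrid-class].
#' @param spec an [OrderingSpec-class]; only its P-value summary fields are
#'   used.
#' @return 1-based integer permutation of the grid's metabolite indices.
#' @export
orderByPvalue <- function(grid, spec = OrderingSpec("pvalue")) {
  s <- .summaryPvalues(grid, spec)
  order(s, seq_along(s))
}

#' Order metabolites by mass-to-charge ratio
#'
#' Ascending m/z, stable on ties — the ordering used along the Manhattan
#' plot x axis, applied to rain plot / heatmap rows.
#'
#' @param annotations data.frame with columns `metabolite_id` and `mz`, or
#'   an [AssociationGrid-class].
#' @return 1-based integer permutation.
#' @export
orderByMz <- function(annotations) {
  if (is(annotations, "AssociationGrid"))
    annotations <- gridAnnotations(annotations)
  mz <- annotations$mz
  if (anyNA(mz)) stop("missing m/z value(s); cannot order", call. = FALSE)
  order(mz, seq_along(mz))
}

## Deterministic dendrogram leaf order. At each merge the child whose
## lexicographically smallest metabolite id is smaller goes first; ids
## travel with the rows, so the leaf-id sequence is invariant to input row
## order whenever all merge distances are distinct.
.leafOrder <- function(merge, ids) {
  n <- length(ids)
  if (n == 1L) return(1L)
  ords <- vector("list", nrow(merge))
  childOrd <- function(v)
    if (v < 0) -v else ords[[v]]
  for (i in seq_len(nrow(merge))) {
    a <- childOrd(merge[i, 1])
    b <- childOrd(merge[i, 2])
    if (min(ids[b]) < min(ids[a])) { tmp <- a; a <- b; b <- tmp }
    ords[[i]] <- c(a, b)
  }
  ords[[nrow(merge)]]
}

#' Order metabolites by hierarchical clustering of effect profiles
#'
#' Agglomerative hierarchical clustering of the per-metabolite beta vectors
#' across outcomes (default: Euclidean distance, average linkage), so that
#' metabolites with similar association profiles sit adjacently. The
#' returned permutation is the dendrogram leaf order, made deterministic by
#' a fixed child-ordering rule (at each merge, the subtree containing the
#' lexicographically smallest metabolite id comes first), so the same data
#' always yield the same figure regardless of input row order.
#'
#' @param grid a complete [AssociationGrid-class] with finite betas.
#' @param spec an [OrderingSpec-class]; `linkage` and `distance` are used.
#' @return 1-based integer permutation.
#' @export
orderByCluster <- function(grid, spec = OrderingSpec("cluster")) {
  B <- gridMatrix(grid, "beta")
  if (any(!is.finite(B)))
    stop("non-finite beta(s); exclude failed fits before clustering",
         call. = FALSE)
  n <- nrow(B)
  if (n == 1L) return(1L)
  d <- switch(spec@distance,
              euclidean = dist(B),
              correlation = {
                if (ncol(B) < 2L)
                  stop("correlation distance needs >= 2 outcomes",
                       call. = FALSE)
                stats::as.dist(1 - cor(t(B)))
              })
  method <- switch(spec@linkage, average = "average",
                   complete = "complete", single = "single",
                   ward = "ward.D2")
  hc <- hclust(d, method = method)
  .leafOrder(hc$merge, rownames(B))
}

#' Order metabolites according to an ordering specification
#'
#' Dispatch wrapper over the three ordering schemes; `method = "given"`
#' returns the identity permutation.
#'
#' @inheritParams orderByPvalue
#' @return 1-based integer permutation.
#' @export
orderMetabolites <- function(grid, spec) {
  switch(spec@method,
         pvalue = orderByPvalue(grid, spec),
         mz = orderByMz(grid),
         cluster = orderByCluster(grid, spec),
         given = seq_len(nrow(gridAnnotations(grid))))
}

#' Keep the k most significant metabolites
#'
#' Restricts the grid to the `k` metabolites with the smallest summary P
#' value (same summary rule as [orderByPvalue()], same stable tie-break),
#' the default display size of a rain plot being the top 50. The selected
#' metabolites keep their original relative order; apply an ordering
#' afterwards to sort the display. If `k >= n` the grid is returned whole.
#'
#' @param grid a complete [AssociationGrid-class].
#' @param k number of metabolites to keep (default 50).
#' @param spec [OrderingSpec-class] supplying the P-value summary rule.
#' @return a complete [AssociationGrid-class] over the retained metabolites.
#' @export
selectTopK <- function(grid, k = 50, spec = OrderingSpec("pvalue")) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ann <- gridAnnotations(grid)
  n <- nrow(ann)
  if (k >= n) return(grid)
  keepIdx <- sort(orderByPvalue(grid, spec)[seq_len(k)])
  keep <- ann$metabolite_id[keepIdx]
  r <- gridRecords(grid)
  AssociationGrid(r[r$metabolite_id %in% keep, , drop = FALSE],
                  annotations = ann[keepIdx, , drop = FALSE],
                  panel = modelPanel(grid))
}
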