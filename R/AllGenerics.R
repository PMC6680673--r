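#' @import methods
#' @importFrom stats complete.cases cor dist hclust median pnorm pt quantile
#'   rbinom rnorm runif sd setNames plogis ks.test qnorm
#' @importFrom utils read.table write.table packageVersion head
NULL

#' Accessor generics
#'
#' Small accessor generics shared across the package's S4 classes:
#' `metaboliteIds()` and `outcomeNames()` return the row/column identities of
#' an object, `mzValues()` the mass-to-charge value per metabolite,
#' `gridRecords()` and `gridAnnotations()` the long-format association records
#' and the annotation table of an [AssociationGrid-class], `modelPanel()` the
#' ordered outcome panel, `sampleIds()` and `variableTypes()` the sample keys
#' and continuous/binary tags of a [PhenotypeTable-class].
#'
#' @param x an object of one of the package's classes.
#' @return A character vector, data frame, or panel object as documented for
#'   each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("outcomeNames", function(x) standardGeneric("outcomeNames"))

#' @rdname accessors
#' @export
setGeneric("mzValues", function(x) standardGeneric("mzValues"))

#' @rdname accessors
#' @export
setGeneric("gridRecords", function(x) standardGeneric("gridRecords"))

#' @rdname accessors
#' @export
setGeneric("gridAnnotations", function(x) standardGeneric("gridAnnotations"))

#' @rdname accessors
#' @export
setGeneric("modelPanel", function(x) standardGeneric("modelPanel"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("variableTypes", function(x) standardGeneric("variableTypes"))

#' Render a plot model to an image file
#'
#' Writes a renderer-independent plot model (rain plot, Manhattan, paired
#' heatmaps, or bar-and-scatter) to `svg`, `png`, or `pdf`, chosen by the
#' file extension. SVG output is written directly so that every rain-plot
#' droplet is one literal `<circle>` element, making figures machine
#' checkable; `png`/`pdf` draw the identical scene through the `grid`
#' graphics system.
#'
#' @param model a plot model object created by one of the `build*Model`
#'   functions.
#' @param path output file path ending in `.svg`, `.png`, or `.pdf`.
#' @param width,height device size in inches (`png` uses 150 dpi).
#' @return `path`, invisibly.
#' @export
setGeneric("renderPlot", function(model, path, width = 7, height = 7)
  standardGeneric("renderPlot"))
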