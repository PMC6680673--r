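## Tabular readers/writers. CSV or TSV only (sniffed by extension), UTF-8,
## header mandatory. Missing values parse from "" or "NA" — covers both
## R- and spreadsheet-exported files.

.delimFor <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t",
         stop("cannot sniff delimiter from extension '.", ext,
              "'; use .csv or .tsv", call. = FALSE))
}

.readRaw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, sep = .delimFor(path), header = TRUE,
             na.strings = c("", "NA"), check.names = FALSE,
             stringsAsFactors = FALSE, fileEncoding = "UTF-8",
             comment.char = "")
}

.asNumericCol <- function(v, col, what) {
  if (is.numeric(v)) return(v)
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric %s in column '%s', row %d: \"%s\"",
                 what, col, bad[1], v[bad[1]]), call. = FALSE)
  out
}

#' Read a study table of a given schema
#'
#' Single entry point over the four typed readers. The schema decides both
#' the expected layout and the returned class:
#' \describe{
#'   \item{`abundance`}{samples x metabolites intensities, first column the
#'     sample id; returns a numeric matrix with sample ids as rownames.}
#'   \item{`phenotype`}{samples x variables, first column the sample id;
#'     returns a [PhenotypeTable-class].}
#'   \item{`annotation`}{columns `metabolite_id`, `mz`; returns a
#'     data.frame.}
#'   \item{`association`}{long format with columns `metabolite_id`, `mz`,
#'     `outcome`, `beta`, `se`, `p`; returns an [AssociationGrid-class].}
#' }
#' All class invariants are enforced on read: duplicate ids, negative
#' intensities, non-positive m/z, binary phenotypes coded outside \{0, 1\},
#' and incomplete association grids are rejected with informative errors.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file with a header row.
#' @param schema one of `"abundance"`, `"phenotype"`, `"annotation"`,
#'   `"association"`.
#' @param ... passed to the schema-specific reader (e.g. `types` for
#'   phenotypes, `panel` for associations).
#' @return the typed object for the schema.
#' @export
readStudyTable <- function(path, schema = c("abundance", "phenotype",
                                            "annotation", "association"),
                           ...) {
  switch(match.arg(schema),
         abundance = readAbundance(path),
         phenotype = readPhenotypes(path, ...),
         annotation = readAnnotations(path),
         association = readAssociationGrid(path, ...))
}

#' @rdname readStudyTable
#' @export
readAbundance <- function(path) {
  d <- .readRaw(path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in abundance table: ",
         ids[duplicated(ids)][1], call. = FALSE)
  d <- d[, -1, drop = FALSE]
  if (anyDuplicated(colnames(d)))
    stop("duplicate metabolite ids in abundance table", call. = FALSE)
  for (j in colnames(d)) d[[j]] <- .asNumericCol(d[[j]], j, "intensity")
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity at sample '%s', metabolite '%s'",
                 rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]),
         call. = FALSE)
  allmiss <- colnames(m)[colSums(!is.na(m)) == 0L]
  if (length(allmiss))
    stop("metabolite(s) with no observed values: ",
         paste(head(allmiss, 5), collapse = ", "), call. = FALSE)
  m
}

#' Read a plain numeric samples x columns matrix
#'
#' Like [readAbundance()] but without the raw-intensity invariants
#' (non-negativity, per-column observation): used for already-standardized
#' matrices, whose z-scores are routinely negative.
#'
#' @param path CSV/TSV file, first column the sample id.
#' @return numeric matrix with sample ids as rownames.
#' @export
readNumericMatrix <- function(path) {
  d <- .readRaw(path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids", call. = FALSE)
  d <- d[, -1, drop = FALSE]
  for (j in colnames(d)) d[[j]] <- .asNumericCol(d[[j]], j, "value")
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @param types optional named character vector of `"continuous"`/`"binary"`
#'   tags (inferred when omitted: 0/1-valued columns are binary).
#' @rdname readStudyTable
#' @export
readPhenotypes <- function(path, types = NULL) {
  d <- .readRaw(path)
  ids <- as.character(d[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ids in phenotype table", call. = FALSE)
  d <- d[, -1, drop = FALSE]
  for (j in colnames(d)) d[[j]] <- .asNumericCol(d[[j]], j, "phenotype value")
  rownames(d) <- ids
  PhenotypeTable(d, types = types)
}

#' @rdname readStudyTable
#' @export
readAnnotations <- function(path) {
  d <- .readRaw(path)
  if (!all(c("metabolite_id", "mz") %in% colnames(d)))
    stop("annotation table needs columns 'metabolite_id' and 'mz'",
         call. = FALSE)
  d$metabolite_id <- as.character(d$metabolite_id)
  d$mz <- .asNumericCol(d$mz, "mz", "m/z value")
  if (anyDuplicated(d$metabolite_id))
    stop("duplicate metabolite ids in annotation table", call. = FALSE)
  bad <- which(!is.finite(d$mz) | d$mz <= 0)
  if (length(bad))
    stop(sprintf("invalid m/z for metabolite '%s': must be finite and > 0",
                 d$metabolite_id[bad[1]]), call. = FALSE)
  d[, c("metabolite_id", "mz")]
}

#' @param panel optional [ModelPanel-class] fixing outcome display order and
#'   families; when omitted, outcomes are ordered by first appearance in the
#'   file and tagged with the `"linear"` family placeholder (families are
#'   irrelevant to plotting precomputed results).
#' @rdname readStudyTable
#' @export
readAssociationGrid <- function(path, panel = NULL) {
  d <- .readRaw(path)
  need <- c("metabolite_id", "mz", "outcome", "beta", "se", "p")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("association table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$metabolite_id <- as.character(d$metabolite_id)
  d$outcome <- as.character(d$outcome)
  for (j in c("mz", "beta", "se", "p"))
    d[[j]] <- .asNumericCol(d[[j]], j, "value")
  if (is.null(panel)) {
    outs <- unique(d$outcome)
    panel <- ModelPanel(lapply(seq_along(outs), function(i)
      ModelSpec(outs[i], "linear", displayIndex = i - 1L)))
  }
  ann <- unique(d[, c("metabolite_id", "mz")])
  if (anyDuplicated(ann$metabolite_id))
    stop("inconsistent mz values for a metabolite id", call. = FALSE)
  AssociationGrid(d[, c("metabolite_id", "outcome", "beta", "se", "p")],
                  annotations = ann, panel = panel)
}

#' Write an association grid as long-format CSV
#'
#' One record per row with columns `metabolite_id`, `mz`, `outcome`,
#' `beta`, `se`, `p`, in canonical grid order. Numbers are printed with 17
#' significant digits so that `readAssociationGrid()` recovers the grid
#' bit-identically.
#'
#' @param grid a valid [AssociationGrid-class].
#' @param path output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
writeAssociationGrid <- function(grid, path) {
  validObject(grid)
  r <- gridRecords(grid)
  ann <- gridAnnotations(grid)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    metabolite_id = r$metabolite_id,
    mz = fmt(ann$mz[match(r$metabolite_id, ann$metabolite_id)]),
    outcome = r$outcome,
    beta = fmt(r$beta), se = fmt(r$se), p = fmt(r$p),
    stringsAsFactors = FALSE)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  write.table(out, con, sep = .delimFor(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
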