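## The three-step LC-MS feature preprocessing chain applied before any
## modeling: quarter-minimum imputation, natural-log transform,
## per-metabolite standardization. Low-level functions operate on the
## on-disk layout (samples as rows, metabolites as columns);
## preprocessStudy() bridges to the transposed MetaboliteStudy container.

#' Impute missing intensities at a quarter of the observed minimum
#'
#' Replaces every missing entry of a metabolite's intensity vector by
#' 0.25 x the minimum observed value for that metabolite — the standard
#' below-detection-limit substitution for LC-MS features, where a missing
#' value most plausibly reflects an intensity below the observed range.
#' Observed entries are never changed. For a matrix, the rule is applied
#' independently to each metabolite column across all samples.
#'
#' @param x numeric vector of one metabolite's intensities, or a
#'   samples x metabolites matrix.
#' @return object of the same shape with no missing values.
#' @examples
#' imputeMissing(c(4, 8, NA))  # -> 4 8 1
#' @export
imputeMissing <- function(x) {
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) {
      x[, j] <- tryCatch(imputeMissing(x[, j]), error = function(e)
        stop(sprintf("metabolite '%s': %s",
                     colnames(x)[j] %||% as.character(j),
                     conditionMessage(e)), call. = FALSE))
    }
    return(x)
  }
  obs <- x[!is.na(x)]
  if (!length(obs))
    stop("all values missing; cannot impute", call. = FALSE)
  m <- min(obs)
  if (m <= 0)
    stop(sprintf(
      "minimum observed value is %g; imputation at 0.25 x minimum requires strictly positive intensities",
      m), call. = FALSE)
  x[is.na(x)] <- 0.25 * m
  x
}

#' Natural-log transform of a complete intensity matrix
#'
#' @param m numeric matrix of strictly positive intensities (run
#'   [imputeMissing()] first).
#' @return `log(m)`, elementwise natural logarithm.
#' @export
logTransform <- function(m) {
  bad <- which(!(m > 0), arr.ind = TRUE)
  if (length(bad)) {
    bad <- rbind(bad)
    stop(sprintf(
      "non-positive or missing value at sample '%s', metabolite '%s': log transform requires strictly positive intensities",
      rownames(m)[bad[1, 1]] %||% bad[1, 1],
      colnames(m)[bad[1, 2]] %||% bad[1, 2]), call. = FALSE)
  }
  log(m)
}

#' Standardize each metabolite to mean 0, SD 1
#'
#' Centers and scales every metabolite column so effect estimates are per
#' 1 SD of log intensity and comparable across metabolites. The default SD
#' uses the sample (n - 1) denominator; `denominator = "n"` selects the
#' population form.
#'
#' @param m samples x metabolites matrix of log intensities.
#' @param denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return matrix of z-scores, same shape and dimnames.
#' @export
standardizeMetabolites <- function(m, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- nrow(m)
  if (n < 2L) stop("standardization requires at least 2 samples",
                   call. = FALSE)
  mu <- colMeans(m)
  ss <- colSums(sweep(m, 2, mu)^2)
  s <- sqrt(ss / (if (denominator == "n-1") n - 1 else n))
  zero <- which(s == 0)
  if (length(zero))
    stop("zero-variance metabolite(s): ",
         paste(head(colnames(m)[zero] %||% zero, 5), collapse = ", "),
         call. = FALSE)
  sweep(sweep(m, 2, mu), 2, s, "/")
}

#' Run the full preprocessing pipeline on an abundance matrix
#'
#' Applies, in order: quarter-minimum imputation, natural-log transform,
#' per-metabolite standardization. Returns the z-score matrix together with
#' a [PreprocessReport-class] recording per-metabolite missing fractions and
#' the imputation constants used. The `reportThreshold` (default 10%
#' missingness) only drives the report's count; metabolites are imputed, not
#' dropped, unless `maxMissingFrac` is set explicitly.
#'
#' @param m samples x metabolites raw intensity matrix with `NA` for
#'   missing.
#' @param sdDenominator passed to [standardizeMetabolites()].
#' @param reportThreshold missingness fraction above which a metabolite is
#'   counted in the report.
#' @param maxMissingFrac optional exclusion cutoff: metabolites with a
#'   missing fraction above it are dropped before imputation. Off (`NULL`)
#'   by default.
#' @return list with elements `matrix` (z-scores) and `report`.
#' @export
preprocessPipeline <- function(m, sdDenominator = c("n-1", "n"),
                               reportThreshold = 0.10,
                               maxMissingFrac = NULL) {
  sdDenominator <- match.arg(sdDenominator)
  frac <- colMeans(is.na(m))
  names(frac) <- colnames(m)
  excluded <- character()
  if (!is.null(maxMissingFrac)) {
    drop <- frac > maxMissingFrac
    excluded <- colnames(m)[drop]
    m <- m[, !drop, drop = FALSE]
    if (!ncol(m))
      stop("all metabolites excluded by maxMissingFrac", call. = FALSE)
  }
  kept <- colnames(m)
  const <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (anyNA(v)) 0.25 * min(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  names(const) <- kept
  z <- standardizeMetabolites(logTransform(imputeMissing(m)),
                              denominator = sdDenominator)
  report <- new("PreprocessReport",
                missingFraction = frac[kept],
                imputationConstant = const,
                threshold = reportThreshold,
                nAboveThreshold = sum(frac[kept] > reportThreshold),
                excluded = excluded)
  list(matrix = z, report = report)
}

#' Preprocess a MetaboliteStudy in place
#'
#' Runs [preprocessPipeline()] on the study's abundance assay and stores the
#' result as a `"zscore"` assay, with the report in
#' `metadata(study)$preprocess`. Metabolites excluded by `maxMissingFrac`
#' (if set) are removed from the study.
#'
#' @param study a [MetaboliteStudy-class].
#' @inheritParams preprocessPipeline
#' @return the updated study.
#' @export
preprocessStudy <- function(study, sdDenominator = c("n-1", "n"),
                            reportThreshold = 0.10, maxMissingFrac = NULL) {
  res <- preprocessPipeline(t(assay(study, "abundance")),
                            sdDenominator = match.arg(sdDenominator),
                            reportThreshold = reportThreshold,
                            maxMissingFrac = maxMissingFrac)
  study <- study[colnames(res$matrix), ]
  assay(study, "zscore") <- t(res$matrix)
  metadata(study)$preprocess <- res$report
  study
}

#' Retrieve the preprocessing report of a study
#'
#' @param study a [MetaboliteStudy-class] processed by [preprocessStudy()].
#' @return the [PreprocessReport-class], or `NULL` if the study has not
#'   been preprocessed.
#' @export
preprocessReport <- function(study) metadata(study)$preprocess
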