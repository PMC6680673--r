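## Per-(metabolite, outcome) regression fits, written from first principles:
## OLS via Cholesky on the normal equations, logistic MLE via iteratively
## reweighted least squares with observed-information standard errors.
## stats::lm / stats::glm are used only as independent oracles in the tests.

.designMatrix <- function(x, covariates) {
  X <- cbind(`(intercept)` = 1, metabolite = x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  X
}

.checkDesign <- function(X) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k)
    stop(sprintf("need more samples (%d) than coefficients (%d)", n, k),
         call. = FALSE)
  if (qr(X)$rank < k)
    stop("rank-deficient design matrix (collinear exposure/covariates)",
         call. = FALSE)
  invisible(NULL)
}

.completeCases <- function(y, x, covariates) {
  ok <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) ok <- ok & complete.cases(as.matrix(covariates))
  ok
}

#' Linear association of one metabolite with a continuous outcome
#'
#' Ordinary least squares of `outcome ~ intercept + metabolite +
#' covariates`, solved on the normal equations via a Cholesky
#' factorization. Returns the metabolite coefficient with its classical
#' (homoskedastic) standard error and a two-sided P value from the t
#' distribution on n - k degrees of freedom. Rows with a missing outcome,
#' exposure, or covariate are dropped (per-model complete-case analysis).
#'
#' @param y continuous outcome vector.
#' @param x standardized metabolite vector (exposure).
#' @param covariates optional numeric matrix or data.frame of adjustment
#'   covariates.
#' @return list with `beta`, `se`, `p` (for the metabolite term),
#'   `coefficients` (the full named coefficient vector), `nUsed`,
#'   `converged` (always `TRUE`), `iterations` (0).
#' @examples
#' fitLinear(c(2, 4, 6, 8), c(1, 2, 3, 4))$beta  # exactly 2
#' @export
fitLinear <- function(y, x, covariates = NULL) {
  stopifnot(length(y) == length(x))
  ok <- .completeCases(y, x, covariates)
  y <- y[ok]; x <- x[ok]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  X <- .designMatrix(x, covariates)
  .checkDesign(X)
  n <- nrow(X); k <- ncol(X)
  R <- chol(crossprod(X))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (n - k)
  vcov <- sigma2 * chol2inv(R)
  se <- sqrt(vcov[2, 2])
  tstat <- beta[2] / se
  list(beta = beta[2], se = se,
       p = 2 * pt(-abs(tstat), df = n - k),
       coefficients = setNames(drop(beta), colnames(X)),
       nUsed = n, converged = TRUE, iterations = 0L)
}

#' Logistic association of one metabolite with a binary outcome
#'
#' Maximum-likelihood logistic regression of a 0/1 outcome on `intercept +
#' metabolite + covariates`, fitted by iteratively reweighted least squares.
#' Convergence is declared when the largest absolute coefficient change
#' falls below `tol` (default 1e-8) within `maxIter` (default 100)
#' iterations. Standard errors come from the inverse observed information at
#' the optimum; P values are two-sided Wald. Non-convergence — including
#' (quasi-)complete separation — returns a flagged record with `beta`, `se`
#' and `p` set to `NA` and a warning, so the record keeps its place in the
#' grid but is excluded from plots.
#'
#' @inheritParams fitLinear
#' @param y binary 0/1 outcome; both classes must be present.
#' @param maxIter,tol IRLS iteration cap and coefficient-change tolerance.
#' @return list with `beta`, `se`, `p`, `coefficients`, `nUsed`,
#'   `converged`, `iterations`.
#' @export
fitLogistic <- function(y, x, covariates = NULL, maxIter = 100L,
                        tol = 1e-8) {
  stopifnot(length(y) == length(x))
  ok <- .completeCases(y, x, covariates)
  y <- y[ok]; x <- x[ok]
  if (!is.null(covariates))
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
  if (!all(y %in% c(0, 1)))
    stop("logistic outcome must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic model is undefined",
         call. = FALSE)
  X <- .designMatrix(x, covariates)
  .checkDesign(X)
  n <- nrow(X); k <- ncol(X)

  beta <- numeric(k)
  converged <- FALSE
  iter <- 0L
  failed <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    R <- tryCatch(chol(XtW %*% X), error = function(e) NULL)
    if (is.null(R)) { failed <- TRUE; break }
    betaNew <- backsolve(R, forwardsolve(t(R), XtW %*% z))
    if (any(!is.finite(betaNew))) { failed <- TRUE; break }
    delta <- max(abs(betaNew - beta))
    beta <- drop(betaNew)
    if (delta < tol) { converged <- TRUE; break }
  }

  if (!converged || failed) {
    warning("logistic fit did not converge in ", iter,
            " iterations (possible separation); record flagged",
            call. = FALSE)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                nUsed = n, converged = FALSE, iterations = iter))
  }
  mu <- plogis(drop(X %*% beta))
  w <- mu * (1 - mu)
  info <- t(X * w) %*% X
  vcov <- chol2inv(chol(info))
  se <- sqrt(vcov[2, 2])
  zstat <- beta[2] / se
  list(beta = beta[2], se = se, p = 2 * pnorm(-abs(zstat)),
       coefficients = setNames(beta, colnames(X)),
       nUsed = n, converged = TRUE, iterations = iter)
}

#' The default Framingham-style outcome panel
#'
#' Eight demographic and clinical outcome models in the fixed clinical
#' display order used throughout the package's figures: age, female sex,
#' body mass index, metabolic syndrome, prevalent diabetes, incident
#' diabetes, Framingham Risk Score, and incident hard cardiovascular
#' disease. Age, BMI and the risk score are continuous (linear models); the
#' other five are binary (logistic models). Every model except the age and
#' female-sex models adjusts for age and female sex; the age model adjusts
#' for sex and vice versa.
#'
#' @return a [ModelPanel-class] of eight [ModelSpec-class]s.
#' @examples
#' outcomeNames(framinghamPanel())
#' @export
framinghamPanel <- function() {
  def <- list(
    list("age", "linear", c("female_sex")),
    list("female_sex", "logistic", c("age")),
    list("bmi", "linear", c("age", "female_sex")),
    list("metabolic_syndrome", "logistic", c("age", "female_sex")),
    list("prevalent_diabetes", "logistic", c("age", "female_sex")),
    list("incident_diabetes", "logistic", c("age", "female_sex")),
    list("framingham_risk_score", "linear", c("age", "female_sex")),
    list("incident_hard_cvd", "logistic", c("age", "female_sex")))
  ModelPanel(lapply(seq_along(def), function(i)
    ModelSpec(def[[i]][[1]], def[[i]][[2]], def[[i]][[3]],
              displayIndex = i - 1L)))
}

.fitOne <- function(spec, y, x, covariates) {
  if (spec@family == "linear") fitLinear(y, x, covariates)
  else fitLogistic(y, x, covariates)
}

#' Fit every (metabolite, outcome) model and assemble the grid
#'
#' For each outcome model in the panel and each metabolite, fits the
#' regression of the outcome on the standardized metabolite plus the
#' model's covariates, and collects the results into a complete
#' [AssociationGrid-class]. Analysis is complete-case per model: samples
#' missing that model's outcome or covariates are dropped for that model
#' only. A failing fit aborts with the (metabolite, outcome) pair named
#' unless `skipFailures = TRUE`, in which case the record is kept flagged
#' with missing estimates.
#'
#' @param x a [MetaboliteStudy-class] carrying a `"zscore"` assay (see
#'   [preprocessStudy()]), or a samples x metabolites z-score matrix.
#' @param phenotypes a [PhenotypeTable-class]; ignored (taken from the
#'   study) when `x` is a `MetaboliteStudy`.
#' @param panel a [ModelPanel-class]; default [framinghamPanel()].
#' @param annotations data.frame `metabolite_id`, `mz`; ignored when `x`
#'   is a study.
#' @param skipFailures keep flagged `NA` records instead of aborting on a
#'   fit error.
#' @return an [AssociationGrid-class].
#' @export
buildGrid <- function(x, phenotypes = NULL, panel = framinghamPanel(),
                      annotations = NULL, skipFailures = FALSE) {
  if (is(x, "MetaboliteStudy")) {
    if (!("zscore" %in% assayNames(x)))
      stop("study has no 'zscore' assay; run preprocessStudy() first",
           call. = FALSE)
    z <- t(assay(x, "zscore"))
    phenotypes <- PhenotypeTable(
      as.data.frame(colData(x)), types = variableTypes(x))
    annotations <- data.frame(metabolite_id = metaboliteIds(x),
                              mz = unname(mzValues(x)),
                              stringsAsFactors = FALSE)
  } else {
    z <- as.matrix(x)
  }
  stopifnot(is(phenotypes, "PhenotypeTable"), !is.null(annotations))
  pd <- as.data.frame(phenotypes)
  common <- intersect(rownames(z), rownames(pd))
  if (!length(common))
    stop("no samples shared between z-score matrix and phenotypes",
         call. = FALSE)
  z <- z[common, , drop = FALSE]
  pd <- pd[common, , drop = FALSE]

  mids <- colnames(z)
  specs <- panel@specs
  out <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    if (!(spec@outcome %in% colnames(pd)))
      stop("outcome '", spec@outcome, "' not found in phenotype table",
           call. = FALSE)
    missCov <- setdiff(spec@covariates, colnames(pd))
    if (length(missCov))
      stop("covariate(s) not found for model '", spec@outcome, "': ",
           paste(missCov, collapse = ", "), call. = FALSE)
    y <- pd[[spec@outcome]]
    covs <- if (length(spec@covariates))
      as.matrix(pd[, spec@covariates, drop = FALSE]) else NULL
    rows <- vector("list", length(mids))
    for (j in seq_along(mids)) {
      fit <- tryCatch(
        withCallingHandlers(
          .fitOne(spec, y, z[, j], covs),
          warning = function(w) {
            message(sprintf("metabolite '%s', outcome '%s': %s",
                            mids[j], spec@outcome, conditionMessage(w)))
            invokeRestart("muffleWarning")
          }),
        error = function(e) e)
      if (inherits(fit, "error")) {
        if (!skipFailures)
          stop(sprintf("fit failed for metabolite '%s', outcome '%s': %s",
                       mids[j], spec@outcome, conditionMessage(fit)),
               call. = FALSE)
        fit <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                    nUsed = NA_integer_, converged = FALSE,
                    iterations = NA_integer_)
      }
      rows[[j]] <- data.frame(
        metabolite_id = mids[j], outcome = spec@outcome,
        beta = fit$beta, se = fit$se, p = fit$p,
        n_used = as.integer(fit$nUsed), converged = fit$converged,
        stringsAsFactors = FALSE)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  AssociationGrid(do.call(rbind, out), annotations = annotations,
                  panel = panel)
}
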