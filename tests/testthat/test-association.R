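test_that("linear fit recovers an exact linear relation", {
  fit <- fitLinear(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(fit$beta, 2.0, tolerance = 1e-12)
  expect_equal(fit$se, 0.0, tolerance = 1e-12)
  expect_identical(fit$nUsed, 4L)
})

test_that("linear fit matches the lm oracle on random full-rank designs", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    k <- sample(0:3, 1)
    x <- rnorm(n)
    C <- if (k) matrix(rnorm(n * k), n) else NULL
    y <- rnorm(n) + 0.3 * x
    fit <- fitLinear(y, x, C)
    ref <- if (k) summary(stats::lm(y ~ x + C)) else summary(stats::lm(y ~ x))
    expect_equal(fit$beta, unname(ref$coefficients["x", 1]),
                 tolerance = 1e-10)
    expect_equal(fit$se, unname(ref$coefficients["x", 2]), tolerance = 1e-10)
    expect_equal(fit$p, unname(ref$coefficients["x", 4]), tolerance = 1e-10)
  }
})

test_that("under the null, |beta| stays within 3 SEs almost always", {
  set.seed(202)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(200); y <- rnorm(200)
    fit <- fitLinear(y, x)
    abs(fit$beta) < 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("collinear designs and undersized samples are rejected", {
  x <- rnorm(10)
  expect_error(fitLinear(rnorm(10), x, cbind(x)), "rank-deficient")
  expect_error(fitLinear(rnorm(3), rnorm(3), cbind(rnorm(3), rnorm(3))),
               "more samples")
})

test_that("per-model complete cases drop only rows missing that model's variables", {
  y <- c(1, 2, NA, 4, 5, 6)
  x <- rnorm(6)
  fit <- fitLinear(y, x)
  expect_identical(fit$nUsed, 5L)
  covs <- cbind(c(0, NA, 1, 1, 0, 1))
  expect_identical(fitLinear(y, x, covs)$nUsed, 4L)
})

test_that("logistic fit is zero when outcome is exactly balanced within x", {
  fit <- fitLogistic(c(0, 1, 0, 1), c(-1, -1, 1, 1))
  expect_lt(abs(fit$beta), 1e-8)
  expect_true(fit$converged)
})

test_that("logistic fit matches independent maximizers of the log-likelihood", {
  set.seed(303)
  for (rep in 1:10) {
    n <- 40
    x <- rnorm(n)
    C <- matrix(rnorm(n), n)
    y <- rbinom(n, 1, plogis(0.2 + 0.8 * x - 0.5 * C[, 1]))
    if (length(unique(y)) < 2) next
    fit <- fitLogistic(y, x, C)
    if (!fit$converged) next
    # oracle 1: direct numerical maximization of the written log-likelihood
    X <- cbind(1, x, C)
    nll <- function(b) {
      eta <- drop(X %*% b)
      -sum(y * eta - log1p(exp(eta)))
    }
    opt <- stats::optim(rep(0, 3), nll, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-14))
    expect_equal(fit$beta, opt$par[2], tolerance = 1e-5)
    expect_equal(fit$se, sqrt(solve(opt$hessian)[2, 2]), tolerance = 1e-4)
    # oracle 2: glm, converged well past the comparison tolerance
    ref <- summary(stats::glm(y ~ x + C, family = stats::binomial(),
                              control = stats::glm.control(epsilon = 1e-12)))
    expect_equal(fit$beta, unname(ref$coefficients["x", 1]),
                 tolerance = 1e-6)
    expect_equal(fit$se, unname(ref$coefficients["x", 2]), tolerance = 1e-6)
  }
})

test_that("the score gradient vanishes at the returned optimum", {
  set.seed(404)
  for (rep in 1:20) {
    n <- 80
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.4 * x))
    fit <- fitLogistic(y, x)
    expect_true(fit$converged)
    # recompute the score at the returned coefficients from scratch
    Xf <- cbind(1, x)
    mu <- plogis(drop(Xf %*% fit$coefficients))
    score <- crossprod(Xf, y - mu)
    expect_lt(max(abs(score)), 1e-6)
  }
})

test_that("perfectly separated data are flagged, not reported", {
  x <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(fit <- fitLogistic(y, x), "did not converge")
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
})

test_that("single-class outcomes and miscoded outcomes error", {
  expect_error(fitLogistic(rep(1, 10), rnorm(10)), "single class")
  expect_error(fitLogistic(c(0, 1, 2, 1), rnorm(4)), "coded 0/1")
})

test_that("fits are invariant to sample permutation", {
  set.seed(505)
  n <- 100
  x <- rnorm(n); yc <- rnorm(n) + 0.4 * x
  yb <- rbinom(n, 1, plogis(0.5 * x))
  C <- matrix(rnorm(2 * n), n)
  perm <- sample(n)
  f1 <- fitLinear(yc, x, C)
  f2 <- fitLinear(yc[perm], x[perm], C[perm, ])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
  g1 <- fitLogistic(yb, x)
  g2 <- fitLogistic(yb[perm], x[perm])
  expect_equal(g1$beta, g2$beta, tolerance = 1e-12)
})

test_that("the default panel is the eight-outcome clinical ordering", {
  panel <- framinghamPanel()
  expect_identical(length(panel), 8L)
  expect_identical(outcomeNames(panel)[1:3], c("age", "female_sex", "bmi"))
  # age/sex adjust for each other; other models adjust for both
  expect_identical(panel[["bmi"]]@covariates, c("age", "female_sex"))
  expect_identical(panel[["age"]]@covariates, "female_sex")
  expect_identical(panel[["incident_hard_cvd"]]@family, "logistic")
})

test_that("buildGrid returns a complete grid in panel order", {
  st <- generateStudy(SyntheticDesign(nSamples = 120, nMetabolites = 10,
                                      seed = 11))
  st <- preprocessStudy(st)
  g <- suppressMessages(buildGrid(st, skipFailures = TRUE))
  expect_identical(dim(g), c(10L, 8L))
  expect_identical(nrow(gridRecords(g)), 80L)
  expect_identical(outcomeNames(g), outcomeNames(framinghamPanel()))
})

test_that("grid estimates recover a planted effect and shrink bias with n", {
  planted <- data.frame(metabolite = "met_001", outcome = "age", beta = 0.5)
  panel <- ModelPanel(list(ModelSpec("age", "linear", displayIndex = 0L)))
  est <- function(n, seed) {
    d <- SyntheticDesign(nSamples = n, nMetabolites = 5, missingRate = 0,
                         plantedEffects = planted, panel = panel,
                         seed = seed)
    st <- preprocessStudy(generateStudy(d))
    r <- gridRecords(buildGrid(st, panel = panel))
    r$beta[r$metabolite_id == "met_001"]
  }
  b200 <- vapply(1:40, function(s) est(200, s), numeric(1))
  b2000 <- vapply(1:40, function(s) est(2000, 100 + s), numeric(1))
  expect_lt(abs(mean(b2000) - 0.5), abs(mean(b200) - 0.5) + 0.02)
  expect_lt(abs(mean(b2000) - 0.5), 0.02)
})

test_that("a failing fit names the pair unless failures are skipped", {
  set.seed(12)
  z <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("s%d", 1:20), c("mA", "mB")))
  pheno <- data.frame(bad = rep(1, 20), row.names = sprintf("s%d", 1:20))
  pt <- PhenotypeTable(pheno, types = c(bad = "binary"))
  panel <- ModelPanel(list(ModelSpec("bad", "logistic", displayIndex = 0L)))
  ann <- data.frame(metabolite_id = c("mA", "mB"), mz = c(300, 400))
  expect_error(buildGrid(z, pt, panel, ann), "mA.*bad|bad.*mA")
  g <- buildGrid(z, pt, panel, ann, skipFailures = TRUE)
  expect_identical(nrow(gridRecords(g)), 2L)
  expect_true(all(!gridRecords(g)$converged))
})
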