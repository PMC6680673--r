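test_that("the same seed reproduces a study exactly", {
  d <- SyntheticDesign(nSamples = 50, nMetabolites = 12, seed = 99)
  s1 <- generateStudy(d)
  s2 <- generateStudy(d)
  expect_identical(SummarizedExperiment::assay(s1, "abundance"),
                   SummarizedExperiment::assay(s2, "abundance"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(s1)),
                   as.data.frame(SummarizedExperiment::colData(s2)))
  expect_identical(mzValues(s1), mzValues(s2))
  s3 <- generateStudy(SyntheticDesign(nSamples = 50, nMetabolites = 12,
                                      seed = 100))
  expect_false(identical(SummarizedExperiment::assay(s1, "abundance"),
                         SummarizedExperiment::assay(s3, "abundance")))
})

test_that("observed missingness matches the designed rates", {
  rates <- c(rep(0.15, 20), rep(0, 80))
  d <- SyntheticDesign(nSamples = 1500, nMetabolites = 100,
                       missingRate = rates, seed = 7)
  st <- generateStudy(d)
  frac <- rowMeans(is.na(SummarizedExperiment::assay(st, "abundance")))
  expect_true(all(abs(frac[1:20] - 0.15) <= 0.05))
  expect_true(all(frac[21:100] == 0))
})

test_that("left-censored missingness removes the low tail", {
  d <- SyntheticDesign(nSamples = 200, nMetabolites = 5, missingRate = 0.2,
                       missingMode = "left_censored", seed = 8)
  st <- generateStudy(d)
  a <- SummarizedExperiment::assay(st, "abundance")
  for (j in 1:5) {
    v <- a[j, ]
    expect_true(min(v, na.rm = TRUE) > 0)
    # every observed value exceeds what was censored by construction:
    # the 20% quantile of the complete column was the cutoff
    expect_equal(unname(mean(is.na(v))), 0.2, tolerance = 0.01)
  }
  # the quarter-minimum rule still imputes below the observed minimum
  imp <- imputeMissing(t(a))
  mins <- apply(t(a), 2, min, na.rm = TRUE)
  for (j in 1:5)
    expect_equal(unname(min(imp[, j])), unname(0.25 * mins[j]))
})

test_that("a design with no planted effects yields only null associations", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    d <- SyntheticDesign(nSamples = 150, nMetabolites = 40,
                         missingRate = 0, seed = seed,
                         panel = ModelPanel(list(
                           ModelSpec("age", "linear", displayIndex = 0L))))
    st <- preprocessStudy(generateStudy(d))
    g <- buildGrid(st, panel = ModelPanel(list(
      ModelSpec("age", "linear", displayIndex = 0L))))
    r <- gridRecords(g)
    hits <- hits + sum(abs(r$beta) < 4 * r$se)
    total <- total + nrow(r)
  }
  expect_gte(hits / total, 0.99)
})

test_that("planted-effect validation rejects unknown references", {
  expect_error(generateStudy(SyntheticDesign(
    nSamples = 20, nMetabolites = 3, seed = 1,
    plantedEffects = data.frame(metabolite = "met_999", outcome = "age",
                                beta = 0.5))), "unknown metabolite")
  expect_error(generateStudy(SyntheticDesign(
    nSamples = 20, nMetabolites = 3, seed = 1,
    plantedEffects = data.frame(metabolite = "met_001", outcome = "nope",
                                beta = 0.5))), "unknown outcome")
})

test_that("the desk-scale default mirrors the motivating study's shape", {
  d <- fixtureCohortShape()
  expect_identical(length(d@panel), 8L)
  expect_identical(outcomeNames(d@panel)[1:2], c("age", "female_sex"))
  expect_identical(d@nMetabolites, 500L)
  expect_identical(d@mzRange, c(225, 650))
  # 16% of metabolites carry the high missingness rate
  expect_identical(sum(d@missingRate > 0.10), 80L)
  st <- generateStudy(SyntheticDesign(
    nSamples = 50, nMetabolites = 30, mzRange = d@mzRange, seed = 5))
  mz <- mzValues(st)
  expect_true(all(mz > 225 & mz < 650))
})

test_that("binary outcomes respect their baseline prevalences", {
  d <- SyntheticDesign(nSamples = 4000, nMetabolites = 2, seed = 17,
                       binaryPrevalence = c(prevalent_diabetes = 0.1))
  st <- generateStudy(d)
  pd <- as.data.frame(SummarizedExperiment::colData(st))
  expect_lt(abs(mean(pd$prevalent_diabetes) - 0.1), 0.03)
  expect_lt(abs(mean(pd$female_sex) - 0.5), 0.05)
  expect_identical(unname(variableTypes(st)[c("age", "female_sex")]),
                   c("continuous", "binary"))
})

test_that("writeStudy emits the four readable tables", {
  d <- SyntheticDesign(nSamples = 25, nMetabolites = 6, seed = 2,
                       plantedEffects = data.frame(
                         metabolite = "met_001", outcome = "bmi",
                         beta = 0.4))
  st <- generateStudy(d)
  dir <- withr::local_tempdir()
  paths <- writeStudy(st, file.path(dir, "study_"))
  ab <- readAbundance(paths[["abundance"]])
  expect_identical(dim(ab), c(25L, 6L))
  pt <- readPhenotypes(paths[["phenotypes"]])
  expect_identical(length(sampleIds(pt)), 25L)
  ann <- readAnnotations(paths[["annotations"]])
  expect_identical(ann$metabolite_id, metaboliteIds(st))
  st2 <- MetaboliteStudy(ab, pt, ann)
  expect_equal(SummarizedExperiment::assay(st2, "abundance"),
               SummarizedExperiment::assay(st, "abundance"))
  expect_identical(truthTable(st)$metabolite, "met_001")
})
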