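test_that("abundance tables parse with missing markers and fail on bad cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,metA,metB",
               "s1,4.0,2.5",
               "s2,NA,3.0",
               "s3,8.0,"), p)
  m <- readAbundance(p)
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(sum(is.na(m)), 2L)
  expect_identical(m["s1", "metA"], 4.0)

  writeLines(c("sample_id,metA", "s1,4.0", "s1,5.0"), p)
  expect_error(readAbundance(p), "duplicate sample ids")

  writeLines(c("sample_id,metA", "s1,four"), p)
  expect_error(readAbundance(p), "non-numeric intensity.*metA.*row 1")

  writeLines(c("sample_id,metA", "s1,-2"), p)
  expect_error(readAbundance(p), "negative intensity")

  writeLines(c("sample_id,metA,metB", "s1,NA,1", "s2,,2"), p)
  expect_error(readAbundance(p), "no observed values.*metA")
})

test_that("TSV extension switches the delimiter", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tmetA", "s1\t4"), p)
  expect_identical(readAbundance(p)["s1", "metA"], 4)
  px <- withr::local_tempfile(fileext = ".xlsx")
  writeLines("sample_id,metA", px)
  expect_error(readAbundance(px), "delimiter")
})

test_that("phenotype reader tags variables and enforces binary coding", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,age,diabetes", "s1,60,0", "s2,70,1", "s3,55,NA"), p)
  pt <- readPhenotypes(p)
  expect_s4_class(pt, "PhenotypeTable")
  expect_identical(unname(variableTypes(pt)[c("age", "diabetes")]),
                   c("continuous", "binary"))
  expect_error(
    readPhenotypes(p, types = c(age = "continuous", diabetes = "continuous")),
    NA)
  writeLines(c("sample_id,diabetes", "s1,2", "s2,0"), p)
  expect_error(readPhenotypes(p, types = c(diabetes = "binary")),
               "outside \\{0, 1\\}")
})

test_that("annotation reader rejects non-positive m/z and duplicates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite_id,mz", "m1,400.2", "m2,250.1"), p)
  ann <- readAnnotations(p)
  expect_identical(ann$mz, c(400.2, 250.1))
  writeLines(c("metabolite_id,mz", "m1,-5"), p)
  expect_error(readAnnotations(p), "finite and > 0")
  writeLines(c("metabolite_id,mz", "m1,400", "m1,401"), p)
  expect_error(readAnnotations(p), "duplicate metabolite ids")
})

test_that("association grids must be complete and valid on read", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite_id,mz,outcome,beta,se,p",
               "m1,400,age,0.5,0.1,0.01",
               "m1,400,bmi,0.2,0.1,0.3",
               "m2,300,age,-0.1,0.2,0.8"), p)
  expect_error(readAssociationGrid(p), "incomplete")
  writeLines(c("metabolite_id,mz,outcome,beta,se,p",
               "m1,400,age,0.5,0.1,0.01",
               "m1,400,bmi,0.2,0.1,0.3",
               "m2,300,age,-0.1,0.2,0.8",
               "m2,300,bmi,0.0,0.2,1.0"), p)
  g <- readAssociationGrid(p)
  expect_identical(dim(g), c(2L, 2L))
  # outcome order follows first appearance when no panel is given
  expect_identical(outcomeNames(g), c("age", "bmi"))
})

test_that("grid writing refuses invalid records", {
  g <- randomGrid(2, 2, seed = 3)
  g@records$p[1] <- 0
  expect_error(writeAssociationGrid(g, tempfile(fileext = ".csv")),
               "P values")
})

test_that("write/read round-trips random grids bit-identically", {
  for (seed in 1:10) {
    g <- randomGrid(nMet = 5, nOut = 3, seed = seed)
    p <- withr::local_tempfile(fileext = ".csv")
    writeAssociationGrid(g, p)
    g2 <- readAssociationGrid(p, panel = modelPanel(g))
    expect_identical(gridRecords(g2)[, c("metabolite_id", "outcome")],
                     gridRecords(g)[, c("metabolite_id", "outcome")])
    expect_identical(gridRecords(g2)$beta, gridRecords(g)$beta)
    expect_identical(gridRecords(g2)$se, gridRecords(g)$se)
    expect_identical(gridRecords(g2)$p, gridRecords(g)$p)
    expect_identical(gridAnnotations(g2)$mz, gridAnnotations(g)$mz)
  }
})

test_that("a written grid has one row per (metabolite, outcome) pair", {
  g <- randomGrid(2, 3, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  writeAssociationGrid(g, p)
  expect_identical(length(readLines(p)), 7L)  # header + 2 x 3
})

test_that("grid constructor rejects duplicate and mismatched records", {
  g <- randomGrid(3, 2, seed = 2)
  rec <- gridRecords(g)
  expect_error(AssociationGrid(rec[-1, ], gridAnnotations(g), modelPanel(g)),
               "incomplete")
  rec2 <- rec
  rec2$outcome[1] <- rec2$outcome[2]
  expect_error(
    AssociationGrid(rec2, gridAnnotations(g), modelPanel(g)),
    "exactly once|incomplete")
})

test_that("readStudyTable dispatches on schema", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("metabolite_id,mz", "m1,400.2"), p)
  expect_identical(readStudyTable(p, "annotation")$mz, 400.2)
})
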