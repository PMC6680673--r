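test_that("the significance transform is -log10 with a cap", {
  expect_equal(negLog10P(0.01), 2.0)
  expect_equal(negLog10P(1.0), 0.0)
  expect_equal(negLog10P(1e-320), 300.0)
  expect_equal(negLog10P(1e-10, cap = 5), 5)
  expect_error(negLog10P(0), "out of")
  expect_error(negLog10P(1.5), "out of")
})

test_that("rain plot models are complete, monotone, and sign-faithful", {
  g <- randomGrid(3, 8, seed = 31)
  m <- buildRainPlotModel(g)
  expect_identical(nrow(m@cells), 24L)
  expect_identical(length(m@rows) * length(m@cols), 24L)
  # radius is monotone in -log10(p): order by radius_value matches radius
  o <- order(m@cells$radius_value)
  expect_true(all(diff(m@cells$radius[o]) >= -1e-12))
  # equal p implies equal radius
  r <- gridRecords(g); r$p[] <- 0.02
  g2 <- AssociationGrid(r, gridAnnotations(g), modelPanel(g))
  m2 <- buildRainPlotModel(g2)
  expect_equal(diff(range(m2@cells$radius)), 0)
  # fill sign equals beta sign (cells keep record order)
  expect_identical(sign(m@cells$fill_value), sign(gridRecords(g)$beta))
})

test_that("smaller P gives a strictly larger droplet", {
  g <- gridFromPvalues(c(0.01, 0.5))
  m <- buildRainPlotModel(g)
  r1 <- m@cells$radius[m@cells$metabolite_id == "m01"]
  r2 <- m@cells$radius[m@cells$metabolite_id == "m02"]
  expect_gt(r1, r2)
})

test_that("area mode also maps significance monotonically", {
  g <- randomGrid(4, 3, seed = 32)
  m <- buildRainPlotModel(g, sizeMode = "area")
  o <- order(m@cells$radius_value)
  expect_true(all(diff(m@cells$radius[o]) >= -1e-12))
  # area, not radius, is linear in the capped significance
  a <- m@cells$radius^2
  t <- pmin(m@cells$radius_value, m@cap) / m@cap
  rr <- m@radiusRange
  expect_equal(a, rr[1]^2 + (rr[2]^2 - rr[1]^2) * t, tolerance = 1e-12)
})

test_that("color limits are symmetric and clipping respects them", {
  g <- randomGrid(5, 2, seed = 33)
  m <- buildRainPlotModel(g, colorLimit = 0.2)
  expect_identical(m@colorLimits, c(-0.2, 0.2))
  expect_true(all(abs(m@cells$fill_value) <= 0.2))
  # symmetric encoding: betas +/- b sit equidistant from the midpoint,
  # and a zero beta sits exactly at it
  B <- matrix(c(1, -1, 0.5, -0.5, 0, 0), 2, 3)
  gs <- gridFromBetas(B)
  ms <- buildRainPlotModel(gs)
  cells <- ms@cells
  byPair <- tapply(cells$fill_value, abs(cells$fill_value), sum)
  expect_true(all(abs(byPair) < 1e-12))
  expect_identical(cells$fill_value[cells$outcome == "out3"], c(0, 0))
})

test_that("row reordering moves cells but never re-encodes them", {
  g <- randomGrid(6, 3, seed = 34)
  m1 <- buildRainPlotModel(g)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  m2 <- buildRainPlotModel(g, rowOrder = perm)
  key <- function(m) m@cells[order(m@cells$metabolite_id, m@cells$outcome),
                             c("fill_value", "radius_value", "radius")]
  expect_equal(key(m2), key(m1), ignore_attr = TRUE)
  expect_identical(m2@rows, m1@rows[perm])
  expect_error(buildRainPlotModel(g, rowOrder = c(1L, 1L, 2L, 3L, 4L, 5L)),
               "permutation")
})

test_that("rows follow the requested order top to bottom", {
  g <- gridFromPvalues(c(0.5, 0.001, 0.1))
  ord <- orderByPvalue(g)
  m <- buildRainPlotModel(g, rowOrder = ord)
  expect_identical(m@rows, c("m02", "m03", "m01"))
  expect_identical(m@cells$row[m@cells$metabolite_id == "m02"], 1L)
})

test_that("Manhattan models facet in panel order with shared y limits", {
  g <- randomGrid(10, 8, seed = 35)
  m <- buildManhattanModel(g)
  expect_identical(m@facets, outcomeNames(g))
  expect_identical(nrow(m@points), 80L)
  counts <- table(m@points$outcome)
  expect_true(all(counts == 10))
  expect_equal(m@yLimits[2],
               max(c(m@points$y, m@thresholdLine)))
  expect_identical(sort(unique(m@points$direction)),
                   sort(unique(sign(gridRecords(g)$beta))))
})

test_that("the Bonferroni threshold line follows alpha / m", {
  g <- randomGrid(500, 1, seed = 36)
  m <- buildManhattanModel(g, alpha = 0.05)
  expect_equal(m@thresholdLine, 4.0)
  expect_equal(buildManhattanModel(g, alpha = 0.05,
                                   bonferroni = FALSE)@thresholdLine,
               -log10(0.05))
})

test_that("bar-and-scatter models align bars and dots per metabolite", {
  g <- randomGrid(50, 3, seed = 37)
  m <- buildBarScatterModel(g, "out2")
  expect_identical(nrow(m@data), 50L)
  expect_identical(m@outcome, "out2")
  r <- gridRecords(g)
  ref <- r[r$outcome == "out2", ]
  expect_equal(m@data$beta,
               ref$beta[match(m@data$metabolite_id, ref$metabolite_id)])
  neg <- which(m@data$beta < 0)
  expect_true(length(neg) > 0)  # sign is preserved, bars extend negative
  expect_error(buildBarScatterModel(g, "height"), "not in the panel")
})

test_that("paired heatmaps stay aligned under any row order", {
  g <- randomGrid(4, 2, seed = 38)
  m <- buildPairedHeatmapModel(g)
  expect_identical(dim(m@fillsBeta), dim(m@fillsP))
  expect_identical(dimnames(m@fillsBeta), dimnames(m@fillsP))
  rev_ <- buildPairedHeatmapModel(g, rowOrder = 4:1)
  expect_identical(rev_@fillsBeta, m@fillsBeta[4:1, ])
  expect_identical(rev_@fillsP, m@fillsP[4:1, ])
})

test_that("paired heatmap beta limits are the symmetric max |beta|", {
  B <- matrix(c(1, 0.5, -1, -0.5), 2, 2)
  g <- gridFromBetas(B)
  m <- buildPairedHeatmapModel(g)
  expect_equal(m@colorLimits, c(-1, 1))
  expect_equal(m@pLimits[1], 0)
})

test_that("the models expose the documented dimensions of information", {
  g <- randomGrid(4, 3, seed = 39)
  rain <- buildRainPlotModel(g)
  # rain plot: magnitude + direction (fill) and significance (radius) for
  # multiple outcomes in one object
  expect_true(all(c("fill_value", "radius_value") %in% colnames(rain@cells)))
  expect_gt(length(rain@cols), 1L)
  # Manhattan: significance + direction but no magnitude channel
  man <- buildManhattanModel(g)
  expect_true(all(c("y", "direction") %in% colnames(man@points)))
  expect_false(any(c("beta", "magnitude", "fill_value") %in%
                   colnames(man@points)))
  # paired heatmaps: two matrices required to carry what rain carries in one
  ph <- buildPairedHeatmapModel(g)
  expect_identical(length(c("fillsBeta", "fillsP")), 2L)
  expect_false(identical(ph@fillsBeta, ph@fillsP))
})

test_that("non-converged records are excluded from plots with a warning", {
  g <- randomGrid(3, 2, seed = 40)
  r <- gridRecords(g)
  r$beta[1] <- NA; r$se[1] <- NA; r$p[1] <- NA; r$converged[1] <- FALSE
  g2 <- AssociationGrid(r, gridAnnotations(g), modelPanel(g))
  expect_warning(m <- buildRainPlotModel(g2), "non-converged")
  expect_identical(nrow(m@cells), 5L)
})
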