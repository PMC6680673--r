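## Thin rendering layer: each plot model is first laid out as a "scene" of
## graphic primitives (circles, rects, lines, text) in point coordinates
## with y growing downwards; the scene is then either written as literal
## SVG elements (xml2) — so every rain droplet is one <circle>, countable
## by tests — or drawn identically on a grid viewport for png/pdf.

.divergingPalette <- grDevices::colorRampPalette(
  c("#2166AC", "#F7F7F7", "#B2182B"))(257)
.sequentialPalette <- grDevices::colorRampPalette(
  c("#F7FBFF", "#08306B"))(256)

.divergingColor <- function(v, limits) {
  t <- (pmin(pmax(v, limits[1]), limits[2]) - limits[1]) / diff(limits)
  .divergingPalette[1 + round(t * 256)]
}

.sequentialColor <- function(v, limits) {
  t <- (pmin(pmax(v, limits[1]), limits[2]) - limits[1]) / diff(limits)
  .sequentialPalette[1 + round(t * 255)]
}

.el <- function(type, ...) c(list(type = type), list(...))

.newScene <- function(width, height)
  list(width = width, height = height, elements = list())

.add <- function(scene, el) {
  scene$elements[[length(scene$elements) + 1L]] <- el
  scene
}

## ---------------------------------------------------------------------------
## Scene builders
## ---------------------------------------------------------------------------

.sceneRain <- function(model) {
  cs <- 22
  ml <- 110; mt <- 90; mr <- 12; mb <- 12
  nr <- length(model@rows); nc <- length(model@cols)
  sc <- .newScene(ml + nc * cs + mr, mt + nr * cs + mb)
  sc <- .add(sc, .el("rect", x = 0, y = 0, w = sc$width, h = sc$height,
                     fill = "#FFFFFF", stroke = "none"))
  sc <- .add(sc, .el("rect", x = ml, y = mt, w = nc * cs, h = nr * cs,
                     fill = "none", stroke = "#CCCCCC"))
  cells <- model@cells
  for (i in seq_len(nrow(cells))) {
    sc <- .add(sc, .el("circle",
      cx = ml + (cells$col[i] - 0.5) * cs,
      cy = mt + (cells$row[i] - 0.5) * cs,
      r = cells$radius[i] * cs,
      fill = .divergingColor(cells$fill_value[i], model@colorLimits),
      stroke = "#555555"))
  }
  for (i in seq_len(nr))
    sc <- .add(sc, .el("text", x = ml - 6, y = mt + (i - 0.5) * cs + 3,
                       label = model@rows[i], size = 8, anchor = "end",
                       rot = 0))
  for (j in seq_len(nc))
    sc <- .add(sc, .el("text", x = ml + (j - 0.5) * cs, y = mt - 8,
                       label = model@cols[j], size = 8, anchor = "start",
                       rot = -45))
  sc
}

.sceneManhattan <- function(model) {
  fw <- 520; fh <- 110; ml <- 60; mt <- 20; gap <- 14
  nf <- length(model@facets)
  sc <- .newScene(ml + fw + 20, mt + nf * (fh + gap) + 20)
  sc <- .add(sc, .el("rect", x = 0, y = 0, w = sc$width, h = sc$height,
                     fill = "#FFFFFF", stroke = "none"))
  pts <- model@points
  xr <- range(pts$mz)
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  ymax <- max(model@yLimits[2], 1e-6)
  dirCol <- function(d) ifelse(d > 0, "#B2182B",
                               ifelse(d < 0, "#2166AC", "#888888"))
  for (f in seq_len(nf)) {
    top <- mt + (f - 1) * (fh + gap)
    sc <- .add(sc, .el("rect", x = ml, y = top, w = fw, h = fh,
                       fill = "none", stroke = "#999999"))
    sc <- .add(sc, .el("text", x = ml + 4, y = top + 12,
                       label = model@facets[f], size = 9,
                       anchor = "start", rot = 0))
    ty <- top + fh - fh * model@thresholdLine / ymax
    sc <- .add(sc, .el("line", x1 = ml, y1 = ty, x2 = ml + fw, y2 = ty,
                       stroke = "#444444", dash = TRUE))
    sub <- pts[pts$outcome == model@facets[f], , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      sc <- .add(sc, .el("circle",
        cx = ml + fw * (sub$mz[i] - xr[1]) / diff(xr),
        cy = top + fh - fh * sub$y[i] / ymax,
        r = 2, fill = dirCol(sub$direction[i]), stroke = "none"))
    }
  }
  sc
}

.sceneBarScatter <- function(model) {
  d <- model@data
  n <- nrow(d)
  bw <- max(6, min(18, floor(600 / max(1, n))))
  ml <- 60; mt <- 30; h <- 200; ph <- 120; gap <- 30
  sc <- .newScene(ml + n * bw + 20, mt + h + gap + ph + 20)
  sc <- .add(sc, .el("rect", x = 0, y = 0, w = sc$width, h = sc$height,
                     fill = "#FFFFFF", stroke = "none"))
  sc <- .add(sc, .el("text", x = ml, y = mt - 12, label = model@outcome,
                     size = 10, anchor = "start", rot = 0))
  bmax <- max(abs(d$beta), 1e-12)
  base <- mt + h / 2
  sc <- .add(sc, .el("line", x1 = ml, y1 = base, x2 = ml + n * bw,
                     y2 = base, stroke = "#444444", dash = FALSE))
  for (i in seq_len(n)) {
    bh <- (h / 2) * d$beta[i] / bmax
    sc <- .add(sc, .el("rect",
      x = ml + (i - 1) * bw + 1,
      y = if (bh >= 0) base - bh else base,
      w = bw - 2, h = abs(bh),
      fill = if (d$beta[i] >= 0) "#B2182B" else "#2166AC",
      stroke = "none"))
  }
  pmax_ <- max(d$neglogp, 1e-12)
  ptop <- mt + h + gap
  sc <- .add(sc, .el("rect", x = ml, y = ptop, w = n * bw, h = ph,
                     fill = "none", stroke = "#999999"))
  for (i in seq_len(n)) {
    sc <- .add(sc, .el("circle",
      cx = ml + (i - 0.5) * bw,
      cy = ptop + ph - ph * d$neglogp[i] / pmax_,
      r = 2.5, fill = "#333333", stroke = "none"))
  }
  sc
}

.scenePaired <- function(model) {
  cs <- 16
  nr <- length(model@rows); nc <- length(model@cols)
  ml <- 100; mt <- 80; gap <- 40
  sc <- .newScene(ml + 2 * nc * cs + gap + 20, mt + nr * cs + 20)
  sc <- .add(sc, .el("rect", x = 0, y = 0, w = sc$width, h = sc$height,
                     fill = "#FFFFFF", stroke = "none"))
  panelX <- c(ml, ml + nc * cs + gap)
  fills <- list(
    function(i, j) .divergingColor(model@fillsBeta[i, j], model@colorLimits),
    function(i, j) .sequentialColor(model@fillsP[i, j], model@pLimits))
  titles <- c("beta", "-log10(P)")
  for (p in 1:2) {
    sc <- .add(sc, .el("text", x = panelX[p], y = mt - 10,
                       label = titles[p], size = 10, anchor = "start",
                       rot = 0))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      v <- if (p == 1) model@fillsBeta[i, j] else model@fillsP[i, j]
      sc <- .add(sc, .el("rect",
        x = panelX[p] + (j - 1) * cs, y = mt + (i - 1) * cs,
        w = cs, h = cs,
        fill = if (is.na(v)) "#BBBBBB" else fills[[p]](i, j),
        stroke = "none"))
    }
  }
  for (i in seq_len(nr))
    sc <- .add(sc, .el("text", x = ml - 6, y = mt + (i - 0.5) * cs + 3,
                       label = model@rows[i], size = 7, anchor = "end",
                       rot = 0))
  sc
}

## ---------------------------------------------------------------------------
## Scene output: SVG via xml2, png/pdf via grid
## ---------------------------------------------------------------------------

.writeSceneSVG <- function(scene, path) {
  root <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = as.character(scene$width), height = as.character(scene$height),
    viewBox = sprintf("0 0 %g %g", scene$width, scene$height))
  for (e in scene$elements) {
    switch(e$type,
      circle = xml2::xml_add_child(root, "circle",
        cx = sprintf("%.3f", e$cx), cy = sprintf("%.3f", e$cy),
        r = sprintf("%.3f", e$r), fill = e$fill, stroke = e$stroke),
      rect = xml2::xml_add_child(root, "rect",
        x = sprintf("%.3f", e$x), y = sprintf("%.3f", e$y),
        width = sprintf("%.3f", e$w), height = sprintf("%.3f", e$h),
        fill = e$fill, stroke = e$stroke),
      line = xml2::xml_add_child(root, "line",
        x1 = sprintf("%.3f", e$x1), y1 = sprintf("%.3f", e$y1),
        x2 = sprintf("%.3f", e$x2), y2 = sprintf("%.3f", e$y2),
        stroke = e$stroke,
        `stroke-dasharray` = if (isTRUE(e$dash)) "4,3" else ""),
      text = {
        node <- xml2::xml_add_child(root, "text",
          x = sprintf("%.3f", e$x), y = sprintf("%.3f", e$y),
          `font-size` = as.character(e$size),
          `font-family` = "sans-serif",
          `text-anchor` = if (e$anchor == "end") "end" else "start")
        if (e$rot != 0)
          xml2::xml_set_attr(node, "transform",
            sprintf("rotate(%g %.3f %.3f)", e$rot, e$x, e$y))
        xml2::xml_set_text(node, e$label)
      })
  }
  xml2::write_xml(root, path)
  invisible(path)
}

.drawSceneGrid <- function(scene) {
  grid::grid.newpage()
  vp <- grid::viewport(x = 0.5, y = 0.5, width = 0.96, height = 0.96,
                       xscale = c(0, scene$width),
                       yscale = c(scene$height, 0))
  grid::pushViewport(vp)
  for (e in scene$elements) {
    switch(e$type,
      circle = grid::grid.circle(
        x = grid::unit(e$cx, "native"), y = grid::unit(e$cy, "native"),
        r = grid::unit(e$r, "native"),
        gp = grid::gpar(
          fill = if (e$fill == "none") NA else e$fill,
          col = if (e$stroke == "none") NA else e$stroke)),
      rect = grid::grid.rect(
        x = grid::unit(e$x, "native"), y = grid::unit(e$y, "native"),
        width = grid::unit(e$w, "native"),
        height = grid::unit(e$h, "native"),
        just = c("left", "top"),
        gp = grid::gpar(
          fill = if (e$fill == "none") NA else e$fill,
          col = if (e$stroke == "none") NA else e$stroke)),
      line = grid::grid.lines(
        x = grid::unit(c(e$x1, e$x2), "native"),
        y = grid::unit(c(e$y1, e$y2), "native"),
        gp = grid::gpar(col = e$stroke,
                        lty = if (isTRUE(e$dash)) "dashed" else "solid")),
      text = grid::grid.text(
        e$label, x = grid::unit(e$x, "native"),
        y = grid::unit(e$y, "native"),
        just = if (e$anchor == "end") "right" else "left",
        rot = -e$rot,
        gp = grid::gpar(fontsize = e$size)))
  }
  grid::popViewport()
}

.renderScene <- function(scene, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = .writeSceneSVG(scene, path),
    png = {
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150, type = "cairo")
      on.exit(grDevices::dev.off())
      .drawSceneGrid(scene)
    },
    pdf = {
      grDevices::pdf(path, width = width, height = height)
      on.exit(grDevices::dev.off())
      .drawSceneGrid(scene)
    },
    stop("unknown output extension '.", ext, "'; use svg, png, or pdf",
         call. = FALSE))
  invisible(path)
}

#' @rdname renderPlot
#' @export
setMethod("renderPlot", "RainPlotModel", function(model, path, width = 7,
                                                  height = 7)
  .renderScene(.sceneRain(model), path, width, height))

#' @rdname renderPlot
#' @export
setMethod("renderPlot", "ManhattanModel", function(model, path, width = 7,
                                                   height = 9)
  .renderScene(.sceneManhattan(model), path, width, height))

#' @rdname renderPlot
#' @export
setMethod("renderPlot", "BarScatterModel", function(model, path, width = 8,
                                                    height = 6)
  .renderScene(.sceneBarScatter(model), path, width, height))

#' @rdname renderPlot
#' @export
setMethod("renderPlot", "PairedHeatmapModel", function(model, path,
                                                       width = 9,
                                                       height = 6)
  .renderScene(.scenePaired(model), path, width, height))
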