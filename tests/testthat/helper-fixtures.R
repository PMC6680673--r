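# Fixtures are built in code: small panels, random-but-valid association
# grids, and miniature synthetic designs used across the test files.

linearPanel <- function(n = 3) {
  ModelPanel(lapply(seq_len(n), function(i)
    ModelSpec(paste0("out", i), "linear", displayIndex = i - 1L)))
}

randomGrid <- function(nMet = 6, nOut = 3, seed = 1) {
  set.seed(seed)
  mids <- sprintf("m%02d", seq_len(nMet))
  panel <- linearPanel(nOut)
  outs <- outcomeNames(panel)
  rec <- expand.grid(metabolite_id = mids, outcome = outs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$beta <- rnorm(nrow(rec))
  rec$se <- runif(nrow(rec), 0.05, 0.3)
  rec$p <- runif(nrow(rec), 1e-6, 1)
  AssociationGrid(rec,
                  annotations = data.frame(metabolite_id = mids,
                                           mz = runif(nMet, 225, 650)),
                  panel = panel)
}

gridFromPvalues <- function(p, outcome = "out1", mz = NULL) {
  n <- length(p)
  mids <- sprintf("m%02d", seq_len(n))
  if (is.null(mz)) mz <- seq(300, 400, length.out = n)
  panel <- ModelPanel(list(ModelSpec(outcome, "linear", displayIndex = 0L)))
  AssociationGrid(
    data.frame(metabolite_id = mids, outcome = outcome,
               beta = rep(0.1, n), se = rep(0.1, n), p = p,
               stringsAsFactors = FALSE),
    annotations = data.frame(metabolite_id = mids, mz = mz),
    panel = panel)
}

# Grid with a chosen beta-profile matrix (one row per metabolite).
gridFromBetas <- function(B, ids = sprintf("m%02d", seq_len(nrow(B)))) {
  nOut <- ncol(B)
  panel <- linearPanel(nOut)
  outs <- outcomeNames(panel)
  rec <- expand.grid(metabolite_id = ids, outcome = outs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$beta <- as.vector(B[cbind(match(rec$metabolite_id, ids),
                                match(rec$outcome, outs))])
  rec$se <- 0.1
  rec$p <- 0.5
  AssociationGrid(rec,
                  annotations = data.frame(metabolite_id = ids,
                                           mz = seq_len(nrow(B)) + 300),
                  panel = panel)
}

countSvgElements <- function(path, name) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(doc, sprintf("//*[local-name()='%s']", name)))
}
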