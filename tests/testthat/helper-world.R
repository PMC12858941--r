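# Fixtures built in code: tiny grids, hand-specified community fields and a
# small but realistic synthetic world shared across tests.

# A CommunityField with explicitly given per-cell covers.
# covers: nCells x nSpecies matrix (rows in cell-id order, rows sum to 1 or 0)
makeCommunity <- function(grid, covers, binomials = NULL) {
  if (is.null(binomials)) {
    binomials <- paste0("genus", seq_len(ncol(covers)), " species",
                        seq_len(ncol(covers)))
  }
  colnames(covers) <- binomials
  new("CommunityField", grid = grid, cover = covers)
}

makePool <- function(traits, binomials = NULL, nAxes = 1) {
  n <- nrow(traits)
  if (is.null(binomials)) {
    binomials <- paste0("genus", seq_len(n), " species", seq_len(n))
  }
  axes <- paste0("env", seq_len(nAxes))
  new("SpeciesPool",
      species = data.frame(speciesId = seq_len(n), binomial = binomials,
                           stringsAsFactors = FALSE),
      traits = as.matrix(traits),
      optima = matrix(0, n, nAxes, dimnames = list(NULL, axes)),
      breadths = matrix(1, n, nAxes, dimnames = list(NULL, axes)))
}

# Small end-to-end world reused by modeling / uncertainty tests.
miniWorld <- function(seed = 11, nCols = 30, nRows = 30, nPlots = 250,
                      nOcc = 15000, nSpecies = 25,
                      clusterSpec = list(nClusters = 10, sdKm = 5),
                      intraspecificCv = 0, coverageFraction = 1) {
  cfg <- pipelineConfig(seed)$world
  cfg$nCols <- nCols; cfg$nRows <- nRows
  cfg$nPlots <- nPlots; cfg$nOcc <- nOcc; cfg$nSpecies <- nSpecies
  cfg$clusterSpec <- clusterSpec
  cfg$intraspecificCv <- intraspecificCv
  cfg$coverageFraction <- coverageFraction
  simulateWorld(cfg, seed)
}

sameGridTest <- function(a, b) {
  isTRUE(all.equal(c(a@originX, a@originY, a@cellEdge),
                   c(b@originX, b@originY, b@cellEdge))) &&
    a@nCols == b@nCols && a@nRows == b@nRows
}

# Training table constructed directly from coordinates + features, bypassing
# the gridding stage (for model-level tests).
makeTable <- function(x, y, label, features, source = "survey",
                      stratum = NA_integer_) {
  stopifnot(is.matrix(features))
  out <- data.frame(cell = seq_along(x), x = x, y = y, label = label,
                    labelRaw = label, source = source, stratum = stratum)
  out <- cbind(out, as.data.frame(features))
  attr(out, "features") <- colnames(features)
  attr(out, "transform") <- structure(list(lambda = 1, mean = 0, sd = 1),
                                      class = "yjTransform")
  out
}
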