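#' @import methods
#' @importFrom stats aggregate approx complete.cases cor dist ks.test median
#'   optim optimize quantile rbinom rlnorm rnorm runif sd var setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Equal-area grid specification
#'
#' Defines a regular equal-area grid on an abstract plane with coordinates in
#' kilometres. Cell \code{(i, j)} (zero-based column \code{i}, row \code{j})
#' covers the half-open square
#' \code{[originX + i*cellEdge, originX + (i+1)*cellEdge) x
#' [originY + j*cellEdge, originY + (j+1)*cellEdge)}.
#' Raster-valued objects built on a \code{GridSpec} store values in matrices of
#' dimension \code{nRows x nCols}; matrix element \code{[r, c]} is grid cell
#' column \code{c - 1}, row \code{r - 1}.
#'
#' @slot originX,originY lower-left corner of the grid (km).
#' @slot cellEdge cell edge length (km), strictly positive.
#' @slot nCols,nRows grid dimensions (counts, at least 1).
#' @export
setClass("GridSpec",
  representation(originX = "numeric", originY = "numeric",
                 cellEdge = "numeric", nCols = "integer", nRows = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellEdge) != 1L || !is.finite(object@cellEdge) ||
        object@cellEdge <= 0) {
      msg <- c(msg, "cellEdge must be a single positive finite number")
    }
    if (object@nCols < 1L || object@nRows < 1L) {
      msg <- c(msg, "nCols and nRows must be >= 1")
    }
    if (!is.finite(object@originX) || !is.finite(object@originY)) {
      msg <- c(msg, "origin must be finite")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a GridSpec
#'
#' @param originX,originY lower-left corner (km).
#' @param cellEdge cell edge length (km).
#' @param nCols,nRows grid dimensions.
#' @return A [GridSpec-class] object.
#' @examples
#' g <- gridSpec(0, 0, cellEdge = 1, nCols = 10, nRows = 10)
#' nCells(g)
#' @export
gridSpec <- function(originX = 0, originY = 0, cellEdge = 1, nCols, nRows) {
  new("GridSpec", originX = as.numeric(originX), originY = as.numeric(originY),
      cellEdge = as.numeric(cellEdge), nCols = as.integer(nCols),
      nRows = as.integer(nRows))
}

#' @describeIn gridSpec number of cells in the grid
#' @param grid a [GridSpec-class].
#' @export
nCells <- function(grid) as.integer(grid@nCols) * as.integer(grid@nRows)

#' @describeIn gridSpec cell-centre coordinates for every cell, in cell-id
#'   order (\code{cell = (row - 1) * nCols + col}, 1-based)
#' @export
cellCenters <- function(grid) {
  cx <- grid@originX + (seq_len(grid@nCols) - 0.5) * grid@cellEdge
  cy <- grid@originY + (seq_len(grid@nRows) - 0.5) * grid@cellEdge
  data.frame(cell = seq_len(nCells(grid)),
             x = rep(cx, times = grid@nRows),
             y = rep(cy, each = grid@nCols))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, edge %g km, origin (%g, %g)\n",
              object@nCols, object@nRows, object@cellEdge,
              object@originX, object@originY))
})

sameGrid <- function(a, b, tol = 1e-9) {
  abs(a@originX - b@originX) < tol && abs(a@originY - b@originY) < tol &&
    abs(a@cellEdge - b@cellEdge) < tol &&
    a@nCols == b@nCols && a@nRows == b@nRows
}

#' Multi-layer environmental predictor stack
#'
#' A named collection of raster layers sharing one [GridSpec-class]. Missing
#' data are explicit \code{NA}s in the layer matrices; no sentinel values are
#' used.
#'
#' @slot grid the shared [GridSpec-class].
#' @slot layers named list of \code{nRows x nCols} numeric matrices.
#' @export
setClass("EnvironmentStack",
  representation(grid = "GridSpec", layers = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@layers) == 0L) msg <- c(msg, "at least one layer required")
    nm <- names(object@layers)
    if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
      msg <- c(msg, "layers must have unique non-empty names")
    }
    for (l in object@layers) {
      if (!is.matrix(l) || nrow(l) != object@grid@nRows ||
          ncol(l) != object@grid@nCols) {
        msg <- c(msg, "every layer must be a matrix of dim nRows x nCols")
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an EnvironmentStack
#' @param grid a [GridSpec-class].
#' @param layers named list of \code{nRows x nCols} matrices (\code{NA} =
#'   nodata).
#' @return An [EnvironmentStack-class].
#' @export
environmentStack <- function(grid, layers) {
  new("EnvironmentStack", grid = grid, layers = layers)
}

#' @describeIn environmentStack names of the layers
#' @param env an [EnvironmentStack-class].
#' @export
layerNames <- function(env) names(env@layers)

#' @describeIn environmentStack extract one layer matrix by name
#' @param name layer name.
#' @export
getLayer <- function(env, name) {
  if (!name %in% names(env@layers)) {
    stop("layer '", name, "' not present in stack", call. = FALSE)
  }
  env@layers[[name]]
}

setMethod("show", "EnvironmentStack", function(object) {
  cat(sprintf("EnvironmentStack: %d layer(s) [%s] on ", length(object@layers),
              paste(head(names(object@layers), 5), collapse = ", ")))
  show(object@grid)
})

#' Synthetic species pool with known trait truth
#'
#' Ground truth for the synthetic world: species identities, unique binomial
#' names, true per-species trait values, and Gaussian niche parameters
#' (optimum and breadth) on named environmental axes.
#'
#' @slot species data.frame with columns \code{speciesId}, \code{binomial}.
#' @slot traits numeric matrix, species x traits, with trait names as columns.
#' @slot optima,breadths numeric matrices, species x environmental axes
#'   (column names are layer names of the environment the pool responds to).
#' @export
setClass("SpeciesPool",
  representation(species = "data.frame", traits = "matrix",
                 optima = "matrix", breadths = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@species)
    if (anyDuplicated(object@species$binomial)) {
      msg <- c(msg, "binomials must be unique")
    }
    if (nrow(object@traits) != n) msg <- c(msg, "traits rows must match species")
    if (any(!is.finite(object@traits))) msg <- c(msg, "trait values must be finite")
    if (nrow(object@optima) != n || nrow(object@breadths) != n) {
      msg <- c(msg, "niche matrices must have one row per species")
    }
    if (any(object@breadths <= 0)) msg <- c(msg, "niche breadths must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "SpeciesPool", function(object) {
  cat(sprintf("SpeciesPool: %d species, traits [%s], niche axes [%s]\n",
              nrow(object@species),
              paste(colnames(object@traits), collapse = ", "),
              paste(colnames(object@optima), collapse = ", ")))
})

#' @describeIn generateSpeciesPool true per-species trait values
#' @param pool a [SpeciesPool-class].
#' @export
traitValues <- function(pool) pool@traits

#' @describeIn generateSpeciesPool species binomial names
#' @export
binomials <- function(pool) pool@species$binomial

#' Latent community composition field
#'
#' Per-cell relative cover of every species in the pool: the hidden state from
#' which surveys and occurrences are sampled. Covers in occupied cells are
#' non-negative and sum to one; empty cells are all-zero rows.
#'
#' @slot grid the [GridSpec-class].
#' @slot cover numeric matrix, \code{nCells x nSpecies}; row order is cell-id
#'   order, column names are binomials.
#' @export
setClass("CommunityField",
  representation(grid = "GridSpec", cover = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@cover) != nCells(object@grid)) {
      msg <- c(msg, "cover must have one row per grid cell")
    }
    if (any(object@cover < 0)) msg <- c(msg, "covers must be >= 0")
    s <- rowSums(object@cover)
    occ <- s > 0
    if (any(occ) && any(abs(s[occ] - 1) > 1e-9)) {
      msg <- c(msg, "occupied-cell covers must sum to 1 within 1e-9")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CommunityField", function(object) {
  occ <- sum(rowSums(object@cover) > 0)
  cat(sprintf("CommunityField: %d species, %d/%d occupied cells on ",
              ncol(object@cover), occ, nCells(object@grid)))
  show(object@grid)
})

#' Gridded trait statistic layer
#'
#' Per-cell trait statistic (survey CWM mean, occurrence FWM, or their merge),
#' with the number of contributing records and a per-cell source flag.
#'
#' @slot grid the [GridSpec-class].
#' @slot values numeric matrix (\code{NA} = unoccupied).
#' @slot counts integer matrix of contributing record counts.
#' @slot source character matrix with entries \code{"survey"},
#'   \code{"occurrence"} or \code{NA}.
#' @slot trait trait name.
#' @export
setClass("TraitGrid",
  representation(grid = "GridSpec", values = "matrix", counts = "matrix",
                 source = "matrix", trait = "character"),
  validity = function(object) {
    d <- c(object@grid@nRows, object@grid@nCols)
    ok <- function(m) is.matrix(m) && all(dim(m) == d)
    if (!ok(object@values) || !ok(object@counts) || !ok(object@source)) {
      return("values, counts and source must all be nRows x nCols matrices")
    }
    occ <- !is.na(object@values)
    if (any(is.na(object@source[occ]))) {
      return("occupied cells must carry a source flag")
    }
    TRUE
  })

setMethod("show", "TraitGrid", function(object) {
  occ <- sum(!is.na(object@values))
  src <- table(object@source[!is.na(object@values)])
  cat(sprintf("TraitGrid '%s': %d occupied cells (%s) on ", object@trait, occ,
              paste(sprintf("%s: %d", names(src), src), collapse = ", ")))
  show(object@grid)
})

#' @describeIn gridTraitValues occupied cells of a [TraitGrid-class] as a
#'   data.frame with cell id, centre coordinates, value, count and source
#' @export
traitGridTable <- function(tg) {
  cc <- cellCenters(tg@grid)
  v <- as.vector(t(tg@values))   # row-major: cell id order
  k <- as.vector(t(tg@counts))
  s <- as.vector(t(tg@source))
  keep <- !is.na(v)
  data.frame(cell = cc$cell[keep], x = cc$x[keep], y = cc$y[keep],
             value = v[keep], count = k[keep], source = s[keep],
             stringsAsFactors = FALSE)
}

#' Spatially blocked fold assignment
#'
#' Maps hexagon blocks and individual label points to one of \code{K}
#' cross-validation folds, chosen as the best of \code{nSim} random
#' assignments by mean pairwise Kolmogorov-Smirnov p-value.
#'
#' @slot hexFold named integer vector: hexagon id -> fold.
#' @slot rowFold integer vector: label row -> fold.
#' @slot rowHex character vector: label row -> hexagon id.
#' @slot K number of folds.
#' @slot balanceScore mean pairwise KS p-value of the chosen assignment.
#' @slot candidateScores scores of all simulated assignments.
#' @slot rangeKm hexagon sizing range (across-flats width, km).
#' @export
setClass("FoldAssignment",
  representation(hexFold = "integer", rowFold = "integer", rowHex = "character",
                 K = "integer", balanceScore = "numeric",
                 candidateScores = "numeric", rangeKm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@hexFold < 1L | object@hexFold > object@K)) {
      msg <- c(msg, "hexagon folds must lie in 1..K")
    }
    if (length(object@rowFold) != length(object@rowHex)) {
      msg <- c(msg, "rowFold and rowHex must have equal length")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf(
    "FoldAssignment: %d hexagons -> %d folds (range %.2f km), balance %.4f over %d simulations\n",
    length(object@hexFold), object@K, object@rangeKm, object@balanceScore,
    length(object@candidateScores)))
  print(table(fold = object@rowFold))
})

#' Per-pixel uncertainty product
#'
#' Coefficient of variation of the fold-model prediction stack, dissimilarity
#' index, area-of-applicability mask and the DI threshold that generated it.
#'
#' @slot grid the [GridSpec-class].
#' @slot cov coefficient-of-variation matrix (NA where undefined).
#' @slot di dissimilarity-index matrix.
#' @slot aoa logical matrix, \code{TRUE} inside the area of applicability.
#' @slot diThreshold the DI threshold \code{Q75 + 1.5 * IQR} of training DI.
#' @slot pctInsideAOA percentage of valid prediction pixels inside the AOA.
#' @slot meanTrainDist the mean cross-fold nearest-neighbour distance.
#' @export
setClass("UncertaintyProduct",
  representation(grid = "GridSpec", cov = "matrix", di = "matrix",
                 aoa = "matrix", diThreshold = "numeric",
                 pctInsideAOA = "numeric", meanTrainDist = "numeric"))

setMethod("show", "UncertaintyProduct", function(object) {
  cat(sprintf(
    "UncertaintyProduct: DI threshold %.4f, %.1f%% of valid pixels inside AOA\n",
    object@diThreshold, object@pctInsideAOA))
})
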