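# Point-to-grid assignment, per-cell occurrence subsampling, FWM/CWM/COMB
# trait grids, predictor aggregation and training-table assembly.

#' Assign point coordinates to grid cells
#'
#' Half-open cell convention with the floor rule: a point exactly on a cell
#' boundary belongs to the higher-index cell whose lower edge it lies on.
#' Out-of-extent points get \code{NA} cell ids and are flagged.
#'
#' @param points data.frame with columns \code{x}, \code{y} (km).
#' @param grid a [GridSpec-class].
#' @return data.frame with columns \code{cell} (1-based id, NA if outside),
#'   \code{col}, \code{row} (zero-based indices) and \code{inside}.
#' @export
assignCells <- function(points, grid) {
  stopifnot(all(c("x", "y") %in% names(points)))
  pc <- .pointToCell(grid, points$x, points$y)
  data.frame(cell = pc$cell, col = ifelse(pc$inside, pc$col, NA_integer_),
             row = ifelse(pc$inside, pc$row, NA_integer_), inside = pc$inside)
}

#' Subsample tagged occurrences per grid cell
#'
#' Cells with fewer than \code{minOcc} records are dropped entirely; cells
#' with more than \code{maxOcc} are reduced to exactly \code{maxOcc} by
#' uniform random sampling without replacement. Applied independently at
#' each resolution being built. Defaults follow the 10--500 records-per-cell
#' rule used for opportunistic observation data.
#'
#' @param tagged tagged occurrences from [tagOccurrences()].
#' @param grid a [GridSpec-class].
#' @param minOcc,maxOcc per-cell record count bounds (1 <= minOcc <= maxOcc).
#' @param seed integer seed.
#' @return subset of \code{tagged} rows (original order preserved).
#' @export
subsampleOccurrences <- function(tagged, grid, minOcc = 10, maxOcc = 500,
                                 seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (minOcc < 1 || minOcc > maxOcc) {
    stop("need 1 <= minOcc <= maxOcc", call. = FALSE)
  }
  ac <- assignCells(tagged, grid)
  keepIdx <- integer(0)
  inside <- which(ac$inside)
  cells <- split(inside, ac$cell[inside])
  withr::with_seed(as.integer(seed), {
    for (idx in cells) {
      n <- length(idx)
      if (n < minOcc) next
      if (n > maxOcc) idx <- sort(sample(idx, maxOcc))
      keepIdx <- c(keepIdx, idx)
    }
  })
  out <- tagged[sort(keepIdx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyTraitGrid <- function(grid, traitName) {
  d <- c(grid@nRows, grid@nCols)
  new("TraitGrid", grid = grid,
      values = matrix(NA_real_, d[1], d[2]),
      counts = matrix(0L, d[1], d[2]),
      source = matrix(NA_character_, d[1], d[2]),
      trait = traitName)
}

#' Aggregate per-record trait values into a trait grid
#'
#' Per-cell arithmetic mean of the records falling in each cell: with
#' occurrence-level species mean values this yields the frequency-weighted
#' mean (FWM) grid; with plot-level CWMs it yields the mean-CWM grid.
#'
#' @param rows data.frame with columns \code{x}, \code{y} and a value column
#'   (\code{value} for tagged occurrences, \code{cwm} for plot CWMs).
#' @param grid a [GridSpec-class].
#' @param mode \code{"fwm"} (source flag "occurrence") or \code{"cwm_mean"}
#'   (source flag "survey").
#' @param traitName trait name recorded on the grid.
#' @return A [TraitGrid-class].
#' @export
gridTraitValues <- function(rows, grid, mode = c("fwm", "cwm_mean"),
                            traitName = NULL) {
  mode <- match.arg(mode)
  valCol <- if ("value" %in% names(rows)) "value" else "cwm"
  if (is.null(traitName)) {
    traitName <- if ("trait" %in% names(rows) && nrow(rows)) rows$trait[1] else "trait"
  }
  tg <- .emptyTraitGrid(grid, traitName)
  if (nrow(rows) == 0L) return(tg)
  ac <- assignCells(rows, grid)
  keep <- ac$inside
  if (!any(keep)) return(tg)
  cell <- ac$cell[keep]
  v <- rows[[valCol]][keep]
  mu <- tapply(v, cell, mean)
  n <- tapply(v, cell, length)
  ids <- as.integer(names(mu))
  r <- (ids - 1L) %/% grid@nCols + 1L
  c_ <- (ids - 1L) %% grid@nCols + 1L
  flat <- cbind(r, c_)
  tg@values[flat] <- as.numeric(mu)
  tg@counts[flat] <- as.integer(n)
  tg@source[flat] <- if (mode == "fwm") "occurrence" else "survey"
  validObject(tg)
  tg
}

#' Merge survey and occurrence trait grids (COMB)
#'
#' Survey (CWM) cells take precedence wherever both sources are present;
#' cells with only occurrence data take the FWM value. Occupancy of the
#' merged grid is the union of both inputs.
#'
#' @param cwmGrid survey-sourced [TraitGrid-class].
#' @param fwmGrid occurrence-sourced [TraitGrid-class] on the same grid.
#' @return A merged [TraitGrid-class].
#' @export
mergeComb <- function(cwmGrid, fwmGrid) {
  if (!sameGrid(cwmGrid@grid, fwmGrid@grid)) {
    stop("trait grids must share the same GridSpec", call. = FALSE)
  }
  out <- cwmGrid
  takeF <- is.na(cwmGrid@values) & !is.na(fwmGrid@values)
  out@values[takeF] <- fwmGrid@values[takeF]
  out@counts[takeF] <- fwmGrid@counts[takeF]
  out@source[takeF] <- fwmGrid@source[takeF]
  out
}

# per-axis fractional overlap weight matrix between target and source cells
.overlapWeights <- function(originT, edgeT, nT, originS, edgeS, nS) {
  w <- matrix(0, nT, nS)
  for (i in seq_len(nT)) {
    lo <- originT + (i - 1) * edgeT
    hi <- lo + edgeT
    j0 <- max(1L, floor((lo - originS) / edgeS) + 1L)
    j1 <- min(nS, ceiling((hi - originS) / edgeS))
    if (j0 > j1) next
    for (j in j0:j1) {
      slo <- originS + (j - 1) * edgeS
      shi <- slo + edgeS
      ov <- min(hi, shi) - max(lo, slo)
      if (ov > 0) w[i, j] <- ov
    }
  }
  w
}

#' Aggregate a predictor stack to a coarser grid
#'
#' Area-weighted mean resampling: each target cell averages the overlapping
#' source cells weighted by overlap area, ignoring nodata (weights are
#' renormalized over the valid area). Target cells with no valid source area
#' are nodata. Upsampling (target finer than source) is unsupported.
#'
#' @param env source [EnvironmentStack-class].
#' @param target target [GridSpec-class] with \code{cellEdge >=} source edge.
#' @return An [EnvironmentStack-class] on \code{target}.
#' @export
aggregatePredictors <- function(env, target) {
  src <- env@grid
  if (target@cellEdge < src@cellEdge - 1e-12) {
    stop("target grid is finer than source: upsampling unsupported",
         call. = FALSE)
  }
  wx <- .overlapWeights(target@originX, target@cellEdge, target@nCols,
                        src@originX, src@cellEdge, src@nCols)
  wy <- .overlapWeights(target@originY, target@cellEdge, target@nRows,
                        src@originY, src@cellEdge, src@nRows)
  layers <- lapply(env@layers, function(m) {
    valid <- !is.na(m)
    mv <- m
    mv[!valid] <- 0
    num <- wy %*% mv %*% t(wx)
    den <- wy %*% (valid + 0) %*% t(wx)
    out <- num / den
    out[den <= 0] <- NA_real_
    out
  })
  environmentStack(target, layers)
}

#' Assemble a model training table from a trait grid and predictor stack
#'
#' One row per labelled cell, carrying the (transformed) label, the source
#' flag, cell-centre coordinates, the stratum id and all predictor values.
#' Rows where strictly fewer than \code{minPredictorFrac} of the predictors
#' are non-missing are excluded.
#'
#' @param labelGrid a [TraitGrid-class].
#' @param env an [EnvironmentStack-class] on the same grid.
#' @param transform optional \code{yjTransform} fitted parameters; if NULL a
#'   transform is fitted to the labels (and returned as attribute
#'   \code{"transform"}).
#' @param minPredictorFrac minimum fraction of non-missing predictors
#'   (default 0.6; a row with exactly this fraction is kept).
#' @param strata optional integer stratum matrix aligned to the grid.
#' @return data.frame with columns \code{cell}, \code{x}, \code{y},
#'   \code{label} (transformed), \code{labelRaw}, \code{source},
#'   \code{stratum}, then one column per predictor; attributes
#'   \code{"transform"} (the [fitYeoJohnson()] parameters) and
#'   \code{"features"} (predictor column names).
#' @export
buildTrainingTable <- function(labelGrid, env, transform = NULL,
                               minPredictorFrac = 0.6, strata = NULL) {
  if (!sameGrid(labelGrid@grid, env@grid)) {
    stop("label grid and predictor stack must share the same GridSpec",
         call. = FALSE)
  }
  lab <- traitGridTable(labelGrid)
  if (nrow(lab) == 0L) stop("label grid is empty", call. = FALSE)
  feats <- layerNames(env)
  X <- vapply(feats, function(nm) as.vector(t(getLayer(env, nm)))[lab$cell],
              numeric(nrow(lab)))
  X <- matrix(X, nrow = nrow(lab), dimnames = list(NULL, feats))
  frac <- rowMeans(!is.na(X))
  keep <- frac >= minPredictorFrac - 1e-12
  if (!any(keep)) {
    stop(sprintf(
      "no training rows survive the %.0f%% predictor completeness filter (%d labelled cells)",
      100 * minPredictorFrac, nrow(lab)), call. = FALSE)
  }
  lab <- lab[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  if (is.null(transform)) transform <- fitYeoJohnson(lab$value)
  st <- if (is.null(strata)) NA_integer_ else as.vector(t(strata))[lab$cell]
  out <- data.frame(cell = lab$cell, x = lab$x, y = lab$y,
                    label = applyYeoJohnson(lab$value, transform),
                    labelRaw = lab$value, source = lab$source, stratum = st,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X))
  attr(out, "transform") <- transform
  attr(out, "features") <- feats
  out
}
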