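# Serialization: quantized multi-band trait map bundles as plain-text Esri
# ASCII grids with a JSON sidecar, plus CSV helpers for the tabular types.

#' Trait map bundle
#'
#' Prediction, COV and AOA bands on one grid, ready for quantized writing.
#'
#' @param grid a [GridSpec-class].
#' @param prediction,cov numeric matrices (original trait units; NA =
#'   nodata).
#' @param aoa logical matrix (TRUE inside the area of applicability).
#' @param metadata list stored verbatim in the JSON sidecar.
#' @return list of class \code{traitMapBundle}.
#' @export
traitMapBundle <- function(grid, prediction, cov, aoa, metadata = list()) {
  d <- c(grid@nRows, grid@nCols)
  for (m in list(prediction, cov, aoa)) {
    if (!all(dim(m) == d)) stop("bands must match the grid", call. = FALSE)
  }
  structure(list(grid = grid, prediction = prediction, cov = cov,
                 aoa = (aoa & !is.na(aoa)), metadata = metadata),
            class = "traitMapBundle")
}

.NODATA_CODE <- -32768L

.quantizeBand <- function(m) {
  v <- m[is.finite(m)]
  if (length(v) == 0L) {
    return(list(codes = matrix(.NODATA_CODE, nrow(m), ncol(m)),
                scale = 0, offset = 0))
  }
  mn <- min(v); mx <- max(v)
  scale <- (mx - mn) / (2^16 - 2)
  offset <- (mx + mn) / 2
  codes <- matrix(.NODATA_CODE, nrow(m), ncol(m))
  ok <- is.finite(m)
  codes[ok] <- if (scale > 0) {
    as.integer(pmin(32767, pmax(-32767, round((m[ok] - offset) / scale))))
  } else 0L
  list(codes = codes, scale = scale, offset = offset)
}

.dequantizeBand <- function(codes, scale, offset) {
  out <- codes * scale + offset
  out[codes == .NODATA_CODE] <- NA_real_
  out
}

.writeAsc <- function(codes, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid@nCols),
               sprintf("nrows %d", grid@nRows),
               sprintf("xllcorner %.10g", grid@originX),
               sprintf("yllcorner %.10g", grid@originY),
               sprintf("cellsize %.10g", grid@cellEdge),
               sprintf("NODATA_value %d", .NODATA_CODE)), con)
  for (r in rev(seq_len(grid@nRows))) {          # ASC rows run north to south
    writeLines(paste(codes[r, ], collapse = " "), con)
  }
}

.readAsc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  h <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                tolower(vapply(kv, `[`, "", 1)))
  dat <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(dat, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to row 1 = south
  list(codes = m,
       grid = gridSpec(h[["xllcorner"]], h[["yllcorner"]], h[["cellsize"]],
                       h[["ncols"]], h[["nrows"]]))
}

#' Write / read a quantized trait map bundle
#'
#' The prediction and COV bands are affinely quantized to signed 16-bit
#' integer codes (\code{value ~ code * scale + offset}, with
#' \code{scale = (max - min) / (2^16 - 2)} and a reserved nodata code), so
#' the round trip is accurate to half a quantization step. The AOA band is
#' stored as 0/1 losslessly. Bands are written as Esri ASCII grids
#' (\code{<prefix>_prediction.asc}, \code{_cov.asc}, \code{_aoa.asc}) with
#' a JSON sidecar (\code{<prefix>.json}) holding scales, offsets, the grid
#' and any metadata. Existing outputs are never silently overwritten.
#'
#' @param bundle a [traitMapBundle()].
#' @param prefix output path prefix (no extension).
#' @param overwrite allow replacing existing files.
#' @return \code{prefix}, invisibly.
#' @export
writeTraitRaster <- function(bundle, prefix, overwrite = FALSE) {
  paths <- paste0(prefix, c("_prediction.asc", "_cov.asc", "_aoa.asc", ".json"))
  if (!overwrite && any(file.exists(paths))) {
    stop("output exists (use overwrite = TRUE): ",
         paths[file.exists(paths)][1], call. = FALSE)
  }
  g <- bundle$grid
  qp <- .quantizeBand(bundle$prediction)
  qc <- .quantizeBand(bundle$cov)
  aoaCodes <- matrix(as.integer(bundle$aoa), g@nRows, g@nCols)
  .writeAsc(qp$codes, g, paths[1])
  .writeAsc(qc$codes, g, paths[2])
  .writeAsc(aoaCodes, g, paths[3])
  side <- list(
    grid = list(originX = g@originX, originY = g@originY,
                cellEdge = g@cellEdge, nCols = g@nCols, nRows = g@nRows),
    bands = list(
      prediction = list(scale = qp$scale, offset = qp$offset),
      cov = list(scale = qc$scale, offset = qc$offset),
      aoa = list(scale = 1, offset = 0)),
    metadata = bundle$metadata)
  jsonlite::write_json(side, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @describeIn writeTraitRaster read a bundle back; the AOA band round trip
#'   is bit-exact and nodata pixels are preserved
#' @export
readTraitRaster <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  g <- do.call(gridSpec, as.list(side$grid))
  p <- .readAsc(paste0(prefix, "_prediction.asc"))
  cv <- .readAsc(paste0(prefix, "_cov.asc"))
  ao <- .readAsc(paste0(prefix, "_aoa.asc"))
  pred <- .dequantizeBand(p$codes, side$bands$prediction$scale,
                          side$bands$prediction$offset)
  covm <- .dequantizeBand(cv$codes, side$bands$cov$scale,
                          side$bands$cov$offset)
  aoa <- ao$codes == 1
  traitMapBundle(g, pred, covm, aoa,
                 metadata = as.list(side$metadata))
}

#' Write an environment stack as ASCII grid layers plus sidecar
#'
#' One unquantized (full-precision text) ASCII grid per layer and a JSON
#' sidecar recording layer names and the grid.
#'
#' @param env an [EnvironmentStack-class].
#' @param prefix output path prefix.
#' @param overwrite allow replacing existing files.
#' @export
writeEnvironmentStack <- function(env, prefix, overwrite = FALSE) {
  g <- env@grid
  for (nm in layerNames(env)) {
    path <- paste0(prefix, "_", nm, ".asc")
    if (!overwrite && file.exists(path)) {
      stop("output exists (use overwrite = TRUE): ", path, call. = FALSE)
    }
    m <- getLayer(env, nm)
    codes <- matrix("-9999", g@nRows, g@nCols)
    ok <- is.finite(m)
    codes[ok] <- format(m[ok], digits = 12, trim = TRUE, scientific = TRUE)
    con <- file(path, "w")
    writeLines(c(sprintf("ncols %d", g@nCols),
                 sprintf("nrows %d", g@nRows),
                 sprintf("xllcorner %.10g", g@originX),
                 sprintf("yllcorner %.10g", g@originY),
                 sprintf("cellsize %.10g", g@cellEdge),
                 "NODATA_value -9999"), con)
    for (r in rev(seq_len(g@nRows))) {
      writeLines(paste(codes[r, ], collapse = " "), con)
    }
    close(con)
  }
  jsonlite::write_json(
    list(layers = layerNames(env),
         grid = list(originX = g@originX, originY = g@originY,
                     cellEdge = g@cellEdge, nCols = g@nCols,
                     nRows = g@nRows)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
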