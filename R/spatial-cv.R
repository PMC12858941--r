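# Spatially blocked cross-validation: empirical semivariogram, spherical
# model fit, range-sized hexagon tessellation, KS-balanced fold assignment
# and leave-one-fold-out splits validated on survey rows only.

#' Empirical semivariogram (Matheron estimator)
#'
#' gamma(h) = sum over pairs in the lag bin of (z_i - z_j)^2 / (2 N(h)).
#' Pairs are subsampled at random to \code{maxPairs} for tractability on
#' large point sets.
#'
#' @param points data.frame with columns \code{x}, \code{y} (km).
#' @param values numeric vector of the spatial variable at the points.
#' @param nBins number of equal-width lag bins.
#' @param maxLag maximum pair separation considered (km); default half the
#'   domain diagonal.
#' @param maxPairs cap on the number of point pairs (default 1e6).
#' @param seed integer seed for pair subsampling.
#' @return object of class \code{variogram}: data.frame with columns
#'   \code{lag} (bin centre), \code{gamma}, \code{n} (pair count), with
#'   attribute \code{maxLag}.
#' @export
empiricalVariogram <- function(points, values, nBins = 15, maxLag = NULL,
                               maxPairs = 1e6, seed = 1) {
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(values) != n) stop("values must match points", call. = FALSE)
  dx <- diff(range(points$x)); dy <- diff(range(points$y))
  if (dx == 0 && dy == 0) {
    stop("all points are coincident: variogram undefined", call. = FALSE)
  }
  if (is.null(maxLag)) maxLag <- sqrt(dx^2 + dy^2) / 2
  if (maxLag <= 0) stop("maxLag must be > 0", call. = FALSE)
  nPairsAll <- n * (n - 1) / 2
  withr::with_seed(as.integer(seed), {
    if (nPairsAll <= maxPairs) {
      ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      i <- ij[, 1]; j <- ij[, 2]
    } else {
      i <- sample.int(n, maxPairs, replace = TRUE)
      j <- sample.int(n, maxPairs, replace = TRUE)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
    }
    h <- sqrt((points$x[i] - points$x[j])^2 + (points$y[i] - points$y[j])^2)
    keep <- h > 0 & h <= maxLag
    h <- h[keep]
    d2 <- (values[i[keep]] - values[j[keep]])^2
    bin <- pmin(nBins, floor(h / (maxLag / nBins)) + 1L)
    gamma <- tapply(d2, bin, function(v) sum(v) / (2 * length(v)))
    cnt <- tapply(d2, bin, length)
    ctr <- (as.integer(names(gamma)) - 0.5) * (maxLag / nBins)
    out <- data.frame(lag = ctr, gamma = as.numeric(gamma),
                      n = as.integer(cnt))
    out <- out[order(out$lag), ]
    rownames(out) <- NULL
    attr(out, "maxLag") <- maxLag
    class(out) <- c("variogram", "data.frame")
    out
  })
}

.sphericalModel <- function(h, nugget, psill, range) {
  u <- pmin(h / range, 1)
  nugget + psill * (1.5 * u - 0.5 * u^3)
}

#' Fit a spherical semivariogram model
#'
#' Weighted least squares (weights = pair counts) fit of
#' \code{gamma(h) = nugget + psill * (1.5 h/r - 0.5 (h/r)^3)} for
#' \code{h <= r} and \code{nugget + psill} beyond, with non-negative
#' parameter bounds. If the variogram is flat (pure nugget) the range is
#' unidentifiable and is pinned to \code{maxLag} with a warning and the
#' \code{pureNugget} flag set.
#'
#' @param vg a \code{variogram} from [empiricalVariogram()].
#' @return object of class \code{sphericalFit}: list with \code{nugget},
#'   \code{psill}, \code{range}, \code{rmse}, \code{pureNugget}.
#' @export
fitSpherical <- function(vg) {
  if (nrow(vg) < 3L) stop("need at least 3 variogram bins", call. = FALSE)
  h <- vg$lag; g <- vg$gamma; w <- vg$n
  maxLag <- attr(vg, "maxLag") %||% max(h)
  obj <- function(p) sum(w * (g - .sphericalModel(h, p[1], p[2], p[3]))^2)
  sill0 <- max(g)
  starts <- lapply(c(0.25, 0.5, 0.75), function(f) {
    c(nugget = min(g), psill = max(sill0 - min(g), 1e-8 * sill0 + 1e-12),
      range = f * maxLag)
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(0, 0, 1e-6 * maxLag),
            upper = c(Inf, Inf, 10 * maxLag),
            control = list(factr = 1e1, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("spherical fit failed to converge; pure-nugget fallback",
            call. = FALSE)
    p <- c(mean(g), 0, maxLag)
    pure <- TRUE
  } else {
    p <- best$par
    tot <- p[1] + p[2]
    pure <- tot <= 0 || p[2] / tot < 0.05
    if (pure) {
      warning("flat (pure nugget) variogram: range unidentifiable, ",
              "falling back to maxLag = ", signif(maxLag, 4), call. = FALSE)
      p[3] <- maxLag
    }
  }
  rmse <- sqrt(mean((g - .sphericalModel(h, p[1], p[2], p[3]))^2))
  structure(list(nugget = unname(p[1]), psill = unname(p[2]),
                 range = unname(p[3]), rmse = rmse, pureNugget = pure),
            class = "sphericalFit")
}

#' @export
print.sphericalFit <- function(x, ...) {
  cat(sprintf(
    "Spherical variogram fit: nugget %.4g, partial sill %.4g, range %.4g km%s\n",
    x$nugget, x$psill, x$range, if (x$pureNugget) " (pure nugget fallback)" else ""))
  invisible(x)
}

# Flat-top hexagon ids with across-flats width w: circumradius R = w/sqrt(3);
# axial coordinates with cube rounding.
.hexIds <- function(x, y, width) {
  R <- width / sqrt(3)
  qf <- (2 / 3) * x / R
  rf <- (-1 / 3 * x + sqrt(3) / 3 * y) / R
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dxs <- abs(rx - xf); dys <- abs(ry - yf); dzs <- abs(rz - zf)
  fixX <- dxs > dys & dxs > dzs
  fixY <- !fixX & dys > dzs
  rx[fixX] <- -ry[fixX] - rz[fixX]
  ry[fixY] <- -rx[fixY] - rz[fixY]
  rz[!fixX & !fixY] <- -rx[!fixX & !fixY] - ry[!fixX & !fixY]
  paste(rx, rz, sep = "_")
}

#' Build KS-balanced spatial folds over a hexagon tessellation
#'
#' The domain is tessellated into flat-top hexagons whose across-flats width
#' equals \code{rangeKm} (the fitted autocorrelation range). Hexagons are
#' assigned uniformly at random to \code{K} folds in each of \code{nSim}
#' simulations; for each simulation, two-sample Kolmogorov-Smirnov tests
#' compare the label values of every fold pair, and the assignment with the
#' maximal mean p-value is kept.
#'
#' @param points data.frame with \code{x}, \code{y} for every label row
#'   (survey and occurrence rows alike).
#' @param values label values used in the KS balance tests.
#' @param rangeKm hexagon across-flats width (km, > 0).
#' @param K number of folds (default 5).
#' @param nSim number of random assignment simulations (default 100).
#' @param seed integer seed.
#' @return A [FoldAssignment-class].
#' @export
buildFolds <- function(points, values, rangeKm, K = 5, nSim = 100, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (rangeKm <= 0) stop("rangeKm must be > 0", call. = FALSE)
  hex <- .hexIds(points$x, points$y, rangeKm)
  uh <- sort(unique(hex))
  if (length(uh) < K) {
    stop("only ", length(uh), " hexagons for ", K,
         " folds: domain too small for this range", call. = FALSE)
  }
  pairIdx <- utils::combn(K, 2)
  withr::with_seed(as.integer(seed), {
    scores <- numeric(nSim)
    draws <- vector("list", nSim)
    for (s in seq_len(nSim)) {
      # balanced random partition: hexagon counts per fold differ by at most
      # one, so K non-empty folds exist whenever there are >= K hexagons
      hf <- sample(rep_len(seq_len(K), length(uh)))
      draws[[s]] <- hf
      rf <- hf[match(hex, uh)]
      byFold <- split(values, rf)
      if (length(byFold) < K) {
        scores[s] <- -Inf
        next
      }
      ps <- apply(pairIdx, 2, function(ij) {
        a <- byFold[[as.character(ij[1])]]
        b <- byFold[[as.character(ij[2])]]
        suppressWarnings(ks.test(a, b, exact = FALSE)$p.value)
      })
      scores[s] <- mean(ps)
    }
    if (all(!is.finite(scores))) {
      stop("no simulation produced ", K, " non-empty folds", call. = FALSE)
    }
    best <- which.max(scores)
    bestFold <- draws[[best]]
    new("FoldAssignment",
        hexFold = setNames(as.integer(bestFold), uh),
        rowFold = as.integer(bestFold[match(hex, uh)]),
        rowHex = hex, K = as.integer(K),
        balanceScore = scores[best],
        candidateScores = scores, rangeKm = as.numeric(rangeKm))
  })
}

#' Map new points onto an existing fold assignment
#'
#' @param folds a [FoldAssignment-class].
#' @param points data.frame with \code{x}, \code{y}.
#' @return integer fold per point (\code{NA} for points in hexagons that
#'   carried no label data when the folds were built).
#' @export
assignHexFold <- function(folds, points) {
  hex <- .hexIds(points$x, points$y, folds@rangeKm)
  as.integer(folds@hexFold[hex])
}

#' Leave-one-fold-out splits with survey-only validation
#'
#' Split \code{k} trains on the rows of every fold except \code{k} (any
#' source) and validates on the fold-\code{k} rows whose source is
#' \code{"survey"}. Folds without survey rows yield a flagged, skipped split.
#'
#' @param table training table from [buildTrainingTable()] (needs a
#'   \code{source} column), with rows in the order used for
#'   [buildFolds()].
#' @param folds a [FoldAssignment-class] with \code{rowFold} matching the
#'   table rows.
#' @return list of K elements, each \code{list(fold, train, validation,
#'   skipped)} with integer row indices.
#' @export
looSplits <- function(table, folds) {
  if (nrow(table) != length(folds@rowFold)) {
    stop("table rows and fold assignment differ in length", call. = FALSE)
  }
  lapply(seq_len(folds@K), function(k) {
    val <- which(folds@rowFold == k & table$source == "survey")
    skipped <- length(val) == 0L
    if (skipped) {
      warning("fold ", k, " has no survey rows; split skipped", call. = FALSE)
    }
    list(fold = k, train = which(folds@rowFold != k), validation = val,
         skipped = skipped)
  })
}
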