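# Pixel-wise coefficient of variation from the fold-model prediction stack,
# and dissimilarity index / area of applicability with the 1.5*IQR + Q75
# threshold and impute-before-DI missing-value handling.

#' Coefficient-of-variation map from a prediction stack
#'
#' Per pixel, the sample standard deviation (denominator K - 1) of the K
#' fold-model predictions divided by their mean, computed on the
#' back-transformed (original trait units) scale. Pixels whose absolute
#' mean falls below \code{epsFrac} times the absolute global mean are
#' masked as undefined (sd/mean is unstable near zero).
#'
#' @param stack list of K >= 2 aligned prediction matrices.
#' @param epsFrac relative epsilon guard on the mean (default 1e-6).
#' @return matrix of COV values (NA where undefined).
#' @export
covMap <- function(stack, epsFrac = 1e-6) {
  if (length(stack) < 2L) stop("need at least 2 fold predictions", call. = FALSE)
  d <- dim(stack[[1]])
  for (m in stack) {
    if (!all(dim(m) == d)) stop("misaligned prediction stack", call. = FALSE)
  }
  K <- length(stack)
  arr <- array(unlist(stack), dim = c(d, K))
  mu <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  eps <- epsFrac * abs(mean(mu, na.rm = TRUE))
  if (!is.finite(eps) || eps == 0) eps <- 1e-12
  out <- s / mu
  out[is.na(mu) | abs(mu) < eps] <- NA_real_
  abs(out)
}

#' Impute missing feature values
#'
#' \code{median}: per-feature median computed on the training data;
#' \code{model}: per-feature boosted-tree regressor fitted on the remaining
#' (median-completed) training features. The imputer is always fitted on
#' training data only and then applied unchanged to new data: pass the
#' \code{"fit"} attribute of the training result via \code{fit}.
#'
#' @param features numeric matrix (rows x features) with NAs.
#' @param strategy \code{"median"} or \code{"model"}.
#' @param fit imputer fitted on training data (attribute \code{"fit"} of a
#'   previous call); NULL fits on \code{features}.
#' @param config [modelConfig()] for the model strategy.
#' @return completed matrix with attribute \code{"fit"}.
#' @export
imputeMissing <- function(features, strategy = c("median", "model"),
                          fit = NULL, config = modelConfig(nrounds = 50)) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(features))
  if (is.null(fit)) {
    allMissing <- colSums(!is.na(features)) == 0L
    if (any(allMissing)) {
      stop("feature(s) entirely missing: ",
           paste(colnames(features)[allMissing], collapse = ", "),
           call. = FALSE)
    }
    med <- apply(features, 2, median, na.rm = TRUE)
    fit <- list(strategy = strategy, medians = med, models = NULL)
    if (strategy == "model") {
      base <- features
      for (j in seq_len(ncol(base))) base[is.na(base[, j]), j] <- med[[j]]
      fit$models <- lapply(seq_len(ncol(features)), function(j) {
        obs <- !is.na(features[, j])
        df <- as.data.frame(base[obs, -j, drop = FALSE])
        df$label <- features[obs, j]
        fitTraitModel(df, colnames(base)[-j], weights = rep(1, sum(obs)),
                      config = config)
      })
    }
  }
  out <- features
  if (fit$strategy == "median") {
    for (j in seq_len(ncol(out))) {
      out[is.na(out[, j]), j] <- fit$medians[[j]]
    }
  } else {
    base <- features
    for (j in seq_len(ncol(base))) {
      base[is.na(base[, j]), j] <- fit$medians[[j]]
    }
    for (j in seq_len(ncol(out))) {
      miss <- is.na(features[, j])
      if (!any(miss)) next
      out[miss, j] <- predictTraitModel(
        fit$models[[j]], base[miss, -j, drop = FALSE])
    }
  }
  attr(out, "fit") <- fit
  out
}

.minCrossDist <- function(A, B) {
  # per row of A, the minimum Euclidean distance to any row of B
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Dissimilarity index of new points relative to training data
#'
#' Features are z-standardized by the training mean and sd (after
#' imputation, which is fitted on the training rows only). For each training
#' row the cross-fold nearest-neighbour distance is computed (minimum
#' distance to rows in other folds); the mean of these is the normalizing
#' distance. Training DI values are the cross-fold distances divided by that
#' mean; each new point's DI is its nearest-neighbour distance to any
#' training row divided by the same mean.
#'
#' @param trainFeatures numeric matrix of training predictor rows.
#' @param foldOfTrainRow integer fold per training row (>= 2 distinct
#'   folds).
#' @param newFeatures numeric matrix of new (prediction) rows; rows that are
#'   entirely NA yield NA DI.
#' @param imputeStrategy passed to [imputeMissing()].
#' @return list with \code{trainDI}, \code{newDI}, \code{meanTrainDist}.
#' @export
computeDI <- function(trainFeatures, foldOfTrainRow, newFeatures,
                      imputeStrategy = "median") {
  if (length(unique(foldOfTrainRow)) < 2L) {
    stop("cross-fold distances need at least two folds", call. = FALSE)
  }
  allNA <- rowSums(!is.na(newFeatures)) == 0L
  tr <- imputeMissing(trainFeatures, imputeStrategy)
  fitImp <- attr(tr, "fit")
  nw <- imputeMissing(newFeatures, imputeStrategy, fit = fitImp)
  mu <- colMeans(tr)
  sg <- apply(tr, 2, sd)
  sg[sg == 0] <- 1
  trZ <- sweep(sweep(tr, 2, mu), 2, sg, "/")
  nwZ <- sweep(sweep(nw, 2, mu), 2, sg, "/")
  n <- nrow(trZ)
  dTrain <- numeric(n)
  for (f in unique(foldOfTrainRow)) {
    inF <- foldOfTrainRow == f
    dTrain[inF] <- .minCrossDist(trZ[inF, , drop = FALSE],
                                 trZ[!inF, , drop = FALSE])
  }
  dBar <- mean(dTrain)
  if (dBar <= 0) stop("degenerate training geometry: mean cross-fold distance is 0",
                      call. = FALSE)
  newDI <- .minCrossDist(nwZ, trZ) / dBar
  newDI[allNA] <- NA_real_
  list(trainDI = dTrain / dBar, newDI = newDI, meanTrainDist = dBar)
}

#' Area-of-applicability DI threshold
#'
#' \code{Q75 + 1.5 * (Q75 - Q25)} of the training DI values, with
#' linear-interpolation quantiles. The AOA mask is \code{DI <= threshold}.
#'
#' @param trainDI training DI values (>= 4).
#' @return the threshold.
#' @examples
#' aoaThreshold(c(0, 0.1, 0.2, 0.3))  # 0.45
#' @export
aoaThreshold <- function(trainDI) {
  if (length(trainDI) < 4L) stop("need at least 4 training DI values",
                                 call. = FALSE)
  q <- quantile(trainDI, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Percentage of valid prediction pixels inside the AOA
#'
#' @param mask logical AOA matrix (TRUE inside).
#' @param validPixels logical matrix of pixels that carry a prediction.
#' @return percentage in [0, 100].
#' @export
aoaCoverage <- function(mask, validPixels) {
  if (!all(dim(mask) == dim(validPixels))) {
    stop("mask and valid-pixel raster are misaligned", call. = FALSE)
  }
  nValid <- sum(validPixels, na.rm = TRUE)
  if (nValid == 0L) stop("zero valid pixels: coverage undefined", call. = FALSE)
  100 * sum(mask & validPixels, na.rm = TRUE) / nValid
}

#' Full uncertainty product for a cross-validated run
#'
#' Combines the COV map of the fold prediction stack with the DI / AOA
#' computation over all predictor-complete pixels of the stack.
#'
#' @param run a \code{cvRun} with a non-empty \code{mapStack}.
#' @param table the training table the run was fitted on.
#' @param folds the [FoldAssignment-class] used.
#' @param env the [EnvironmentStack-class] predictions were made on.
#' @param imputeStrategy passed to [computeDI()].
#' @return An [UncertaintyProduct-class].
#' @export
uncertaintyProduct <- function(run, table, folds, env,
                               imputeStrategy = "median") {
  if (length(run$mapStack) < 2L) {
    stop("cvRun carries no prediction stack (env was not supplied)",
         call. = FALSE)
  }
  g <- env@grid
  features <- attr(table, "features")
  cov <- covMap(run$mapStack)
  X <- vapply(features, function(nm) as.vector(t(getLayer(env, nm))),
              numeric(nCells(g)))
  X <- matrix(X, ncol = length(features), dimnames = list(NULL, features))
  trainX <- .featureMatrix(table, features)
  di <- computeDI(trainX, folds@rowFold, X, imputeStrategy = imputeStrategy)
  thr <- aoaThreshold(di$trainDI)
  diMat <- matrix(di$newDI, nrow = g@nRows, byrow = TRUE)
  valid <- !is.na(run$finalMap)
  aoa <- !is.na(diMat) & diMat <= thr
  new("UncertaintyProduct", grid = g, cov = cov, di = diMat, aoa = aoa,
      diThreshold = thr, pctInsideAOA = aoaCoverage(aoa, valid),
      meanTrainDist = di$meanTrainDist)
}
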