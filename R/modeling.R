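# Missing-value-tolerant gradient-boosted trait-environment models with
# source-based sample weighting, permutation-importance feature pruning,
# leave-one-fold-out cross-validation and per-fold map prediction.

#' Model configuration
#'
#' Hyperparameters for the boosted-tree learner plus pruning settings. The
#' learner contract is a missing-value-tolerant gradient-boosted regression
#' tree ensemble; defaults are modest and fully exposed.
#'
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param maxDepth maximum tree depth.
#' @param subsample,colsample row/column subsampling per tree.
#' @param minChildWeight minimum child hessian weight.
#' @param prune run backward-elimination feature pruning per split.
#' @param pruneMaxIter maximum pruning iterations (0 disables pruning).
#' @param pruneRepeats permutation repeats used during pruning.
#' @param seed integer seed controlling all learner randomness.
#' @return list of class \code{modelConfig}.
#' @export
modelConfig <- function(nrounds = 200, eta = 0.1, maxDepth = 5,
                        subsample = 0.9, colsample = 0.9,
                        minChildWeight = 1, prune = FALSE,
                        pruneMaxIter = 3, pruneRepeats = 3, seed = 1) {
  structure(list(nrounds = nrounds, eta = eta, maxDepth = maxDepth,
                 subsample = subsample, colsample = colsample,
                 minChildWeight = minChildWeight, prune = prune,
                 pruneMaxIter = pruneMaxIter, pruneRepeats = pruneRepeats,
                 seed = as.integer(seed)),
            class = "modelConfig")
}

#' Source-balancing sample weights
#'
#' Survey rows get weight 1; occurrence rows get weight
#' \code{nSurvey / nOccurrence} so both sources contribute equal total
#' weight in the combined subset. Single-source tables get unit weights.
#'
#' @param table training table with a \code{source} column.
#' @return numeric weight per row.
#' @examples
#' tab <- data.frame(source = rep(c("survey", "occurrence"), c(100, 400)))
#' w <- computeWeights(tab)
#' sum(w[tab$source == "survey"]) == sum(w[tab$source == "occurrence"])
#' @export
computeWeights <- function(table) {
  src <- table$source
  nS <- sum(src == "survey")
  nO <- sum(src == "occurrence")
  w <- rep(1, nrow(table))
  if (nS > 0 && nO > 0) w[src == "occurrence"] <- nS / nO
  w
}

.featureMatrix <- function(rows, features) {
  m <- as.matrix(rows[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit a boosted-tree trait model
#'
#' Deterministic under a fixed seed and input order; tolerates missing
#' predictor values at fit and predict time (missing values are routed to
#' the loss-minimizing side of each split). All-missing features are dropped
#' with a warning.
#'
#' @param rows training rows (data.frame with \code{label} and feature
#'   columns).
#' @param features feature column names.
#' @param weights optional per-row weights (default [computeWeights()]).
#' @param config a [modelConfig()].
#' @param transform optional \code{yjTransform} carried for back-transform.
#' @return object of class \code{traitModel}: list with the fitted booster,
#'   \code{features}, \code{transform} and training metadata.
#' @export
fitTraitModel <- function(rows, features, weights = NULL,
                          config = modelConfig(), transform = NULL) {
  if (nrow(rows) < 10L) stop("too few training rows", call. = FALSE)
  X <- .featureMatrix(rows, features)
  allMissing <- colSums(!is.na(X)) == 0L
  if (any(allMissing)) {
    warning("dropping all-missing feature(s): ",
            paste(features[allMissing], collapse = ", "), call. = FALSE)
    features <- features[!allMissing]
    X <- X[, !allMissing, drop = FALSE]
  }
  if (is.null(weights)) {
    weights <- if ("source" %in% names(rows)) computeWeights(rows) else
      rep(1, nrow(rows))
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = rows$label, weight = weights,
                                 missing = NA)
  params <- list(objective = "reg:squarederror", eta = config$eta,
                 max_depth = config$maxDepth, subsample = config$subsample,
                 colsample_bytree = config$colsample,
                 min_child_weight = config$minChildWeight,
                 nthread = 1, seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$nrounds, verbose = 0)
  structure(list(booster = booster, features = features,
                 transform = transform, config = config,
                 meta = list(nRows = nrow(rows),
                             nSurvey = sum(rows$source == "survey"),
                             nOccurrence = sum(rows$source == "occurrence"))),
            class = "traitModel")
}

#' Predict from a trait model
#'
#' @param model a \code{traitModel}.
#' @param rows data.frame (or matrix) containing the model's feature
#'   columns; missing values are tolerated.
#' @param backTransform return predictions on the original trait scale via
#'   the stored transform.
#' @return numeric predictions.
#' @export
predictTraitModel <- function(model, rows, backTransform = FALSE) {
  X <- if (is.matrix(rows)) rows[, model$features, drop = FALSE] else
    .featureMatrix(rows, model$features)
  p <- predict(model$booster, xgboost::xgb.DMatrix(X, missing = NA))
  if (backTransform) {
    if (is.null(model$transform)) {
      stop("model carries no transform to invert", call. = FALSE)
    }
    p <- invertYeoJohnson(p, model$transform)
  }
  p
}

#' Permutation importance of features or feature groups
#'
#' For each feature (or group, shuffled jointly) the importance is the mean
#' over repeats of \code{loss(shuffled) - loss(intact)}, with squared-error
#' loss on the transformed label scale, evaluated on held-out rows. A
#' feature the model never splits on has importance exactly 0.
#'
#' @param model a \code{traitModel}.
#' @param rows held-out evaluation rows (disjoint from training rows).
#' @param labels observed labels for \code{rows} (transformed scale).
#' @param groups optional named list of feature groups; default one group
#'   per model feature.
#' @param nRepeats shuffle repeats.
#' @param seed integer seed.
#' @return data.frame with columns \code{feature}, \code{importance},
#'   \code{se}.
#' @export
permutationImportance <- function(model, rows, labels, groups = NULL,
                                  nRepeats = 5, seed = 1) {
  X <- .featureMatrix(rows, model$features)
  if (is.null(groups)) {
    groups <- setNames(as.list(model$features), model$features)
  }
  unknown <- setdiff(unlist(groups), model$features)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- predict(model$booster, xgboost::xgb.DMatrix(X, missing = NA))
  baseLoss <- mean((labels - base)^2)
  withr::with_seed(as.integer(seed), {
    res <- lapply(names(groups), function(gn) {
      cols <- match(groups[[gn]], model$features)
      d <- vapply(seq_len(nRepeats), function(r) {
        Xp <- X
        perm <- sample.int(nrow(X))
        Xp[, cols] <- X[perm, cols, drop = FALSE]
        p <- predict(model$booster, xgboost::xgb.DMatrix(Xp, missing = NA))
        mean((labels - p)^2) - baseLoss
      }, numeric(1))
      data.frame(feature = gn, importance = mean(d),
                 se = if (nRepeats > 1) sd(d) / sqrt(nRepeats) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Backward-elimination feature pruning
#'
#' Iteratively fits on the training rows, computes permutation importance on
#' the held-out tuning rows, drops every feature with importance <= 0 and
#' refits, stopping when no feature qualifies or after
#' \code{config$pruneMaxIter} iterations (\code{pruneMaxIter = 0} returns
#' the input feature list unchanged). If pruning would remove every feature,
#' the single best is kept with a warning.
#'
#' @param trainRows training rows.
#' @param tuneRows held-out tuning rows (disjoint from \code{trainRows}).
#' @param features starting feature list.
#' @param config a [modelConfig()].
#' @return character vector of surviving features.
#' @export
pruneFeatures <- function(trainRows, tuneRows, features,
                          config = modelConfig()) {
  if (config$pruneMaxIter <= 0) return(features)
  for (it in seq_len(config$pruneMaxIter)) {
    model <- fitTraitModel(trainRows, features, config = config)
    imp <- permutationImportance(model, tuneRows, tuneRows$label,
                                 nRepeats = config$pruneRepeats,
                                 seed = config$seed + it)
    drop <- imp$feature[imp$importance <= 0]
    if (length(drop) == 0L) break
    if (length(drop) == length(features)) {
      warning("pruning would remove all features; keeping the best one",
              call. = FALSE)
      features <- imp$feature[which.max(imp$importance)]
      break
    }
    features <- setdiff(features, drop)
  }
  features
}

.predictMap <- function(model, env, backTransform = TRUE) {
  g <- env@grid
  feats <- model$features
  X <- vapply(feats, function(nm) as.vector(t(getLayer(env, nm))),
              numeric(nCells(g)))
  X <- matrix(X, ncol = length(feats), dimnames = list(NULL, feats))
  anyPresent <- rowSums(!is.na(X)) > 0
  p <- rep(NA_real_, nrow(X))
  if (any(anyPresent)) {
    p[anyPresent] <- predictTraitModel(model, X[anyPresent, , drop = FALSE],
                                       backTransform = backTransform)
  }
  matrix(p, nrow = g@nRows, byrow = TRUE)
}

#' Cross-validated model run
#'
#' For each leave-one-fold-out split: optionally prune features against an
#' internal tuning fold drawn from the training partition, fit a model,
#' predict the held-out survey validation rows, and (if a predictor stack is
#' given) predict a full map on the original trait scale. A final model is
#' fitted on all rows for the production map. Importances are averaged over
#' folds.
#'
#' @param table training table from [buildTrainingTable()].
#' @param folds a [FoldAssignment-class] aligned with \code{table} rows.
#' @param config a [modelConfig()].
#' @param env optional [EnvironmentStack-class] for per-split map
#'   prediction.
#' @param groups optional feature groups for the importance report.
#' @param validation optional external validation source as
#'   \code{list(table, fold)}: a survey-labelled table plus its per-row fold
#'   ids (e.g. from [assignHexFold()]). Needed when the training table
#'   itself carries no survey rows (the occurrence-only subset), whose
#'   models are still validated against held-out survey community-weighted
#'   means. Default: the training table's own survey rows.
#' @return list of class \code{cvRun}: \code{splits} (per-split models and
#'   indices), \code{pooled} (observed/predicted/fold/stratum for all
#'   survey validation rows), \code{mapStack} (per-split prediction
#'   matrices, original scale), \code{finalModel}, \code{finalMap},
#'   \code{importance}, \code{skippedFolds}.
#' @export
cvRun <- function(table, folds, config = modelConfig(), env = NULL,
                  groups = NULL, validation = NULL) {
  features <- attr(table, "features")
  if (is.null(features)) {
    stop("table lacks a 'features' attribute (use buildTrainingTable)",
         call. = FALSE)
  }
  transform <- attr(table, "transform")
  if (is.null(validation)) {
    splits <- looSplits(table, folds)
  } else {
    splits <- lapply(seq_len(folds@K), function(k) {
      val <- which(validation$fold == k)
      list(fold = k, train = which(folds@rowFold != k), validation = val,
           skipped = length(val) == 0L)
    })
  }
  valSource <- if (is.null(validation)) table else validation$table
  pooled <- list()
  mapStack <- list()
  impList <- list()
  outSplits <- list()
  for (sp in splits) {
    if (sp$skipped) next
    trainTab <- table[sp$train, , drop = FALSE]
    feats <- features
    if (isTRUE(config$prune) && config$pruneMaxIter > 0) {
      # internal tuning fold: the smallest-index other fold within training
      trainFolds <- folds@rowFold[sp$train]
      tuneFold <- min(setdiff(unique(trainFolds), sp$fold))
      tuneIdx <- trainFolds == tuneFold
      feats <- pruneFeatures(trainTab[!tuneIdx, , drop = FALSE],
                             trainTab[tuneIdx, , drop = FALSE],
                             features, config)
    }
    model <- fitTraitModel(trainTab, feats, config = config,
                           transform = transform)
    valTab <- valSource[sp$validation, , drop = FALSE]
    pred <- predictTraitModel(model, valTab)
    pooled[[length(pooled) + 1L]] <- data.frame(
      fold = sp$fold, observed = valTab$label, predicted = pred,
      stratum = valTab$stratum, stringsAsFactors = FALSE)
    impList[[length(impList) + 1L]] <-
      permutationImportance(model, valTab, valTab$label, groups = groups,
                            nRepeats = config$pruneRepeats,
                            seed = config$seed + sp$fold)
    if (!is.null(env)) {
      mapStack[[length(mapStack) + 1L]] <- .predictMap(model, env)
    }
    outSplits[[length(outSplits) + 1L]] <-
      list(fold = sp$fold, model = model, validation = sp$validation,
           features = feats)
  }
  if (length(pooled) == 0L) {
    stop("every fold was skipped: no survey validation rows", call. = FALSE)
  }
  pooledDf <- do.call(rbind, pooled)
  imp <- do.call(rbind, impList)
  impAvg <- aggregate(importance ~ feature, imp, mean)
  finalModel <- fitTraitModel(table, features, config = config,
                              transform = transform)
  finalMap <- if (is.null(env)) NULL else .predictMap(finalModel, env)
  structure(list(splits = outSplits, pooled = pooledDf, mapStack = mapStack,
                 finalModel = finalModel, finalMap = finalMap,
                 importance = impAvg[order(-impAvg$importance), ],
                 skippedFolds = vapply(splits, function(s) s$skipped,
                                       logical(1))),
            class = "cvRun")
}

#' Enumerate planned model tasks
#'
#' One model task per (trait, resolution, subset) combination; the standard
#' full design of 31 traits x 5 resolutions x 3 subsets enumerates 465
#' tasks.
#'
#' @param traits character vector of trait names.
#' @param resolutions numeric vector of cell edge lengths (km).
#' @param subsets subset labels (default SCI, CIT, COMB).
#' @return data.frame with one row per task.
#' @export
planModelTasks <- function(traits, resolutions,
                           subsets = c("SCI", "CIT", "COMB")) {
  out <- expand.grid(trait = traits, resolution = resolutions,
                     subset = subsets, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out[order(out$trait, out$resolution, out$subset), ]
}
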