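# Source weighting, boosted-tree fitting, permutation importance, pruning
# and the cross-validated run.

test_that("computeWeights balances total source weight", {
  tab <- data.frame(source = rep(c("survey", "occurrence"), c(100, 400)))
  w <- computeWeights(tab)
  expect_equal(unique(w[tab$source == "occurrence"]), 0.25)
  expect_equal(sum(w[tab$source == "survey"]),
               sum(w[tab$source == "occurrence"]))
  expect_true(all(computeWeights(data.frame(source = rep("survey", 7))) == 1))
  expect_true(all(computeWeights(
    data.frame(source = rep(c("survey", "occurrence"), each = 50))) == 1))
})

test_that("duplicating occurrence rows leaves total source weight unchanged", {
  tab <- data.frame(source = rep(c("survey", "occurrence"), c(60, 90)))
  dup <- rbind(tab, tab[tab$source == "occurrence", , drop = FALSE])
  w1 <- computeWeights(tab)
  w2 <- computeWeights(dup)
  expect_equal(sum(w1[tab$source == "occurrence"]),
               sum(w2[dup$source == "occurrence"]))
})

test_that("fitTraitModel learns, tolerates NAs, and is deterministic", {
  set.seed(20)
  n <- 500
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 3 * X[, 1]
  tab <- makeTable(runif(n), runif(n), y, X)
  hold <- 401:500
  cfg <- modelConfig(nrounds = 500, eta = 0.3, maxDepth = 3, subsample = 1,
                     colsample = 1, seed = 5)
  m <- fitTraitModel(tab[-hold, ], c("x1", "x2", "x3"), config = cfg)
  p <- predictTraitModel(m, tab[hold, ])
  r2 <- 1 - sum((y[hold] - p)^2) / sum((y[hold] - mean(y[hold]))^2)
  expect_gte(r2, 0.99)

  # constant labels -> constant predictions
  tabC <- makeTable(runif(50), runif(50), rep(2.5, 50),
                    matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x1")))
  mC <- fitTraitModel(tabC, "x1", config = modelConfig(nrounds = 20))
  expect_true(all(abs(predictTraitModel(mC, tabC) - 2.5) < 1e-6))

  # missing predictors still give finite predictions
  Xna <- X; Xna[1:50, 1] <- NA
  tabNA <- makeTable(runif(n), runif(n), y, Xna)
  mNA <- fitTraitModel(tabNA, c("x1", "x2", "x3"), config = cfg)
  expect_true(all(is.finite(predictTraitModel(mNA, tabNA[1:50, ]))))

  # all-missing feature dropped with warning
  Xam <- X; Xam[, 3] <- NA
  expect_warning(mAM <- fitTraitModel(makeTable(runif(n), runif(n), y, Xam),
                                      c("x1", "x2", "x3"), config = cfg),
                 "all-missing")
  expect_equal(mAM$features, c("x1", "x2"))

  # determinism under fixed config + seed
  m2 <- fitTraitModel(tab[-hold, ], c("x1", "x2", "x3"), config = cfg)
  expect_identical(predictTraitModel(m2, tab[hold, ]), p)
})

test_that("permutation importance separates signal from noise", {
  set.seed(30)
  n <- 600
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("signal", "noise1", "noise2")))
  y <- 2 * X[, "signal"]
  tab <- makeTable(runif(n), runif(n), y, X)
  m <- fitTraitModel(tab[1:400, ], colnames(X),
                     config = modelConfig(nrounds = 150, eta = 0.2,
                                          colsample = 1))
  imp <- permutationImportance(m, tab[401:600, ], y[401:600],
                               nRepeats = 20, seed = 3)
  expect_gt(imp$importance[imp$feature == "signal"], 0)
  for (f in c("noise1", "noise2")) {
    row <- imp[imp$feature == f, ]
    expect_lt(abs(row$importance), 2 * row$se + 1e-4)
  }
  # a feature never offered to the model has importance exactly 0
  m1 <- fitTraitModel(tab[1:400, ], c("signal", "noise1"),
                      config = modelConfig(nrounds = 50, colsample = 1,
                                           subsample = 1))
  # refit with noise2 present in the matrix but constant -> never split on
  X2 <- X; X2[, "noise2"] <- 1
  tab2 <- makeTable(runif(n), runif(n), y, X2)
  m2 <- fitTraitModel(tab2[1:400, ], colnames(X2),
                      config = modelConfig(nrounds = 50, colsample = 1,
                                           subsample = 1))
  imp2 <- permutationImportance(m2, tab2[401:600, ], y[401:600],
                                nRepeats = 3, seed = 1)
  expect_identical(imp2$importance[imp2$feature == "noise2"], 0)
  # groups are shuffled jointly
  impG <- permutationImportance(m, tab[401:600, ], y[401:600],
                                groups = list(all = c("signal", "noise1"),
                                              rest = "noise2"),
                                nRepeats = 5, seed = 2)
  expect_gt(impG$importance[impG$feature == "all"], 0)
  expect_error(permutationImportance(m, tab[401:600, ], y[401:600],
                                     groups = list(bad = "nope")), "unknown")
})

test_that("pruneFeatures removes noise, keeps signal, honours maxIter 0", {
  set.seed(40)
  n <- 700
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("s1", "s2", "n1", "n2")))
  y <- X[, "s1"] + X[, "s2"]
  tab <- makeTable(runif(n), runif(n), y, X)
  cfg <- modelConfig(nrounds = 120, eta = 0.2, colsample = 1,
                     pruneMaxIter = 4, pruneRepeats = 5, seed = 2)
  kept <- pruneFeatures(tab[1:500, ], tab[501:700, ], colnames(X), cfg)
  expect_true(all(c("s1", "s2") %in% kept))
  expect_false(any(c("n1", "n2") %in% kept))

  cfg0 <- modelConfig(pruneMaxIter = 0)
  expect_identical(pruneFeatures(tab[1:500, ], tab[501:700, ],
                                 colnames(X), cfg0), colnames(X))
})

test_that("cvRun produces K split models, pooled pairs and a final model", {
  w <- miniWorld(seed = 23)
  means <- speciesMeans(w$traitDB)
  cwm <- plotCWM(w$surveys, means, "sla")
  cwmGrid <- gridTraitValues(cwm, w$grid, "cwm_mean", traitName = "sla")
  tab <- buildTrainingTable(cwmGrid, w$env, strata = w$strata)
  folds <- buildFolds(tab[, c("x", "y")], tab$label, rangeKm = 8, K = 5,
                      nSim = 20, seed = 7)
  cfg <- modelConfig(nrounds = 80, seed = 3)
  run <- cvRun(tab, folds, cfg, env = w$env)
  expect_length(run$splits, 5)
  expect_s3_class(run$finalModel, "traitModel")
  expect_length(run$mapStack, 5)
  # pooled pairs bookkeeping: all survey validation rows, once each
  expect_equal(nrow(run$pooled),
               sum(tab$source == "survey" & !is.na(folds@rowFold)))
  # determinism end to end
  run2 <- cvRun(tab, folds, cfg, env = w$env)
  expect_identical(run$pooled$predicted, run2$pooled$predicted)
  expect_identical(run$finalMap, run2$finalMap)
})

test_that("planModelTasks enumerates the full cross product", {
  tasks <- planModelTasks(c("sla", "height"), c(1, 22), c("SCI", "COMB"))
  expect_equal(nrow(tasks), 8)
  expect_equal(nrow(unique(tasks)), 8)
  full <- planModelTasks(paste0("t", 1:31), c(1, 22, 55, 111, 222))
  expect_equal(nrow(full), 465)
})
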