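# Cell assignment, per-cell subsampling, trait grids, COMB merge, predictor
# aggregation, the power transform and the training-table filter.

test_that("assignCells uses half-open cells with the floor rule", {
  g <- gridSpec(0, 0, 1, 10, 10)
  expect_equal(assignCells(data.frame(x = 0, y = 0), g)$cell, 1L)
  # boundary point belongs to the higher-index cell's lower edge
  expect_equal(assignCells(data.frame(x = 1, y = 0), g)$col, 1L)
  expect_equal(assignCells(data.frame(x = 0, y = 1), g)$row, 1L)
  out <- assignCells(data.frame(x = c(-0.1, 10), y = c(5, 5)), g)
  expect_true(all(!out$inside))
  expect_true(all(is.na(out$cell)))

  set.seed(5)
  pts <- data.frame(x = runif(1000, 0, 10), y = runif(1000, 0, 10))
  ac <- assignCells(pts, g)
  expect_true(all(ac$inside))
  expect_true(all(ac$col %in% 0:9 & ac$row %in% 0:9))
  expect_equal(sum(table(ac$cell)), 1000)   # conservation
})

test_that("subsampleOccurrences enforces the 10-500 per-cell rule", {
  g <- gridSpec(0, 0, 1, 3, 1)
  mk <- function(cellX, n) data.frame(
    recordId = sprintf("c%d_%d", cellX, seq_len(n)),
    x = cellX + 0.5, y = 0.5, binomial = "genus a", trait = "t", value = 1)
  tagged <- rbind(mk(0, 7), mk(1, 620), mk(2, 250))
  out <- subsampleOccurrences(tagged, g, seed = 8)
  counts <- table(assignCells(out, g)$cell)
  expect_false("1" %in% names(counts))          # 7 < 10 -> cell dropped
  expect_equal(unname(counts[["2"]]), 500)      # 620 -> exactly 500
  expect_equal(unname(counts[["3"]]), 250)      # within bounds untouched
  expect_true(all(counts >= 10 & counts <= 500))
  # determinism
  expect_identical(out, subsampleOccurrences(tagged, g, seed = 8))
  expect_false(identical(out$recordId,
                         subsampleOccurrences(tagged, g, seed = 9)$recordId))
  expect_error(subsampleOccurrences(tagged, g, minOcc = 0, seed = 1), "minOcc")
})

test_that("gridTraitValues averages per cell and flags the source", {
  g <- gridSpec(0, 0, 1, 2, 1)
  rows <- data.frame(recordId = 1:3, x = c(0.2, 0.5, 0.9), y = 0.5,
                     binomial = "a b", trait = "t", value = c(2, 4, 6))
  tg <- gridTraitValues(rows, g, "fwm")
  expect_equal(tg@values[1, 1], 4)
  expect_equal(tg@counts[1, 1], 3L)
  expect_equal(tg@source[1, 1], "occurrence")
  expect_true(is.na(tg@values[1, 2]))

  cwm <- data.frame(plotId = "p", x = 1.5, y = 0.5, trait = "t", cwm = 9)
  sg <- gridTraitValues(cwm, g, "cwm_mean")
  expect_equal(sg@values[1, 2], 9)
  expect_equal(sg@source[1, 2], "survey")

  const <- gridTraitValues(transform(rows, value = 5), g, "fwm")
  expect_true(all(const@values[!is.na(const@values)] == 5))
  empty <- gridTraitValues(rows[0, ], g, "fwm")
  expect_true(all(is.na(empty@values)))
})

test_that("mergeComb gives survey precedence and unions occupancy", {
  g <- gridSpec(0, 0, 1, 3, 1)
  cwm <- gridTraitValues(data.frame(plotId = "p", x = 0.5, y = 0.5,
                                    trait = "t", cwm = 3), g, "cwm_mean")
  fwm <- gridTraitValues(data.frame(recordId = 1:2, x = c(0.5, 1.5), y = 0.5,
                                    binomial = "a b", trait = "t",
                                    value = c(9, 9)), g, "fwm")
  comb <- mergeComb(cwm, fwm)
  expect_equal(comb@values[1, 1], 3)               # survey wins
  expect_equal(comb@source[1, 1], "survey")
  expect_equal(comb@values[1, 2], 9)               # occurrence-only cell
  expect_equal(comb@source[1, 2], "occurrence")
  occ <- !is.na(comb@values)
  expect_equal(occ, !is.na(cwm@values) | !is.na(fwm@values))
  expect_error(mergeComb(cwm, gridTraitValues(data.frame(
    recordId = 1, x = 0.5, y = 0.5, binomial = "a b", trait = "t",
    value = 1), gridSpec(0, 0, 1, 4, 1), "fwm")), "same GridSpec")
})

test_that("aggregatePredictors does nodata-aware area-weighted means", {
  src <- gridSpec(0, 0, 1, 2, 2)
  tgt <- gridSpec(0, 0, 2, 1, 1)
  m <- matrix(c(3, 1, 4, 2), 2, 2)   # column-major: [1,1]=3 [2,1]=1 ...
  env <- environmentStack(src, list(a = m, const = matrix(7, 2, 2)))
  ag <- aggregatePredictors(env, tgt)
  expect_equal(getLayer(ag, "a")[1, 1], 2.5)
  expect_equal(getLayer(ag, "const")[1, 1], 7)

  m2 <- matrix(c(1, NA, 2, NA), 2, 2)
  ag2 <- aggregatePredictors(environmentStack(src, list(a = m2)), tgt)
  expect_equal(getLayer(ag2, "a")[1, 1], 1.5)   # renormalized over valid area
  ag3 <- aggregatePredictors(environmentStack(
    src, list(a = matrix(NA_real_, 2, 2))), tgt)
  expect_true(is.na(getLayer(ag3, "a")[1, 1]))
  expect_error(aggregatePredictors(environmentStack(tgt, list(
    a = matrix(1, 1, 1))), src), "finer")
})

test_that("aggregation conserves the global mean on nodata-free layers", {
  src <- gridSpec(0, 0, 1, 12, 12)
  set.seed(3)
  m <- matrix(rnorm(144), 12, 12)
  env <- environmentStack(src, list(a = m))
  for (edge in c(2, 3)) {
    tgt <- gridSpec(0, 0, edge, 12 / edge, 12 / edge)
    ag <- aggregatePredictors(env, tgt)
    expect_equal(mean(getLayer(ag, "a")), mean(m), tolerance = 1e-9)
  }
})

test_that("Yeo-Johnson transform satisfies its closed-form contracts", {
  p1 <- structure(list(lambda = 1, mean = 0, sd = 1), class = "yjTransform")
  x <- c(0, 0.5, 2, 10)
  expect_equal(applyYeoJohnson(x, p1), x, tolerance = 1e-12)
  for (lam in c(-1, 0, 0.5, 1, 2, 3)) {
    p <- structure(list(lambda = lam, mean = 0, sd = 1), class = "yjTransform")
    expect_equal(applyYeoJohnson(0, p), 0)
    set.seed(lam * 7 + 11)
    z <- c(rnorm(50, 0, 3), -5, 5)
    expect_equal(invertYeoJohnson(applyYeoJohnson(z, p), p), z,
                 tolerance = 1e-8)
  }
  # fitted transform round-trips on its own support, mixed signs
  set.seed(2)
  v <- c(rlnorm(300), -rlnorm(100, -1))
  fit <- fitYeoJohnson(v, standardize = TRUE)
  expect_equal(invertYeoJohnson(applyYeoJohnson(v, fit), fit), v,
               tolerance = 1e-8)
  # ML lambda symmetrizes a right-skewed sample
  expect_lt(fit$lambda, 1)
  expect_error(fitYeoJohnson(c(1, Inf)), "non-finite")
})

test_that("buildTrainingTable applies the 60% completeness filter", {
  g <- gridSpec(0, 0, 1, 5, 2)
  nFeat <- 10
  layers <- setNames(lapply(1:nFeat, function(i) matrix(i, 2, 5)),
                     paste0("f", 1:nFeat))
  # cell 1: 5/10 present (50%) -> dropped; cell 2: 6/10 (60%) -> kept;
  # cell 3: complete -> kept
  for (i in 1:5) layers[[i]][1, 1] <- NA
  for (i in 1:4) layers[[i]][1, 2] <- NA
  env <- environmentStack(g, layers)
  tg <- gridTraitValues(data.frame(
    plotId = paste0("p", 1:3), x = c(0.5, 1.5, 2.5), y = 0.5,
    trait = "t", cwm = c(1, 2, 3)), g, "cwm_mean")
  tab <- buildTrainingTable(tg, env)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$labelRaw, c(2, 3))
  expect_equal(attr(tab, "features"), paste0("f", 1:nFeat))
  tr <- attr(tab, "transform")
  expect_equal(invertYeoJohnson(tab$label, tr), tab$labelRaw,
               tolerance = 1e-8)
  expect_error(buildTrainingTable(tg, env, minPredictorFrac = 1.01),
               "no training rows")
})
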