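# Synthetic world generators: determinism, distributional contracts and the
# ground-truth CWM oracle.

test_that("generateEnvironment honours degenerate and determinism contracts", {
  g <- gridSpec(0, 0, 1, 12, 15)
  flat <- generateEnvironment(g, "e", autocorrRangeKm = 5, noiseSd = 0,
                              base = 3.5, seed = 1)
  expect_true(all(getLayer(flat, "e") == 3.5))

  e1 <- generateEnvironment(g, c("a", "b"), 5, seed = 42)
  e2 <- generateEnvironment(g, c("a", "b"), 5, seed = 42)
  e3 <- generateEnvironment(g, c("a", "b"), 5, seed = 43)
  expect_identical(e1@layers, e2@layers)
  expect_false(identical(e1@layers, e3@layers))
  # independent layers, marginal sd ~ 1 by construction
  expect_equal(sd(as.vector(getLayer(e1, "a"))), 1, tolerance = 1e-9)

  expect_error(generateEnvironment(g, "e", autocorrRangeKm = -1, seed = 1),
               "autocorrRangeKm")
  expect_error(generateEnvironment(g, character(0), 5, seed = 1), "layerNames")
})

test_that("realized autocorrelation range matches the request", {
  g <- gridSpec(0, 0, 1, 200, 200)
  env <- generateEnvironment(g, "e", autocorrRangeKm = 30, seed = 1)
  cc <- cellCenters(g)
  set.seed(99)
  idx <- sample(nrow(cc), 4000)
  vg <- empiricalVariogram(cc[idx, ], as.vector(t(getLayer(env, "e")))[idx],
                           nBins = 15, maxLag = 60, seed = 1)
  fit <- fitSpherical(vg)
  expect_lt(abs(fit$range - 30) / 30, 0.3)
})

test_that("generateSpeciesPool: moments, uniqueness, determinism", {
  niche <- list(axes = "env1")
  degenerate <- generateSpeciesPool(
    2, list(t = list(dist = "constant", value = 7)), niche, seed = 1)
  expect_equal(unname(traitValues(degenerate)[, "t"]), c(7, 7))

  pool <- generateSpeciesPool(
    1000, list(mass = list(dist = "lognormal", meanlog = 0, sdlog = 1)),
    niche, seed = 5)
  expect_false(anyDuplicated(binomials(pool)) > 0)
  expect_lt(abs(mean(log(traitValues(pool)[, "mass"]))), 0.1)

  again <- generateSpeciesPool(
    1000, list(mass = list(dist = "lognormal", meanlog = 0, sdlog = 1)),
    niche, seed = 5)
  expect_identical(traitValues(pool), traitValues(again))

  expect_error(generateSpeciesPool(
    5, setNames(list(list(dist = "constant", value = 1),
                     list(dist = "constant", value = 2)), c("t", "t")),
    niche, seed = 1), "duplicate")
})

test_that("simulateCommunities follows the Gaussian niche model", {
  g <- gridSpec(0, 0, 1, 4, 4)
  env <- environmentStack(g, list(env1 = matrix(0, 4, 4)))
  # identical niches -> equal covers everywhere
  pool <- makePool(data.frame(t = c(1, 2, 3)))
  comm <- simulateCommunities(env, pool)
  expect_true(all(abs(comm@cover - 1 / 3) < 1e-12))

  # monotone response: species with optimum at the cell's env dominates
  pool2 <- makePool(data.frame(t = c(1, 2)))
  pool2@optima[, 1] <- c(0, 10)
  comm2 <- simulateCommunities(env, pool2)
  expect_true(all(comm2@cover[, 1] > comm2@cover[, 2]))

  # hand renormalization: responses (0.2, 0.6) -> covers (0.25, 0.75)
  # env = 0; choose optima/breadths so exp(-opt^2/2b^2) = 0.2 and 0.6
  pool3 <- makePool(data.frame(t = c(1, 2)))
  pool3@optima[, 1] <- sqrt(-2 * log(c(0.2, 0.6)))
  comm3 <- simulateCommunities(env, pool3)
  expect_equal(unname(comm3@cover[1, ]), c(0.25, 0.75), tolerance = 1e-12)

  expect_error(simulateCommunities(
    environmentStack(g, list(other = matrix(0, 4, 4))), pool),
    "missing from environment")
})

test_that("sampleSurveys records exact cell communities and clusters", {
  g <- gridSpec(0, 0, 1, 2, 1)
  covers <- rbind(c(0.25, 0.75), c(0.5, 0.5))
  comm <- makeCommunity(g, covers)
  sv <- sampleSurveys(comm, 8, list(nClusters = 1, sdKm = 10), seed = 3)
  # every plot's covers are exactly the cell's community
  for (pid in unique(sv$plotId)) {
    pl <- sv[sv$plotId == pid, ]
    cell <- assignCells(pl[1, ], g)$cell
    expect_equal(sort(pl$cover), sort(covers[cell, ][covers[cell, ] > 0]),
                 tolerance = 1e-12)
    expect_equal(sum(pl$cover), 1, tolerance = 1e-9)
  }
  # tight single cluster keeps plots near the centre
  g2 <- gridSpec(0, 0, 1, 50, 50)
  comm2 <- makeCommunity(g2, matrix(1 / 2, nCells(g2), 2))
  ctr <- data.frame(x = 25, y = 25)
  sv2 <- sampleSurveys(comm2, 40, list(centers = ctr, sdKm = 0.8), seed = 4)
  plots <- sv2[!duplicated(sv2$plotId), ]
  d <- sqrt((plots$x - 25)^2 + (plots$y - 25)^2)
  expect_lt(quantile(d, 0.95), 3 * 0.8)

  expect_error(sampleSurveys(comm, 3, list(nClusters = 1, sdKm = 5),
                             seed = 1, uniqueCells = TRUE), "occupied cells")
})

test_that("sampleOccurrences follows effort and detectability", {
  g <- gridSpec(0, 0, 1, 2, 1)
  comm <- makeCommunity(g, rbind(c(0.5, 0.5), c(0.5, 0.5)))
  # zero effort in cell 2 -> no records there
  eff <- matrix(c(1, 0), 1, 2)
  occ <- sampleOccurrences(comm, 500, effort = eff, seed = 2)
  expect_true(all(assignCells(occ, g)$cell == 1))
  # equal covers, equal detectability: frequencies 0.5 +- 0.02 at n = 1e4
  occ2 <- sampleOccurrences(comm, 10000, effort = eff, seed = 7)
  f <- table(occ2$binomial) / nrow(occ2)
  expect_true(all(abs(f - 0.5) < 0.02))
  # zero detectability silences a species completely
  det <- setNames(c(1, 0), colnames(comm@cover))
  occ3 <- sampleOccurrences(comm, 300, detectability = det, seed = 5)
  expect_true(all(occ3$binomial == colnames(comm@cover)[1]))
  # reproducibility
  expect_identical(sampleOccurrences(comm, 50, seed = 9),
                   sampleOccurrences(comm, 50, seed = 9))
  expect_error(sampleOccurrences(comm, 10, effort = matrix(0, 1, 2),
                                 seed = 1), "all-zero")
})

test_that("occurrence species frequencies converge to cover x detectability", {
  g <- gridSpec(0, 0, 1, 1, 1)
  p <- c(0.15, 0.25, 0.6)
  comm <- makeCommunity(g, matrix(p, 1, 3))
  occ <- sampleOccurrences(comm, 10000, seed = 21)
  obs <- table(factor(occ$binomial, levels = colnames(comm@cover)))
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
})

test_that("subsetTraitDB: coverage, noise level and noise-free identity", {
  pool <- generateSpeciesPool(
    100, list(t = list(dist = "lognormal", meanlog = 1, sdlog = 0.3)),
    list(axes = "env1"), seed = 2)
  exact <- subsetTraitDB(pool, coverageFraction = 1, intraspecificCv = 0,
                         seed = 1)
  expect_equal(exact$value,
               traitValues(pool)[match(exact$species, binomials(pool)), "t"],
               tolerance = 1e-12)

  half <- subsetTraitDB(pool, coverageFraction = 0.5, seed = 3)
  expect_equal(length(unique(half$species)), 50)

  noisy <- subsetTraitDB(pool, coverageFraction = 1, intraspecificCv = 0.1,
                         nMeasPerSpecies = 200, seed = 4)
  cvs <- tapply(noisy$value, noisy$species, function(v) sd(v) / mean(v))
  expect_lt(abs(mean(cvs) - 0.1), 0.03)

  expect_error(subsetTraitDB(pool, coverageFraction = 0, seed = 1),
               "coverageFraction")
})

test_that("trueCWMSurface matches hand oracles and stays convex", {
  g <- gridSpec(0, 0, 1, 2, 2)
  pool <- makePool(data.frame(t = c(10, 30)))
  comm <- makeCommunity(g, matrix(0.5, 4, 2))
  expect_true(all(trueCWMSurface(comm, pool, "t") == 20))

  pool2 <- makePool(data.frame(t = c(5, 20)))
  covers <- rbind(c(0.6, 0.4), c(1, 0), c(0, 1), c(0, 0))
  comm2 <- makeCommunity(g, covers)
  s <- trueCWMSurface(comm2, pool2, "t")
  v <- as.vector(t(s))                       # cell-id order
  expect_equal(v[1], 11)                     # 0.6*5 + 0.4*20
  expect_equal(v[2], 5)                      # single species
  expect_equal(v[3], 20)
  expect_true(is.na(v[4]))                   # empty cell -> nodata
  rng <- range(traitValues(pool2))
  expect_true(all(v[!is.na(v)] >= rng[1] & v[!is.na(v)] <= rng[2]))
})
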