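# Synthetic miniature world with known ground truth: spatially autocorrelated
# environment layers, a species pool with Gaussian niches, niche-driven
# community composition, clustered survey plots, effort-biased opportunistic
# occurrences and an incomplete trait-measurement database.

# Gaussian-kernel smoothing of white noise yields a stationary random field
# whose correlogram is Gaussian with scale sigma*sqrt(2). The constant below
# maps a requested spherical-model range to the kernel sd so that the range
# recovered by fitSpherical() from the realized field matches the request.
.RANGE_TO_SIGMA <- 0.22

.smoothKernelMatrix <- function(n, sigmaCells) {
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigmaCells^2))
  sweep(w, 1, rowSums(w), "/")
}

#' Generate spatially autocorrelated environment layers
#'
#' Each layer is an independent realization of a stationary random field built
#' by Gaussian-kernel smoothing of white noise, rescaled to the requested
#' marginal standard deviation around a base level. The kernel bandwidth is
#' calibrated so that a spherical semivariogram fitted to the realized field
#' recovers approximately \code{autocorrRangeKm}.
#'
#' @param grid a [GridSpec-class].
#' @param layerNames character vector of layer names (non-empty).
#' @param autocorrRangeKm target spatial autocorrelation range (km, > 0).
#' @param noiseSd marginal standard deviation of each layer (0 gives a
#'   constant layer equal to \code{base}).
#' @param base base level, a single number or named vector per layer.
#' @param seed integer seed (required; output is bit-reproducible).
#' @return An [EnvironmentStack-class].
#' @examples
#' g <- gridSpec(0, 0, 1, 40, 40)
#' env <- generateEnvironment(g, c("temp", "precip"), autocorrRangeKm = 10,
#'                            seed = 1)
#' @export
generateEnvironment <- function(grid, layerNames, autocorrRangeKm,
                                noiseSd = 1, base = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (length(layerNames) == 0L) stop("layerNames must be non-empty", call. = FALSE)
  if (!is.numeric(autocorrRangeKm) || autocorrRangeKm <= 0) {
    stop("autocorrRangeKm must be > 0", call. = FALSE)
  }
  baseVec <- if (length(base) == 1L) {
    setNames(rep(as.numeric(base), length(layerNames)), layerNames)
  } else {
    if (!all(layerNames %in% names(base))) {
      stop("base must be a single number or named per layer", call. = FALSE)
    }
    base[layerNames]
  }
  sigmaCells <- .RANGE_TO_SIGMA * autocorrRangeKm / grid@cellEdge
  withr::with_seed(as.integer(seed), {
    wr <- .smoothKernelMatrix(grid@nRows, sigmaCells)
    wc <- .smoothKernelMatrix(grid@nCols, sigmaCells)
    layers <- lapply(layerNames, function(nm) {
      if (noiseSd == 0) {
        return(matrix(baseVec[[nm]], grid@nRows, grid@nCols))
      }
      z <- matrix(rnorm(grid@nRows * grid@nCols), grid@nRows, grid@nCols)
      f <- wr %*% z %*% t(wc)
      s <- sd(as.vector(f))
      if (s == 0) f[] <- 0 else f <- (f - mean(f)) / s
      baseVec[[nm]] + noiseSd * f
    })
    names(layers) <- layerNames
    environmentStack(grid, layers)
  })
}

.SYLLABLES <- c("ab", "al", "an", "ar", "be", "bo", "ca", "ce", "co", "da",
                "de", "do", "el", "er", "fa", "fi", "ga", "ge", "ha", "hi",
                "il", "is", "ka", "la", "lo", "ma", "me", "mi", "na", "ne",
                "no", "ol", "or", "pa", "pe", "po", "ra", "re", "ri", "sa",
                "se", "si", "ta", "te", "ti", "ul", "ur", "va", "ve", "vi")

.makeBinomials <- function(n) {
  # deterministic unique two-word latin-flavoured names
  out <- character(n)
  i <- 0L
  k <- 1L
  while (i < n) {
    a <- .SYLLABLES[((k - 1L) %% 50L) + 1L]
    b <- .SYLLABLES[(((k - 1L) %/% 50L) %% 50L) + 1L]
    c3 <- .SYLLABLES[(((k - 1L) %/% 2500L) %% 50L) + 1L]
    i <- i + 1L
    out[i] <- paste0(a, b, "us ", c3, b, "a")
    k <- k + 1L
  }
  out
}

.drawTrait <- function(spec, n, optima) {
  dist <- spec$dist %||% "lognormal"
  switch(dist,
    constant = rep(spec$value, n),
    normal = rnorm(n, spec$mean, spec$sd),
    lognormal = rlnorm(n, spec$meanlog %||% 0, spec$sdlog %||% 1),
    uniform = runif(n, spec$min, spec$max),
    optimumLinked = {
      # trait deterministically (plus optional noise) tied to the species'
      # niche optimum on one axis: makes the CWM surface a smooth function
      # of the environment, the structure the trait-environment models learn
      ax <- spec$axis
      if (is.null(ax) || !ax %in% colnames(optima)) {
        stop("optimumLinked trait needs an 'axis' present in the niche spec",
             call. = FALSE)
      }
      (spec$intercept %||% 0) + (spec$slope %||% 1) * optima[, ax] +
        rnorm(n, 0, spec$sd %||% 0)
    },
    stop("unknown trait distribution '", dist, "'", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a species pool with true traits and Gaussian niches
#'
#' @param nSpecies number of species (>= 2).
#' @param traitSpecs named list; each element describes one trait's
#'   distribution, e.g. \code{list(dist = "lognormal", meanlog = 0, sdlog = 1)},
#'   \code{list(dist = "normal", mean, sd)}, \code{list(dist = "constant",
#'   value)}, or \code{list(dist = "optimumLinked", axis, intercept, slope,
#'   sd)} which ties the trait to the species' niche optimum on one
#'   environmental axis.
#' @param nicheSpec list with \code{axes} (character, environment layer
#'   names), \code{optimumRange} (length-2 numeric) and \code{breadthRange}
#'   (length-2 positive numeric); optima and breadths are drawn uniformly.
#' @param seed integer seed.
#' @return A [SpeciesPool-class].
#' @export
generateSpeciesPool <- function(nSpecies, traitSpecs, nicheSpec, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (nSpecies < 2L) stop("nSpecies must be >= 2", call. = FALSE)
  if (anyDuplicated(names(traitSpecs))) {
    stop("duplicate trait names in traitSpecs", call. = FALSE)
  }
  axes <- nicheSpec$axes
  if (length(axes) == 0L) stop("nicheSpec$axes must be non-empty", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    optR <- nicheSpec$optimumRange %||% c(-2, 2)
    brR <- nicheSpec$breadthRange %||% c(0.5, 2)
    optima <- matrix(runif(nSpecies * length(axes), optR[1], optR[2]),
                     nSpecies, length(axes), dimnames = list(NULL, axes))
    breadths <- matrix(runif(nSpecies * length(axes), brR[1], brR[2]),
                       nSpecies, length(axes), dimnames = list(NULL, axes))
    traits <- vapply(names(traitSpecs),
                     function(nm) .drawTrait(traitSpecs[[nm]], nSpecies, optima),
                     numeric(nSpecies))
    traits <- matrix(traits, nrow = nSpecies,
                     dimnames = list(NULL, names(traitSpecs)))
    new("SpeciesPool",
        species = data.frame(speciesId = seq_len(nSpecies),
                             binomial = .makeBinomials(nSpecies),
                             stringsAsFactors = FALSE),
        traits = traits, optima = optima, breadths = breadths)
  })
}

# environment values per cell (cell-id order) for the given axes
.envMatrix <- function(env, axes) {
  vapply(axes, function(a) as.vector(t(getLayer(env, a))),
         numeric(nCells(env@grid)))
}

#' Simulate community composition from Gaussian niche responses
#'
#' Per-cell relative cover of species \code{s} is proportional to
#' \code{exp(-sum_a (env_a - optimum_sa)^2 / (2 * breadth_sa^2))},
#' renormalized to sum to one. Species whose response falls below
#' \code{absenceFloor} are absent; cells where every species is below the
#' floor (or where any niche axis is nodata) are empty.
#'
#' @param env an [EnvironmentStack-class] containing every niche axis.
#' @param pool a [SpeciesPool-class].
#' @param absenceFloor response threshold below which a species is absent.
#' @return A [CommunityField-class].
#' @export
simulateCommunities <- function(env, pool, absenceFloor = 1e-4) {
  axes <- colnames(pool@optima)
  missing_ax <- setdiff(axes, layerNames(env))
  if (length(missing_ax)) {
    stop("niche axes missing from environment: ",
         paste(missing_ax, collapse = ", "), call. = FALSE)
  }
  E <- .envMatrix(env, axes)                # nCells x nAxes
  n <- nrow(E)
  nsp <- nrow(pool@optima)
  resp <- matrix(0, n, nsp, dimnames = list(NULL, pool@species$binomial))
  for (s in seq_len(nsp)) {
    d2 <- sweep(E, 2, pool@optima[s, ], "-")^2
    d2 <- sweep(d2, 2, 2 * pool@breadths[s, ]^2, "/")
    resp[, s] <- exp(-rowSums(d2))
  }
  resp[is.na(resp)] <- 0                    # nodata cells -> empty
  resp[resp < absenceFloor] <- 0
  tot <- rowSums(resp)
  occ <- tot > 0
  resp[occ, ] <- resp[occ, , drop = FALSE] / tot[occ]
  new("CommunityField", grid = env@grid, cover = resp)
}

.pointToCell <- function(grid, x, y) {
  ci <- floor((x - grid@originX) / grid@cellEdge)
  ri <- floor((y - grid@originY) / grid@cellEdge)
  inx <- ci >= 0 & ci < grid@nCols & ri >= 0 & ri < grid@nRows
  cell <- ifelse(inx, ri * grid@nCols + ci + 1, NA_integer_)
  list(cell = as.integer(cell), col = as.integer(ci), row = as.integer(ri),
       inside = inx)
}

#' Sample clustered vegetation survey plots
#'
#' Plot locations come from a clustered point process (uniform cluster
#' centres, Gaussian dispersion); each plot records the complete relative
#' cover of its cell's community (optionally truncated to the top-\code{k}
#' species with covers renormalized). Plots falling in empty cells are
#' redrawn.
#'
#' @param comm a [CommunityField-class].
#' @param nPlots number of plots (>= 1).
#' @param clusterSpec list with \code{nClusters} and \code{sdKm} (Gaussian
#'   dispersion of plots around their cluster centre, km). \code{centers}
#'   (data.frame x, y) may be supplied to fix cluster locations.
#' @param seed integer seed.
#' @param topK if non-NULL, keep only the \code{topK} highest-cover species
#'   per plot and renormalize.
#' @param uniqueCells if TRUE no two plots share a grid cell; it is an error
#'   to request more plots than occupied cells.
#' @return data.frame with columns \code{plotId}, \code{x}, \code{y},
#'   \code{binomial}, \code{cover}; covers sum to one within each plot.
#' @export
sampleSurveys <- function(comm, nPlots, clusterSpec = list(nClusters = 5,
                          sdKm = 2), seed, topK = NULL, uniqueCells = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (nPlots < 1L) stop("nPlots must be >= 1", call. = FALSE)
  g <- comm@grid
  occCells <- which(rowSums(comm@cover) > 0)
  if (length(occCells) == 0L) stop("community field is empty", call. = FALSE)
  if (uniqueCells && nPlots > length(occCells)) {
    stop("nPlots exceeds the number of occupied cells (uniqueCells = TRUE)",
         call. = FALSE)
  }
  xmax <- g@originX + g@nCols * g@cellEdge
  ymax <- g@originY + g@nRows * g@cellEdge
  withr::with_seed(as.integer(seed), {
    centers <- clusterSpec$centers
    if (is.null(centers)) {
      nc <- clusterSpec$nClusters %||% 5
      centers <- data.frame(x = runif(nc, g@originX, xmax),
                            y = runif(nc, g@originY, ymax))
    }
    sdKm <- clusterSpec$sdKm %||% 2
    px <- numeric(nPlots); py <- numeric(nPlots); pcell <- integer(nPlots)
    used <- integer(0)
    accepted <- 0L
    tries <- 0L
    while (accepted < nPlots) {
      tries <- tries + 1L
      if (tries > 10000L * nPlots) {
        stop("could not place survey plots in occupied cells (sampling error)",
             call. = FALSE)
      }
      ctr <- centers[sample.int(nrow(centers), 1L), ]
      x <- rnorm(1, ctr$x, sdKm); y <- rnorm(1, ctr$y, sdKm)
      pc <- .pointToCell(g, x, y)
      if (!pc$inside || !(pc$cell %in% occCells)) next
      if (uniqueCells && pc$cell %in% used) next
      accepted <- accepted + 1L
      px[accepted] <- x; py[accepted] <- y; pcell[accepted] <- pc$cell
      used <- c(used, pc$cell)
    }
    rows <- lapply(seq_len(nPlots), function(i) {
      cov <- comm@cover[pcell[i], ]
      sp <- which(cov > 0)
      if (!is.null(topK) && length(sp) > topK) {
        sp <- sp[order(cov[sp], decreasing = TRUE)[seq_len(topK)]]
      }
      w <- cov[sp] / sum(cov[sp])
      data.frame(plotId = sprintf("plot_%05d", i), x = px[i], y = py[i],
                 binomial = names(cov)[sp], cover = as.numeric(w),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Sample opportunistic occurrence records
#'
#' Record locations are drawn proportionally to an effort surface (uniform by
#' default) over occupied cells; the species at each location is drawn
#' proportionally to local relative cover times per-species detectability.
#'
#' @param comm a [CommunityField-class].
#' @param nOcc number of occurrence records.
#' @param effort \code{nRows x nCols} non-negative effort matrix aligned to
#'   the grid, or NULL for uniform effort.
#' @param detectability named per-species detection probability in [0, 1]
#'   (default 1 for all species).
#' @param seed integer seed.
#' @return data.frame with columns \code{recordId}, \code{x}, \code{y},
#'   \code{binomial}.
#' @export
sampleOccurrences <- function(comm, nOcc, effort = NULL, detectability = NULL,
                              seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  g <- comm@grid
  if (is.null(effort)) {
    effort <- matrix(1, g@nRows, g@nCols)
  }
  if (!all(dim(effort) == c(g@nRows, g@nCols))) {
    stop("effort surface must be aligned to the community grid", call. = FALSE)
  }
  if (any(effort < 0, na.rm = TRUE)) stop("effort must be >= 0", call. = FALSE)
  sp <- colnames(comm@cover)
  det <- setNames(rep(1, length(sp)), sp)
  if (!is.null(detectability)) {
    if (any(detectability < 0 | detectability > 1)) {
      stop("detectability must lie in [0, 1]", call. = FALSE)
    }
    det[names(detectability)] <- detectability
  }
  # effective per-cell sampling weight: effort x total detectable cover
  detCover <- comm@cover %*% det              # nCells x 1
  effVec <- as.vector(t(effort))
  effVec[is.na(effVec)] <- 0
  w <- effVec * as.numeric(detCover)
  if (sum(w) <= 0) {
    stop("all-zero effective effort: no cell can produce records", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    cells <- sample.int(length(w), nOcc, replace = TRUE, prob = w)
    ri <- (cells - 1L) %/% g@nCols
    ci <- (cells - 1L) %% g@nCols
    x <- g@originX + (ci + runif(nOcc)) * g@cellEdge
    y <- g@originY + (ri + runif(nOcc)) * g@cellEdge
    species <- character(nOcc)
    for (cell in unique(cells)) {
      idx <- which(cells == cell)
      p <- comm@cover[cell, ] * det
      species[idx] <- sample(sp, length(idx), replace = TRUE, prob = p)
    }
    data.frame(recordId = sprintf("occ_%07d", seq_len(nOcc)),
               x = x, y = y, binomial = species, stringsAsFactors = FALSE)
  })
}

#' Generate an incomplete trait-measurement database
#'
#' A fixed fraction of pool species receives noisy measurements centred on
#' their true trait values; the remainder has no records (the coverage gap of
#' real trait databases). Optionally a fraction of emitted names carries
#' authority-suffix noise ("Genus species L.") and capitalization.
#'
#' @param pool a [SpeciesPool-class].
#' @param coverageFraction fraction of species with any measurements (0, 1].
#' @param intraspecificCv coefficient of variation of measurement noise
#'   around the true value (>= 0).
#' @param nMeasPerSpecies measurements per covered species per trait.
#' @param authorityNoise fraction of emitted names decorated with an
#'   authority suffix and capitalization.
#' @param seed integer seed.
#' @return data.frame with columns \code{species}, \code{trait}, \code{value}.
#' @export
subsetTraitDB <- function(pool, coverageFraction = 1, intraspecificCv = 0,
                          nMeasPerSpecies = 1, authorityNoise = 0, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (coverageFraction <= 0 || coverageFraction > 1) {
    stop("coverageFraction must lie in (0, 1]", call. = FALSE)
  }
  if (intraspecificCv < 0) stop("intraspecificCv must be >= 0", call. = FALSE)
  n <- nrow(pool@species)
  nCov <- round(coverageFraction * n)
  withr::with_seed(as.integer(seed), {
    covered <- sort(sample.int(n, nCov))
    rows <- list()
    for (tr in colnames(pool@traits)) {
      truth <- pool@traits[covered, tr]
      m <- nMeasPerSpecies
      vals <- rep(truth, each = m) *
        (1 + rnorm(length(truth) * m, 0, intraspecificCv))
      rows[[tr]] <- data.frame(
        species = rep(pool@species$binomial[covered], each = m),
        trait = tr, value = vals, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (authorityNoise > 0) {
      deco <- runif(nrow(out)) < authorityNoise
      nm <- out$species[deco]
      nm <- paste0(toupper(substring(nm, 1, 1)), substring(nm, 2), " L.")
      out$species[deco] <- nm
    }
    out
  })
}

#' True community-weighted mean trait surface
#'
#' The recovery-test oracle: per occupied cell, the cover-weighted mean of
#' true species trait values (covers already sum to one). Empty cells are NA.
#'
#' @param comm a [CommunityField-class].
#' @param pool the [SpeciesPool-class] that generated it.
#' @param traitName trait column in the pool.
#' @return \code{nRows x nCols} numeric matrix.
#' @export
trueCWMSurface <- function(comm, pool, traitName) {
  if (!traitName %in% colnames(pool@traits)) {
    stop("trait '", traitName, "' not in pool", call. = FALSE)
  }
  v <- as.numeric(comm@cover %*% pool@traits[, traitName])
  v[rowSums(comm@cover) == 0] <- NA_real_
  matrix(v, nrow = comm@grid@nRows, byrow = TRUE)
}

#' Categorical strata from an environment layer
#'
#' Bins one layer into quantile classes, standing in for biome categories in
#' per-stratum metric breakdowns.
#'
#' @param env an [EnvironmentStack-class].
#' @param name layer to bin.
#' @param nStrata number of quantile classes.
#' @return integer matrix of stratum ids (NA where the layer is nodata).
#' @export
strataFromLayer <- function(env, name, nStrata = 4) {
  m <- getLayer(env, name)
  qs <- quantile(m, probs = seq(0, 1, length.out = nStrata + 1), na.rm = TRUE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  matrix(as.integer(cut(m, breaks = qs, labels = FALSE)),
         nrow(m), ncol(m))
}
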