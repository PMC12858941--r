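# End-to-end orchestration: simulate -> match -> grid -> folds -> fit ->
# predict -> uncertainty -> evaluate, with provenance metadata on disk.

#' Default pipeline configuration
#'
#' Desk-scale defaults for a full synthetic-world run. Every entry can be
#' overridden by passing a named list to [runPipeline()]; unknown entries
#' are rejected.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    world = list(
      nCols = 60, nRows = 60, cellEdgeKm = 1,
      envLayers = c("env1", "env2", "env3"),
      autocorrRangeKm = 12, envSd = 1,
      nSpecies = 40,
      traitSpecs = list(
        sla = list(dist = "optimumLinked", axis = "env1", intercept = 15,
                   slope = 6, sd = 1),
        height = list(dist = "lognormal", meanlog = 0.5, sdlog = 0.6)),
      nicheSpec = list(axes = c("env1", "env2", "env3"),
                       optimumRange = c(-2, 2), breadthRange = c(0.8, 2)),
      nPlots = 600,
      clusterSpec = list(nClusters = 12, sdKm = 6),
      nOcc = 20000, effort = NULL, detectability = NULL,
      coverageFraction = 0.9, intraspecificCv = 0.1, nMeasPerSpecies = 5),
    traits = c("sla", "height"),
    resolutions = c(1, 3),
    subsets = c("SCI", "CIT", "COMB"),
    minOcc = 10, maxOcc = 500, minPredictorFrac = 0.6,
    folds = list(K = 5, nSim = 100),
    model = list(nrounds = 150, eta = 0.1, maxDepth = 5, subsample = 0.9,
                 colsample = 0.9, minChildWeight = 1, prune = FALSE,
                 pruneMaxIter = 3, pruneRepeats = 3),
    imputeStrategy = "median",
    writeMaps = TRUE)
}

.REPLACE_WHOLESALE <- c("traitSpecs", "nicheSpec", "clusterSpec", "effort",
                        "detectability", "traits", "resolutions", "subsets",
                        "envLayers")

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base)) stop("unknown config entry '", nm, "'",
                                   call. = FALSE)
    if (!nm %in% .REPLACE_WHOLESALE && is.list(base[[nm]]) &&
        is.list(override[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper running the generator chain of the synthetic-world
#' module under one configuration: environment, species pool, communities,
#' clustered surveys, occurrence records and the incomplete trait database.
#'
#' @param cfg the \code{world} sub-list of [pipelineConfig()].
#' @param seed integer seed.
#' @return list with \code{grid}, \code{env}, \code{pool}, \code{comm},
#'   \code{surveys}, \code{occurrences}, \code{traitDB}, \code{strata}.
#' @export
simulateWorld <- function(cfg, seed) {
  g <- gridSpec(0, 0, cfg$cellEdgeKm, cfg$nCols, cfg$nRows)
  env <- generateEnvironment(g, cfg$envLayers, cfg$autocorrRangeKm,
                             noiseSd = cfg$envSd %||% 1, seed = seed)
  pool <- generateSpeciesPool(cfg$nSpecies, cfg$traitSpecs, cfg$nicheSpec,
                              seed = seed + 1L)
  comm <- simulateCommunities(env, pool)
  surveys <- sampleSurveys(comm, cfg$nPlots, cfg$clusterSpec, seed = seed + 2L)
  occ <- sampleOccurrences(comm, cfg$nOcc, effort = cfg$effort,
                           detectability = cfg$detectability,
                           seed = seed + 3L)
  db <- subsetTraitDB(pool, cfg$coverageFraction, cfg$intraspecificCv,
                      cfg$nMeasPerSpecies, seed = seed + 4L)
  list(grid = g, env = env, pool = pool, comm = comm, surveys = surveys,
       occurrences = occ, traitDB = db,
       strata = strataFromLayer(env, cfg$envLayers[1]))
}

.tableForSubset <- function(subset, cwmGrid, fwmGrid, env, strata,
                            minPredictorFrac, transform = NULL) {
  labelGrid <- switch(subset,
    SCI = cwmGrid,
    CIT = fwmGrid,
    COMB = mergeComb(cwmGrid, fwmGrid),
    stop("unknown subset '", subset, "'", call. = FALSE))
  buildTrainingTable(labelGrid, env, transform = transform,
                     minPredictorFrac = minPredictorFrac, strata = strata)
}

#' Run the full trait-mapping pipeline on a synthetic world
#'
#' Executes simulate, match, grid, folds, fit, predict, uncertainty and
#' evaluate for every planned (trait, resolution, subset) task, writing CSV
#' tables, JSON metrics/metadata and quantized map bundles under
#' \code{outDir}. Reruns with the same configuration and seed produce
#' identical metrics. Existing non-empty output directories are refused
#' unless \code{overwrite = TRUE}.
#'
#' @param config a [pipelineConfig()] list, a partial override list, or a
#'   path to a YAML file with the same structure.
#' @param outDir output directory (NULL runs in memory only).
#' @param overwrite allow writing into a non-empty \code{outDir}.
#' @return invisibly, a list with the world, per-task results and the
#'   metrics table.
#' @export
runPipeline <- function(config = list(), outDir = NULL, overwrite = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(pipelineConfig(), config)
  seed <- cfg$seed
  if (!is.null(outDir)) {
    if (dir.exists(outDir) && length(list.files(outDir)) > 0 && !overwrite) {
      stop("output directory is not empty (use overwrite = TRUE): ", outDir,
           call. = FALSE)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  world <- simulateWorld(cfg$world, seed)
  if (!is.null(outDir)) {
    write.csv(world$surveys, file.path(outDir, "surveys.csv"),
              row.names = FALSE)
    write.csv(world$occurrences, file.path(outDir, "occurrences.csv"),
              row.names = FALSE)
    write.csv(world$traitDB, file.path(outDir, "trait_measurements.csv"),
              row.names = FALSE)
  }
  means <- speciesMeans(world$traitDB)
  tasks <- planModelTasks(cfg$traits, cfg$resolutions, cfg$subsets)
  message(nrow(tasks), " model task(s) planned")
  mcfg <- do.call(modelConfig, c(cfg$model, list(seed = seed)))
  results <- list()
  metricsRows <- list()
  for (trait in cfg$traits) {
    cwm <- plotCWM(world$surveys, means, trait)
    tagged <- tagOccurrences(world$occurrences, means, trait)
    if (!is.null(outDir)) {
      jsonlite::write_json(
        matchReport(world$surveys, world$occurrences, means, trait),
        file.path(outDir, paste0("match_report_", trait, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    # autocorrelation range from survey CWMs at the finest resolution
    vg <- empiricalVariogram(cwm, cwm$cwm, seed = seed)
    sph <- fitSpherical(vg)
    for (res in cfg$resolutions) {
      g <- gridSpec(world$grid@originX, world$grid@originY, res,
                    ceiling(world$grid@nCols * world$grid@cellEdge / res),
                    ceiling(world$grid@nRows * world$grid@cellEdge / res))
      envR <- if (res == world$grid@cellEdge) world$env else
        aggregatePredictors(world$env, g)
      strataR <- if (res == world$grid@cellEdge) world$strata else
        round(getLayer(aggregatePredictors(
          environmentStack(world$grid, list(s = world$strata + 0)), g), "s"))
      sub <- subsampleOccurrences(tagged, g, cfg$minOcc, cfg$maxOcc,
                                  seed = seed + 10L)
      cwmGrid <- gridTraitValues(cwm, g, "cwm_mean", traitName = trait)
      fwmGrid <- gridTraitValues(sub, g, "fwm", traitName = trait)
      # the label transform is fitted once, on the survey CWM labels, and
      # reused for every subset so all validation happens on one scale
      sciTab <- .tableForSubset("SCI", cwmGrid, fwmGrid, envR, strataR,
                                cfg$minPredictorFrac)
      transform <- attr(sciTab, "transform")
      for (subset in cfg$subsets) {
        tab <- if (subset == "SCI") sciTab else
          .tableForSubset(subset, cwmGrid, fwmGrid, envR, strataR,
                          cfg$minPredictorFrac, transform = transform)
        folds <- buildFolds(tab[, c("x", "y")], tab$label, sph$range,
                            K = cfg$folds$K, nSim = cfg$folds$nSim,
                            seed = seed + 20L)
        validation <- NULL
        if (subset == "CIT") {
          vf <- assignHexFold(folds, sciTab)
          keep <- which(!is.na(vf))
          validation <- list(table = sciTab[keep, , drop = FALSE],
                             fold = vf[keep])
        }
        run <- cvRun(tab, folds, mcfg, env = envR, validation = validation)
        met <- computeMetrics(run$pooled$observed, run$pooled$predicted,
                              run$pooled$stratum)
        unc <- NULL
        if (subset != "CIT" && length(run$mapStack) >= 2) {
          unc <- uncertaintyProduct(run, tab, folds, envR,
                                    cfg$imputeStrategy)
        }
        key <- sprintf("%s_res%g_%s", trait, res, subset)
        results[[key]] <- list(table = tab, folds = folds, run = run,
                               metrics = met, uncertainty = unc,
                               range = sph$range)
        metricsRows[[key]] <- data.frame(
          trait = trait, resolution = res, subset = subset,
          n = met$n, r = met$r, nrmse = met$nrmse, r2 = met$r2,
          rangeKm = sph$range,
          pctInsideAOA = if (is.null(unc)) NA_real_ else unc@pctInsideAOA,
          meanCOV = if (is.null(unc)) NA_real_ else
            mean(unc@cov, na.rm = TRUE),
          stringsAsFactors = FALSE)
        if (!is.null(outDir) && isTRUE(cfg$writeMaps) && !is.null(unc)) {
          bundle <- traitMapBundle(
            g, run$finalMap, unc@cov, unc@aoa,
            metadata = list(trait = trait, resolution = res,
                            subset = subset, seed = seed,
                            diThreshold = unc@diThreshold,
                            lambda = attr(tab, "transform")$lambda))
          writeTraitRaster(bundle, file.path(outDir, key),
                           overwrite = overwrite)
        }
      }
    }
  }
  metrics <- do.call(rbind, metricsRows)
  rownames(metrics) <- NULL
  if (!is.null(outDir)) {
    write.csv(metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)
  }
  invisible(list(world = world, results = results, metrics = metrics,
                 tasks = tasks, config = cfg))
}
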