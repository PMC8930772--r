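#' Build a pipeline run configuration
#'
#' A `RunConfig` collects everything one reproducible run needs: the master
#' seed (fanned out to per-stage, per-scene seeds), the synthetic design,
#' the network and training settings, the segmentation mode, the counting
#' sweep and the statistics plan. `segment$mode = "oracle"` replaces the
#' trained network with idealised ground-truth prediction maps, which is
#' the configuration used for validating the measurement stages in
#' isolation from training.
#'
#' @param masterSeed integer master seed.
#' @param archetypes list of [StrainArchetype-class] objects.
#' @param design list: `nExperiments`, `fieldsPerStrain`.
#' @param scenes list of [generateScene()] arguments (e.g. `nCells`,
#'   `imageShape`, `cellRadiusRange`, `borderFraction`).
#' @param pixelSizeUm calibration.
#' @param train list: `enabled`, `depth`, `baseChannels`, plus
#'   [trainConfig()] arguments.
#' @param segment list: `mode` ("network" or "oracle"), `minAreaPx`,
#'   `seedThreshold`, `membershipThreshold`, `oracleBandwidth`.
#' @param sweep list of [thresholdSweepSpec()] arguments plus
#'   `supersizedThreshold`, `supersizedAreaUm2`, `connectivity`.
#' @param stats list: `metric`, `pairs` (preselected strain pairs,
#'   mandatory for the stats stage), `alpha`, `method`.
#' @return nested list of class `RunConfig`.
#' @export
runConfig <- function(masterSeed = 1L,
                      archetypes = list(wtArchetype(), nullArchetype()),
                      design = list(nExperiments = 3L, fieldsPerStrain = 3L),
                      scenes = list(nCells = 64L,
                                    imageShape = c(448L, 448L),
                                    cellRadiusRange = c(11, 16),
                                    borderFraction = 0.1),
                      pixelSizeUm = 0.065,
                      train = list(enabled = TRUE, depth = 3L,
                                   baseChannels = 16L, cropSize = 128L,
                                   steps = 500L, batchSize = 4L),
                      segment = list(mode = "network", minAreaPx = 300L,
                                     seedThreshold = 0.5,
                                     membershipThreshold = 0.5,
                                     oracleBandwidth = 0.02),
                      stats = list(metric = "mean_ld_per_cell",
                                   pairs = NULL, alpha = 0.05,
                                   method = "sidak"),
                      sweep = list()) {
  structure(list(masterSeed = as.integer(masterSeed),
                 archetypes = archetypes, design = design, scenes = scenes,
                 pixelSizeUm = pixelSizeUm, train = train,
                 segment = segment, stats = stats, sweep = sweep),
            class = "RunConfig")
}

#' A small demonstration configuration
#'
#' Two archetypes, two experiments, two fields of 64 cells, a tiny network:
#' a complete end-to-end run that finishes in minutes on one CPU.
#'
#' @param masterSeed master seed.
#' @return a `RunConfig`.
#' @export
demoRunConfig <- function(masterSeed = 1L) {
  runConfig(
    masterSeed = masterSeed,
    design = list(nExperiments = 2L, fieldsPerStrain = 2L),
    scenes = list(nCells = 64L, imageShape = c(448L, 448L),
                  cellRadiusRange = c(11, 16), borderFraction = 0.08),
    train = list(enabled = TRUE, depth = 2L, baseChannels = 8L,
                 cropSize = 128L, steps = 60L, batchSize = 2L),
    stats = list(metric = "mean_ld_per_cell",
                 pairs = list(c("wt", "seipin-null")), alpha = 0.05,
                 method = "sidak"))
}

configHash <- function(x) {
  json <- jsonlite::serializeJSON(x)
  sprintf("%08x", crc32(charToRaw(as.character(json))))
}

sceneDirName <- function(scene) {
  sprintf("%s_%s_%s", scene@strainTag, scene@experimentId, scene@fieldId)
}

logLine <- function(logPath, stage, msg, ...) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, message = sprintf(msg, ...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = logPath, append = TRUE, sep = "")
  message("[", stage, "] ", entry$message)
}

stageMarker <- function(outDir, stage) {
  file.path(outDir, sprintf(".stage-%s.json", stage))
}

stageDone <- function(outDir, stage, hash) {
  mk <- stageMarker(outDir, stage)
  if (!file.exists(mk)) return(FALSE)
  info <- jsonlite::read_json(mk, simplifyVector = TRUE)
  if (!identical(info$hash, hash)) return(FALSE)
  files <- names(info$md5)
  if (is.null(files)) return(TRUE)
  ok <- file.exists(file.path(outDir, files))
  if (!all(ok)) return(FALSE)
  cur <- unname(tools::md5sum(file.path(outDir, files)))
  identical(cur, unname(unlist(info$md5)))
}

markStage <- function(outDir, stage, hash, files) {
  rel <- sub(paste0("^", outDir, "/?"), "", files)
  md5 <- as.list(unname(tools::md5sum(files)))
  names(md5) <- rel
  jsonlite::write_json(list(hash = hash, md5 = md5),
                       stageMarker(outDir, stage), auto_unbox = TRUE)
}

#' Run the full pipeline: simulate, train, segment, quantify, stats
#'
#' Executes the stages in order into `outDir`, writing per-stage outputs
#' (scene TIFFs, checkpoint and training log, ROI archives, `cells.csv`,
#' `fields.csv`, `experiment_table.csv`, `anova.csv`, `pairwise.csv`), a
#' JSON-lines log and a manifest with file hashes. Completed stages whose
#' configuration and outputs still hash-match are skipped unless
#' `force = TRUE`, so a pipeline can resume after interruption. A failing
#' stage halts the run with the stage named; earlier outputs are kept.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param force re-run stages even when up to date.
#' @return the run manifest (named list), invisibly.
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline.log.jsonl")
  hash <- configHash(config)
  calib <- calibration(config$pixelSizeUm)
  manifest <- list(configHash = hash, stages = list())
  runStage <- function(stage, fun) {
    if (!force && stageDone(outDir, stage, hash)) {
      logLine(logPath, stage, "up to date, skipped")
      info <- jsonlite::read_json(stageMarker(outDir, stage),
                                  simplifyVector = TRUE)
      manifest$stages[[stage]] <<- c(info, status = "skipped")
      return(invisible(NULL))
    }
    files <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    markStage(outDir, stage, hash, files)
    manifest$stages[[stage]] <<- list(
      hash = hash, files = sub(paste0("^", outDir, "/?"), "", files),
      status = "done")
    invisible(NULL)
  }

  scenesDir <- file.path(outDir, "scenes")
  scenes <- NULL
  loadScenes <- function() {
    if (is.null(scenes)) {
      dirs <- sort(list.dirs(scenesDir, recursive = FALSE))
      scenes <<- lapply(dirs, readScene)
    }
    scenes
  }

  runStage("simulate", function() {
    args <- c(list(archetypes = config$archetypes,
                   nExperiments = config$design$nExperiments,
                   fieldsPerStrain = config$design$fieldsPerStrain,
                   seed = deriveSeed(config$masterSeed, "simulate"),
                   calib = calib),
              config$scenes)
    sc <- do.call(generateExperiment, args)
    scenes <<- sc
    paths <- vapply(sc, function(s) {
      d <- file.path(scenesDir, sceneDirName(s))
      writeScene(s, d)
      d
    }, character(1))
    logLine(logPath, "simulate", "generated %d scenes (%d cells each)",
            length(sc), max(vapply(sc, function(s) max(s@labelImage), 0)))
    list.files(paths, full.names = TRUE)
  })

  ckptPath <- file.path(outDir, "checkpoint.rds")
  doTrain <- isTRUE(config$train$enabled) &&
    identical(config$segment$mode, "network")
  if (doTrain) {
    runStage("train", function() {
      sc <- loadScenes()
      spec <- networkSpec(depth = config$train$depth %||% 3L,
                          baseChannels = config$train$baseChannels %||% 16L)
      tcArgs <- config$train[setdiff(names(config$train),
                                     c("enabled", "depth", "baseChannels"))]
      tcArgs$seed <- deriveSeed(config$masterSeed, "train")
      tc <- do.call(trainConfig, tcArgs)
      net <- trainNetwork(spec, sc, tc)
      writeCheckpoint(net, ckptPath)
      logCsv <- file.path(outDir, "training_log.csv")
      writeTrainLog(net, logCsv)
      logLine(logPath, "train",
              "trained %d steps; best validation loss %.4f at step %d",
              tc$steps, net$bestValLoss, net$bestStep)
      c(ckptPath, logCsv)
    })
  }

  segDir <- file.path(outDir, "segmentation")
  runStage("segment", function() {
    sc <- loadScenes()
    net <- if (doTrain) readCheckpoint(ckptPath) else NULL
    files <- character(0)
    for (s in sc) {
      maps <- if (identical(config$segment$mode, "oracle")) {
        oraclePredictionMaps(s, config$segment$oracleBandwidth %||% 0.02)
      } else {
        predictMaps(net, s@brightfield)
      }
      raw <- clusterInstances(maps,
                              config$segment$seedThreshold %||% 0.5,
                              config$segment$membershipThreshold %||% 0.5)
      res <- postprocess(raw, dim(s@brightfield),
                         config$segment$minAreaPx %||% 300L)
      d <- file.path(segDir, sceneDirName(s))
      files <- c(files, exportRois(res, d))
      logLine(logPath, "segment", "%s: %d cells retained, %d removed",
              sceneDirName(s), length(res@instances), nrow(res@removed))
    }
    files
  })

  runStage("quantify", function() {
    sc <- loadScenes()
    sweepArgs <- config$sweep[intersect(names(config$sweep),
                                        c("start", "stop", "step", "upper"))]
    spec <- do.call(thresholdSweepSpec, sweepArgs)
    allCells <- list(); allFields <- list()
    for (s in sc) {
      d <- file.path(segDir, sceneDirName(s))
      lab <- readTiff16(file.path(d, "labels.tif"))
      ids <- setdiff(sort(unique(as.integer(lab))), 0L)
      regions <- lapply(ids, function(k) which(lab == k))
      names(regions) <- as.character(ids)
      fs <- summarizeField(
        s, regions, spec, calib,
        connectivity = config$sweep$connectivity %||% 8L,
        supersizedThreshold = config$sweep$supersizedThreshold %||% 10000,
        supersizedAreaUm2 = config$sweep$supersizedAreaUm2 %||% 0.5)
      fs$cells <- cbind(strain = s@strainTag,
                        experiment_id = s@experimentId,
                        field_id = s@fieldId, fs$cells)
      allCells[[length(allCells) + 1L]] <- fs$cells
      allFields[[length(allFields) + 1L]] <- fs$summary
      logLine(logPath, "quantify", "%s: %d cells, mean LD %.2f, %.1f%% supersized",
              sceneDirName(s), fs$summary$n_cells,
              fs$summary$mean_ld_per_cell, fs$summary$pct_cells_supersized)
    }
    cellsCsv <- file.path(outDir, "cells.csv")
    fieldsCsv <- file.path(outDir, "fields.csv")
    utils::write.csv(do.call(rbind, allCells), cellsCsv, row.names = FALSE)
    utils::write.csv(do.call(rbind, allFields), fieldsCsv,
                     row.names = FALSE)
    c(cellsCsv, fieldsCsv)
  })

  runStage("stats", function() {
    if (is.null(config$stats$pairs)) {
      stop("no preselected strain pairs configured (stats$pairs)")
    }
    fields <- utils::read.csv(file.path(outDir, "fields.csv"))
    tab <- buildExperimentTable(fields, config$stats$metric)
    an <- linkedAnova(tab)
    pw <- holmSidak(config$stats$pairs, tab, an,
                    alpha = config$stats$alpha %||% 0.05,
                    method = config$stats$method %||% "sidak")
    tabCsv <- file.path(outDir, "experiment_table.csv")
    utils::write.csv(tab, tabCsv, row.names = FALSE)
    paths <- writeStatsReport(pw, outDir, an)
    logLine(logPath, "stats", "ANOVA F(%d, %d) = %.3g, p = %.3g",
            an$dfStrain, an$dfResidual, an$F, an$pValue)
    c(tabCsv, paths)
  })

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a run configuration as YAML
#'
#' Archetypes are stored as plain parameter maps; everything else
#' round-trips as-is.
#'
#' @param config a [runConfig()].
#' @param path YAML file path.
#' @return `readRunConfig` returns a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  x$archetypes <- lapply(config$archetypes, function(a) list(
    name = a@name, droplets_per_cell_mean = a@dropletsPerCellMean,
    radius_log_mean = a@radiusLogMean, radius_log_sd = a@radiusLogSd,
    intensity_range = a@intensityRange,
    clustering_prob = a@clusteringProb))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$archetypes <- lapply(x$archetypes, function(a) strainArchetype(
    a$name, a$droplets_per_cell_mean, a$radius_log_mean, a$radius_log_sd,
    unlist(a$intensity_range), a$clustering_prob))
  x$masterSeed <- as.integer(x$masterSeed)
  structure(x, class = "RunConfig")
}

# ---- canonical fixture images ----

diskImage <- function(shape, centers, radii, intensities) {
  img <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(radii)) {
    px <- diskPixels(centers[[i]], radii[i], shape[1], shape[2])
    img[px] <- as.integer(intensities[i])
  }
  img
}

#' Canonical fixture images for the counting stage
#'
#' `fixtureThreeDisks()`: three disjoint uniform disks of intensity 25,000
#' (3 particles at every sweep threshold). `fixtureBridge()`: two disks of
#' intensity 25,000 joined by a one-pixel bridge of intensity 6,000 -- two
#' particles at thresholds of 8,000 and above, one at 6,000 and below.
#' `fixtureDisk()`: a single centred disk for the supersized-area
#' boundaries.
#'
#' @return an integer image matrix (zero background).
#' @examples
#' img <- fixtureBridge()
#' countParticles(img, seq_along(img), 10000)$count  # 2
#' countParticles(img, seq_along(img), 6000)$count   # 1
#' @export
fixtureThreeDisks <- function() {
  diskImage(c(40L, 40L), list(c(10, 10), c(10, 30), c(30, 20)),
            c(3, 3, 3), c(25000, 25000, 25000))
}

#' @rdname fixtureThreeDisks
#' @export
fixtureBridge <- function() {
  img <- diskImage(c(32L, 32L), list(c(16, 9), c(16, 25)), c(4, 4),
                   c(25000, 25000))
  bridge <- img[16, ] == 0 & seq_len(32) > 9 & seq_len(32) < 25
  img[16, bridge] <- 6000L
  img
}

#' @param radiusPx disk radius in pixels.
#' @param intensity uniform disk intensity in counts.
#' @param pad margin around the disk in pixels.
#' @rdname fixtureThreeDisks
#' @export
fixtureDisk <- function(radiusPx, intensity = 30000, pad = 4L) {
  n <- 2L * (as.integer(ceiling(radiusPx)) + pad) + 1L
  ctr <- (n + 1) / 2
  diskImage(c(n, n), list(c(ctr, ctr)), radiusPx, intensity)
}

#' Write the canonical fixture bundle
#'
#' Writes the fixture images used across the test-suite as 16-bit TIFFs
#' (`bridge.tif`, `three-disks.tif`, `disk-r25.tif`, `disk-r10.tif`,
#' `disk-r5.tif`, `disk-dim.tif`) plus one small saved scene with oracle
#' ground truth (`oracle-scene/`). All integer images, so the bundle is
#' identical across platforms.
#'
#' @param outDir output directory.
#' @return named character vector of paths, invisibly.
#' @export
makeFixtures <- function(outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    bridge = file.path(outDir, "bridge.tif"),
    threeDisks = file.path(outDir, "three-disks.tif"),
    diskR25 = file.path(outDir, "disk-r25.tif"),
    diskR10 = file.path(outDir, "disk-r10.tif"),
    diskR5 = file.path(outDir, "disk-r5.tif"),
    diskDim = file.path(outDir, "disk-dim.tif"))
  writeTiff16(fixtureBridge(), paths["bridge"])
  writeTiff16(fixtureThreeDisks(), paths["threeDisks"])
  writeTiff16(fixtureDisk(25, 30000), paths["diskR25"])
  writeTiff16(fixtureDisk(10, 30000), paths["diskR10"])
  writeTiff16(fixtureDisk(5, 30000), paths["diskR5"])
  writeTiff16(fixtureDisk(10, 9000), paths["diskDim"])
  sceneDir <- file.path(outDir, "oracle-scene")
  sc <- generateScene(wtArchetype(), nCells = 6L, imageShape = c(96L, 96L),
                      cellRadiusRange = c(9, 12), borderFraction = 0,
                      seed = 7L)
  writeScene(sc, sceneDir)
  invisible(c(paths, oracleScene = sceneDir))
}
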