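#' Pixel-size calibration
#'
#' Couples pixel coordinates to physical units. Only the pixel edge length is
#' needed: droplet areas in square micrometres are `n_px * pixelSizeUm^2`.
#' The default 0.065 um/px corresponds to a typical 100x objective with an
#' sCMOS camera. Intensities are 16-bit counts throughout (0-65535).
#'
#' @slot pixelSizeUm positive length of a pixel edge in micrometres.
#' @slot bitDepth intensity bit depth; fixed at 16 in this package.
#' @export
setClass("Calibration",
  representation(pixelSizeUm = "numeric", bitDepth = "integer"),
  prototype(pixelSizeUm = 0.065, bitDepth = 16L),
  validity = function(object) {
    if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0) {
      return("pixelSizeUm must be a single positive number")
    }
    if (object@bitDepth != 16L) return("only 16-bit images are supported")
    TRUE
  }
)

#' @param pixelSizeUm positive pixel edge length in micrometres.
#' @rdname Calibration-class
#' @return a `Calibration` object.
#' @examples
#' calibration(0.065)
#' @export
calibration <- function(pixelSizeUm = 0.065) {
  new("Calibration", pixelSizeUm = pixelSizeUm, bitDepth = 16L)
}

#' Strain archetype for the synthetic generator
#'
#' A generative description of one strain's lipid-droplet phenotype: how many
#' droplets a cell carries (Poisson), how large they are (log-normal radius in
#' micrometres), how bright their peaks are (uniform in a 16-bit count range)
#' and how strongly droplets cluster into tight groups.
#'
#' @slot name strain label.
#' @slot dropletsPerCellMean Poisson mean of droplets per cell.
#' @slot radiusLogMean,radiusLogSd log-normal parameters of droplet radius, um.
#' @slot intensityRange length-2 peak-intensity range in counts; must stay
#'   strictly above the lowest counting threshold (2,000) so every droplet is
#'   in principle countable.
#' @slot clusteringProb probability a droplet is placed tangent to an existing
#'   droplet of the same cell rather than independently.
#' @export
setClass("StrainArchetype",
  representation(name = "character", dropletsPerCellMean = "numeric",
                 radiusLogMean = "numeric", radiusLogSd = "numeric",
                 intensityRange = "numeric", clusteringProb = "numeric"),
  validity = function(object) {
    if (object@dropletsPerCellMean < 0) return("dropletsPerCellMean must be >= 0")
    if (object@radiusLogSd < 0) return("radiusLogSd must be >= 0")
    if (length(object@intensityRange) != 2 ||
        object@intensityRange[1] > object@intensityRange[2]) {
      return("intensityRange must be (low, high) with low <= high")
    }
    if (object@intensityRange[1] <= 2000 || object@intensityRange[2] > 65535) {
      return("intensityRange must lie within (2000, 65535]")
    }
    if (object@clusteringProb < 0 || object@clusteringProb > 1) {
      return("clusteringProb must be in [0, 1]")
    }
    TRUE
  }
)

#' @param name,dropletsPerCellMean,radiusLogMean,radiusLogSd,intensityRange,clusteringProb
#'   see the class slots.
#' @rdname StrainArchetype-class
#' @return a `StrainArchetype`.
#' @export
strainArchetype <- function(name, dropletsPerCellMean, radiusLogMean,
                            radiusLogSd, intensityRange,
                            clusteringProb = 0) {
  new("StrainArchetype", name = name,
      dropletsPerCellMean = dropletsPerCellMean,
      radiusLogMean = radiusLogMean, radiusLogSd = radiusLogSd,
      intensityRange = as.numeric(intensityRange),
      clusteringProb = clusteringProb)
}

#' Built-in strain archetypes
#'
#' `wtArchetype()` emulates a wild-type field: many small (median radius well
#' below 400 nm), relatively uniform droplets. `nullArchetype()` emulates a
#' seipin-null field: few droplets per cell, log-median radius above 400 nm
#' (the supersized regime) and a strong tendency to cluster.
#'
#' @return a `StrainArchetype`.
#' @examples
#' wtArchetype()
#' nullArchetype()
#' @export
wtArchetype <- function() {
  strainArchetype("wt", dropletsPerCellMean = 8,
                  radiusLogMean = log(0.15), radiusLogSd = 0.25,
                  intensityRange = c(8000, 30000), clusteringProb = 0.05)
}

#' @rdname wtArchetype
#' @export
nullArchetype <- function() {
  strainArchetype("seipin-null", dropletsPerCellMean = 2,
                  radiusLogMean = log(0.5), radiusLogSd = 0.35,
                  intensityRange = c(10000, 40000), clusteringProb = 0.6)
}

#' A synthetic microscope field with full ground truth
#'
#' One field pairs a brightfield channel (for segmentation) with a
#' fluorescence channel (BODIPY-like droplet stain, for quantification), the
#' ground-truth cell label image, the exact droplet table, calibration, and
#' the strain/experiment/field labels used by the statistics stage.
#'
#' @slot brightfield,fluorescence 16-bit integer matrices.
#' @slot labelImage integer matrix; 0 is background, k > 0 is cell k.
#' @slot droplets data.frame with columns `owner_cell`, `row`, `col`,
#'   `radius_px`, `peak`, `area_um2`.
#' @slot calibration a [Calibration-class] object.
#' @slot strainTag,experimentId,fieldId labels.
#' @slot seed the scene's own generation seed.
#' @export
setClass("Scene",
  representation(brightfield = "matrix", fluorescence = "matrix",
                 labelImage = "matrix", droplets = "data.frame",
                 calibration = "Calibration", strainTag = "character",
                 experimentId = "character", fieldId = "character",
                 seed = "integer"),
  validity = function(object) {
    dm <- dim(object@brightfield)
    if (!identical(dm, dim(object@fluorescence)) ||
        !identical(dm, dim(object@labelImage))) {
      return("brightfield, fluorescence and labelImage must share one shape")
    }
    if (any(object@brightfield < 0 | object@brightfield > 65535) ||
        any(object@fluorescence < 0 | object@fluorescence > 65535)) {
      return("intensities must lie in [0, 65535]")
    }
    ids <- sort(unique(object@labelImage[object@labelImage > 0]))
    if (length(ids) && !identical(as.integer(ids), seq_along(ids))) {
      return("cell labels must be 1..n without gaps")
    }
    if (nrow(object@droplets) &&
        !all(object@droplets$owner_cell %in% ids)) {
      return("droplet owner_cell ids must exist in labelImage")
    }
    TRUE
  }
)

#' Per-pixel network predictions for instance clustering
#'
#' The three outputs of the segmentation network: a seed score in `[0, 1]`
#' per pixel, a positive clustering bandwidth (sigma) per pixel, and a 2-D
#' offset per pixel. Adding the offset to the pixel's own coordinate
#' (normalised by the larger image dimension) gives the spatial embedding,
#' which is trained to be constant within a cell and distinct between cells.
#'
#' @slot seed matrix in `[0, 1]`.
#' @slot bandwidth matrix of positive sigmas (embedding units).
#' @slot offsetRow,offsetCol matrices of embedding offsets.
#' @export
setClass("PredictionMaps",
  representation(seed = "matrix", bandwidth = "matrix",
                 offsetRow = "matrix", offsetCol = "matrix"),
  validity = function(object) {
    dm <- dim(object@seed)
    if (!identical(dm, dim(object@bandwidth)) ||
        !identical(dm, dim(object@offsetRow)) ||
        !identical(dm, dim(object@offsetCol))) {
      return("all four maps must share one shape")
    }
    if (any(object@seed < 0 | object@seed > 1)) return("seed must lie in [0, 1]")
    if (any(object@bandwidth <= 0)) return("bandwidth must be positive")
    TRUE
  }
)

#' Segmented cell instances after filtering
#'
#' The output of [postprocess()]: retained instances (with raw pixel sets,
#' convex-hull polygons and hull-rasterised regions), the removed instances
#' with their reasons, a hull-rendered label image, and the parameters used.
#' Downstream droplet quantification measures inside the convex-hull regions,
#' mirroring an ImageJ ROI workflow.
#'
#' @slot instances list; each element has `id`, `pixels` (linear indices of
#'   the raw cluster), `areaPx`, `hull` (polygon vertices, row/col),
#'   `hullPixels`, `touchesBorder`, `seedPixel`, `seedScore`.
#' @slot removed data.frame with `id`, `reason` ("small" or "border"),
#'   `areaPx`.
#' @slot labelImage integer matrix rendered from the hulls (first id wins on
#'   the rare overlapping hull pixel).
#' @slot parameters list of thresholds and filter settings used.
#' @export
setClass("SegmentationResult",
  representation(instances = "list", removed = "data.frame",
                 labelImage = "matrix", parameters = "list"),
  validity = function(object) {
    p <- unlist(lapply(object@instances, `[[`, "pixels"))
    if (anyDuplicated(p)) return("instance pixel sets must be disjoint")
    minA <- object@parameters$minAreaPx
    if (!is.null(minA) && length(object@instances)) {
      a <- vapply(object@instances, `[[`, numeric(1), "areaPx")
      if (any(a < minA)) return("retained instance below the area threshold")
      tb <- vapply(object@instances, `[[`, logical(1), "touchesBorder")
      if (any(tb)) return("retained instance touches the image border")
    }
    TRUE
  }
)

setMethod("show", "Calibration", function(object) {
  cat("Calibration:", object@pixelSizeUm, "um/px,", object@bitDepth, "bit\n")
})

setMethod("show", "StrainArchetype", function(object) {
  cat(sprintf(
    "StrainArchetype '%s': %.2g droplets/cell, radius lognormal(%.3g, %.3g) um,\n  peaks %d-%d counts, clustering %.2g\n",
    object@name, object@dropletsPerCellMean, object@radiusLogMean,
    object@radiusLogSd, object@intensityRange[1], object@intensityRange[2],
    object@clusteringProb))
})

setMethod("show", "Scene", function(object) {
  cat(sprintf(
    "Scene %s/%s/%s: %d x %d px, %d cells, %d droplets (seed %d)\n",
    object@strainTag, object@experimentId, object@fieldId,
    nrow(object@brightfield), ncol(object@brightfield),
    max(object@labelImage), nrow(object@droplets), object@seed))
})

setMethod("show", "PredictionMaps", function(object) {
  cat(sprintf(
    "PredictionMaps %d x %d px: seed in [%.3f, %.3f], sigma in [%.4f, %.4f]\n",
    nrow(object@seed), ncol(object@seed), min(object@seed), max(object@seed),
    min(object@bandwidth), max(object@bandwidth)))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d instances retained, %d removed (%s)\n",
              length(object@instances), nrow(object@removed),
              if (nrow(object@removed)) {
                paste(names(table(object@removed$reason)),
                      table(object@removed$reason), collapse = ", ")
              } else "none"))
})
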