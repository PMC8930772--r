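#' Descending threshold-sweep specification
#'
#' The droplet-counting sweep: particles are counted at every lower
#' threshold from `start` down to `stop` in steps of `step` (the upper
#' threshold stays at the 16-bit maximum), and a cell's droplet number is the
#' maximum count over the sweep. The defaults are the canonical sweep
#' 20,000, 18,000, ..., 2,000.
#'
#' @param start,stop,step sweep bounds and decrement, counts.
#' @param upper upper threshold (maximal by default).
#' @return an object of class `ThresholdSweepSpec` with a `thresholds`
#'   component listing the descending sweep.
#' @examples
#' thresholdSweepSpec()$thresholds
#' @export
thresholdSweepSpec <- function(start = 20000, stop = 2000, step = 2000,
                               upper = 65535) {
  if (start < stop) stop("start must be >= stop")
  if (step <= 0 || (start - stop) %% step != 0) {
    stop("step must be positive and divide start - stop")
  }
  structure(list(start = start, stop = stop, step = step, upper = upper,
                 thresholds = seq(start, stop, by = -step)),
            class = "ThresholdSweepSpec")
}

#' Count thresholded particles inside one cell region
#'
#' Binarises the fluorescence channel at `pixel >= lowerThreshold` (and
#' `<= upper`), restricted to the cell region, and counts connected
#' components. Connectivity is 8 by default, matching the ImageJ "Analyze
#' Particles" convention the original routine ran under.
#'
#' @param fluor 16-bit fluorescence matrix.
#' @param region nonempty integer vector of linear pixel indices (the cell's
#'   ROI; typically a convex-hull region from [postprocess()]).
#' @param lowerThreshold lower intensity threshold in `(0, 65535]`.
#' @param upper upper threshold (default maximal).
#' @param connectivity 8 (default) or 4.
#' @param calib optional [Calibration-class]; adds particle areas in um^2.
#' @return list with `count`, `areasPx` and (given `calib`) `areasUm2`.
#' @export
countParticles <- function(fluor, region, lowerThreshold, upper = 65535,
                           connectivity = 8L, calib = NULL) {
  if (length(region) == 0) stop("cell region must be nonempty")
  if (lowerThreshold <= 0 || lowerThreshold > 65535) {
    stop("lowerThreshold must be in (0, 65535]")
  }
  H <- nrow(fluor)
  r <- pixRow(region, H); c <- pixCol(region, H)
  r0 <- min(r); c0 <- min(c)
  sub <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
  vals <- fluor[region]
  keep <- vals >= lowerThreshold & vals <= upper
  sub[cbind(r[keep] - r0 + 1L, c[keep] - c0 + 1L)] <- TRUE
  lab <- .labelComponents(sub, as.integer(connectivity))
  n <- max(lab)
  areasPx <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  out <- list(count = n, areasPx = areasPx)
  if (!is.null(calib)) out$areasUm2 <- areasPx * calib@pixelSizeUm^2
  out
}

#' Threshold-sweep droplet count and supersized scoring for one cell
#'
#' Runs [countParticles()] at every sweep threshold; the cell's droplet
#' number (`ldCount`) is the maximal count over the sweep. Supersized
#' scoring is a separate pass at the 10,000 lower threshold: particles with
#' area strictly greater than 0.5 um^2 are counted as supersized.
#'
#' @inheritParams countParticles
#' @param spec a [thresholdSweepSpec()].
#' @param calib a [Calibration-class] (needed for the area rule).
#' @param supersizedThreshold lower threshold of the supersized pass, counts.
#' @param supersizedAreaUm2 strict area cut in um^2.
#' @return list with `countsPerThreshold` (named by threshold), `ldCount`,
#'   `supersizedParticles`, `hasSupersized`.
#' @export
sweepCell <- function(fluor, region, spec = thresholdSweepSpec(),
                      calib = calibration(), connectivity = 8L,
                      supersizedThreshold = 10000,
                      supersizedAreaUm2 = 0.5) {
  counts <- vapply(spec$thresholds, function(thr)
    countParticles(fluor, region, thr, spec$upper, connectivity)$count,
    integer(1))
  names(counts) <- as.character(spec$thresholds)
  ss <- countParticles(fluor, region, supersizedThreshold, spec$upper,
                       connectivity, calib = calib)
  nSuper <- sum(ss$areasUm2 > supersizedAreaUm2)
  list(countsPerThreshold = counts, ldCount = max(counts, 0L),
       supersizedParticles = nSuper, hasSupersized = nSuper >= 1L)
}

#' Quantify every cell of a field and summarise it
#'
#' Applies [sweepCell()] to each cell region of a field and aggregates to
#' the field level: mean droplets per cell and the percentage of cells
#' containing at least one supersized particle.
#'
#' Regions can come from a [SegmentationResult-class] (hull regions, the
#' standard route), from a scene's ground-truth label image
#' (`segmentation = NULL`), or from an explicit named list of pixel-index
#' vectors.
#'
#' @param scene a [Scene-class], or a fluorescence matrix if `regions` is
#'   given explicitly.
#' @param segmentation a [SegmentationResult-class], an explicit list of
#'   regions, or `NULL` to quantify on the ground-truth labels.
#' @inheritParams sweepCell
#' @param strainTag,experimentId,fieldId labels; default to the scene's.
#' @return list with `summary` (one-row data.frame: labels, `n_cells`,
#'   `mean_ld_per_cell`, `pct_cells_supersized`) and `cells` (per-cell
#'   table: counts at each threshold, `ld_count`, `supersized_particles`,
#'   `has_supersized`).
#' @export
summarizeField <- function(scene, segmentation = NULL,
                           spec = thresholdSweepSpec(), calib = NULL,
                           connectivity = 8L,
                           supersizedThreshold = 10000,
                           supersizedAreaUm2 = 0.5,
                           strainTag = NULL, experimentId = NULL,
                           fieldId = NULL) {
  if (is(scene, "Scene")) {
    fluor <- scene@fluorescence
    if (is.null(calib)) calib <- scene@calibration
    if (is.null(strainTag)) strainTag <- scene@strainTag
    if (is.null(experimentId)) experimentId <- scene@experimentId
    if (is.null(fieldId)) fieldId <- scene@fieldId
  } else {
    fluor <- scene
    if (is.null(calib)) calib <- calibration()
    if (is.null(strainTag)) strainTag <- "strain"
    if (is.null(experimentId)) experimentId <- "E1"
    if (is.null(fieldId)) fieldId <- "F1"
  }
  regions <- regionList(segmentation, scene)
  if (length(regions) == 0) {
    stop(sprintf("field %s/%s/%s has no cells to quantify",
                 strainTag, experimentId, fieldId))
  }
  rows <- lapply(names(regions), function(id) {
    sw <- sweepCell(fluor, regions[[id]], spec, calib, connectivity,
                    supersizedThreshold, supersizedAreaUm2)
    cnt <- as.list(sw$countsPerThreshold)
    names(cnt) <- paste0("n_at_", names(sw$countsPerThreshold))
    data.frame(cell_id = id, cnt, ld_count = sw$ldCount,
               supersized_particles = sw$supersizedParticles,
               has_supersized = sw$hasSupersized,
               check.names = FALSE)
  })
  cells <- do.call(rbind, rows)
  summary <- data.frame(
    strain = strainTag, experiment_id = experimentId, field_id = fieldId,
    n_cells = nrow(cells),
    mean_ld_per_cell = mean(cells$ld_count),
    pct_cells_supersized = 100 * mean(cells$has_supersized))
  list(summary = summary, cells = cells)
}

# normalise the three region sources into a named list of pixel indices
regionList <- function(segmentation, scene) {
  if (is.null(segmentation)) {
    if (!is(scene, "Scene")) {
      stop("segmentation = NULL needs a Scene with ground-truth labels")
    }
    lab <- scene@labelImage
    ids <- seq_len(max(lab))
    regions <- lapply(ids, function(k) which(lab == k))
    names(regions) <- as.character(ids)
    regions[lengths(regions) > 0]
  } else if (is(segmentation, "SegmentationResult")) {
    regions <- lapply(segmentation@instances, `[[`, "hullPixels")
    names(regions) <- vapply(segmentation@instances, function(x)
      as.character(x$id), character(1))
    regions
  } else if (is.list(segmentation)) {
    if (is.null(names(segmentation))) {
      names(segmentation) <- as.character(seq_along(segmentation))
    }
    segmentation
  } else {
    stop("segmentation must be NULL, a SegmentationResult, or a list")
  }
}
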