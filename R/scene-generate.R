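#' Generate one synthetic microscope field with exact ground truth
#'
#' Places non-overlapping elliptical cells on a noisy brightfield-like
#' background (dark interior, bright rim), draws each cell's droplets from the
#' strain archetype (Poisson count, log-normal radius, uniform peak
#' intensity, optional clustering), renders the fluorescence channel as hard
#' disks softened by a small truncated Gaussian blur, and stores the ground
#' truth exactly. The fluorescence background (including read noise) is
#' capped strictly below the lowest counting threshold of 2,000, so
#' background alone can never register as a particle; droplet signal extends
#' at most `blurRadius` pixels past each disk.
#'
#' Droplets that cannot be placed inside their cell within the retry budget
#' are omitted, so the droplet table always describes exactly what was
#' rendered.
#'
#' @param archetype a [StrainArchetype-class].
#' @param nCells number of cells to place (> 0).
#' @param imageShape `c(rows, cols)`.
#' @param calib a [Calibration-class]; default 0.065 um/px.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param cellRadiusRange range of ellipse semi-axes in pixels.
#' @param borderFraction fraction of cells deliberately placed across the
#'   image border (to exercise the border filter downstream).
#' @param cellGap minimum Chebyshev gap in pixels between cell masks.
#' @param bfBackground,bfInterior,bfRim,bfNoiseSd brightfield appearance in
#'   counts: background level, cell interior level, rim level, Gaussian read
#'   noise sd.
#' @param fluorBackground,fluorNoiseSd fluorescence background level and
#'   noise sd; their sum is capped at 1,900 counts.
#' @param blurSigma,blurRadius droplet blur: sd and truncation radius (px).
#' @param minDropletGap minimum gap between non-clustered droplet disks, px.
#' @param retryBudget placement attempts per cell (and per droplet) before
#'   giving up.
#' @param strainTag,experimentId,fieldId labels carried into downstream
#'   tables; `strainTag` defaults to the archetype name.
#' @return a [Scene-class].
#' @examples
#' sc <- generateScene(wtArchetype(), nCells = 6, imageShape = c(96, 96),
#'                     cellRadiusRange = c(8, 11), seed = 1)
#' sc
#' @export
generateScene <- function(archetype, nCells = 200L,
                          imageShape = c(1024L, 1024L),
                          calib = calibration(), seed = 1L,
                          cellRadiusRange = c(18, 30),
                          borderFraction = 0.1, cellGap = 2L,
                          bfBackground = 30000, bfInterior = 22000,
                          bfRim = 45000, bfNoiseSd = 1500,
                          fluorBackground = 600, fluorNoiseSd = 150,
                          blurSigma = 0.6, blurRadius = 1L,
                          minDropletGap = 2, retryBudget = 200L,
                          strainTag = archetype@name,
                          experimentId = "E1", fieldId = "F1") {
  stopifnot(is(archetype, "StrainArchetype"))
  if (nCells <= 0) stop("nCells must be positive")
  H <- as.integer(imageShape[1]); W <- as.integer(imageShape[2])
  oldseed <- .Random.seed_save()
  on.exit(.Random.seed_restore(oldseed), add = TRUE)
  set.seed(as.integer(seed))

  lab <- matrix(0L, H, W)
  occ <- matrix(FALSE, H, W)   # cell masks dilated by cellGap
  cells <- list()
  for (k in seq_len(nCells)) {
    placed <- FALSE
    wantBorder <- stats::runif(1) < borderFraction
    for (try in seq_len(retryBudget)) {
      a <- stats::runif(1, cellRadiusRange[1], cellRadiusRange[2])
      b <- stats::runif(1, cellRadiusRange[1], cellRadiusRange[2])
      th <- stats::runif(1, 0, pi)
      rmax <- max(a, b)
      if (wantBorder) {
        edge <- sample.int(4L, 1L)
        u <- stats::runif(1)
        d <- stats::runif(1, 0, 0.5 * min(a, b))  # centre close to the edge
        ctr <- switch(edge,
          c(1 + d, 1 + u * (W - 2)),
          c(H - d, 1 + u * (W - 2)),
          c(1 + u * (H - 2), 1 + d),
          c(1 + u * (H - 2), W - d))
      } else {
        m <- rmax + cellGap + 1
        if (2 * m >= min(H, W)) next
        ctr <- c(stats::runif(1, m, H - m), stats::runif(1, m, W - m))
      }
      px <- ellipsePixels(ctr, a, b, th, H, W)
      if (length(px) < 9L) next
      test <- dilateIndices(px, H, W, cellGap)
      if (any(occ[test])) next
      occ[test] <- TRUE
      lab[px] <- k
      cells[[k]] <- list(id = k, center = ctr, semiAxes = c(a, b),
                         orientation = th, pixels = px)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "could not place cell %d of %d after %d attempts: density too high for a %dx%d field (radii %.1f-%.1f px)",
        k, nCells, retryBudget, H, W, cellRadiusRange[1], cellRadiusRange[2]))
    }
  }

  # droplets
  pxUm <- calib@pixelSizeUm
  dropRows <- list()
  fluorDrops <- matrix(0, H, W)
  for (k in seq_len(nCells)) {
    cell <- cells[[k]]
    nD <- stats::rpois(1, archetype@dropletsPerCellMean)
    placedD <- list()
    for (j in seq_len(nD)) {
      rUm <- stats::rlnorm(1, archetype@radiusLogMean, archetype@radiusLogSd)
      rPx <- max(1, rUm / pxUm)
      peak <- round(stats::runif(1, archetype@intensityRange[1],
                                 archetype@intensityRange[2]))
      # the cluster/independent decision is drawn once per droplet; the
      # retry loop only re-samples positions, so crowding cannot inflate
      # the effective clustering rate
      cluster <- length(placedD) > 0 &&
        stats::runif(1) < archetype@clusteringProb
      ok <- FALSE
      for (try in seq_len(retryBudget)) {
        if (cluster) {
          anchorIdx <- sample.int(length(placedD), 1L)
          anchor <- placedD[[anchorIdx]]
          ang <- stats::runif(1, 0, 2 * pi)
          d <- anchor$radius + rPx
          ctr <- anchor$center + d * c(cos(ang), sin(ang))
        } else {
          ctr <- sampleInsideEllipse(cell, margin = rPx + 1)
          if (is.null(ctr)) break  # droplet cannot fit in this cell at all
        }
        if (!insideEllipse(ctr, cell, margin = rPx + 1)) next
        if (length(placedD)) {
          others <- if (cluster) placedD[-anchorIdx] else placedD
          gap <- if (cluster) 0 else minDropletGap  # tangent to the anchor,
          if (length(others)) {                     # no deep overlap elsewhere
            dd <- vapply(others, function(p)
              sqrt(sum((p$center - ctr)^2)) - p$radius - rPx, numeric(1))
            if (any(dd < gap)) next
          }
        }
        ok <- TRUE
        break
      }
      if (!ok) next  # omitted: the table reflects only rendered droplets
      placedD[[length(placedD) + 1L]] <- list(center = ctr, radius = rPx)
      dropRows[[length(dropRows) + 1L]] <- data.frame(
        owner_cell = k, row = ctr[1], col = ctr[2], radius_px = rPx,
        peak = peak, area_um2 = pi * rPx^2 * pxUm^2)
      # render the hard disk, max-combined so peaks stay interpretable
      disk <- diskPixels(ctr, rPx, H, W)
      fluorDrops[disk] <- pmax(fluorDrops[disk], peak)
    }
  }
  dropTab <- if (length(dropRows)) do.call(rbind, dropRows) else
    data.frame(owner_cell = integer(), row = numeric(), col = numeric(),
               radius_px = numeric(), peak = numeric(), area_um2 = numeric())

  fluorDrops <- blurImage(fluorDrops, blurSigma, blurRadius)
  fbg <- fluorBackground + stats::rnorm(H * W, 0, fluorNoiseSd)
  fbg <- pmin(pmax(fbg, 0), 1900)  # background stays below the counting floor
  fluor <- clampInt(matrix(fbg, H, W) + fluorDrops)

  # brightfield: dark interior, bright rim on a noisy background
  bf <- matrix(bfBackground, H, W)
  for (cell in cells) {
    q <- ellipseQ(cell, H, W)
    inside <- which(q$q <= 1)
    rim <- inside[q$q[inside] >= 0.72]
    bf[q$idx[inside]] <- bfInterior
    bf[q$idx[rim]] <- bfRim
  }
  bf <- clampInt(bf + matrix(stats::rnorm(H * W, 0, bfNoiseSd), H, W))

  new("Scene", brightfield = bf, fluorescence = fluor, labelImage = lab,
      droplets = dropTab, calibration = calib, strainTag = strainTag,
      experimentId = experimentId, fieldId = fieldId,
      seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

# pixels (linear indices) of an ellipse clipped to the image
ellipsePixels <- function(center, a, b, theta, H, W) {
  q <- ellipseQ(list(center = center, semiAxes = c(a, b),
                     orientation = theta), H, W)
  q$idx[q$q <= 1]
}

# quadratic form of the ellipse over its bounding box
ellipseQ <- function(cell, H, W) {
  ctr <- cell$center; a <- cell$semiAxes[1]; b <- cell$semiAxes[2]
  th <- cell$orientation
  rmax <- max(a, b)
  r0 <- max(1L, floor(ctr[1] - rmax)); r1 <- min(H, ceiling(ctr[1] + rmax))
  c0 <- max(1L, floor(ctr[2] - rmax)); c1 <- min(W, ceiling(ctr[2] + rmax))
  rows <- r0:r1; colsv <- c0:c1
  dr <- matrix(rows - ctr[1], length(rows), length(colsv))
  dc <- matrix(colsv - ctr[2], length(rows), length(colsv), byrow = TRUE)
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  qm <- (u / a)^2 + (v / b)^2
  idx <- as.integer(outer(rows, (colsv - 1L) * H, "+"))
  list(idx = idx, q = as.numeric(qm))
}

diskPixels <- function(center, radius, H, W) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(H, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(W, ceiling(center[2] + radius))
  rows <- r0:r1; colsv <- c0:c1
  dr <- matrix(rows - center[1], length(rows), length(colsv))
  dc <- matrix(colsv - center[2], length(rows), length(colsv), byrow = TRUE)
  idx <- as.integer(outer(rows, (colsv - 1L) * H, "+"))
  idx[as.numeric(dr^2 + dc^2) <= radius^2]
}

# is a point inside the cell ellipse shrunk by `margin` on both axes?
insideEllipse <- function(pt, cell, margin = 0) {
  a <- cell$semiAxes[1] - margin; b <- cell$semiAxes[2] - margin
  if (a <= 0 || b <= 0) return(FALSE)
  th <- cell$orientation
  d <- pt - cell$center
  u <- d[1] * cos(th) + d[2] * sin(th)
  v <- -d[1] * sin(th) + d[2] * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# uniform point in the margin-shrunk ellipse (NULL if it vanishes)
sampleInsideEllipse <- function(cell, margin = 0) {
  a <- cell$semiAxes[1] - margin; b <- cell$semiAxes[2] - margin
  if (a <= 0 || b <= 0) return(NULL)
  th <- cell$orientation
  r <- sqrt(stats::runif(1)); ang <- stats::runif(1, 0, 2 * pi)
  u <- a * r * cos(ang); v <- b * r * sin(ang)
  cell$center + c(u * cos(th) - v * sin(th), u * sin(th) + v * cos(th))
}

#' Generate a complete strain x experiment x field design of scenes
#'
#' Mirrors the standard imaging design: each strain is imaged in
#' `fieldsPerStrain` fields in each of `nExperiments` independent
#' experiments. Per-scene seeds are derived from the master seed with
#' [deriveSeed()], so each scene is reproducible in isolation.
#'
#' @param archetypes nonempty list of [StrainArchetype-class] objects.
#' @param nExperiments,fieldsPerStrain design size; the classic design is 3
#'   experiments x 3 fields.
#' @param seed master seed.
#' @param ... passed on to [generateScene()] (cell counts, shapes, ...).
#' @return list of [Scene-class] objects, one per strain x experiment x field.
#' @export
generateExperiment <- function(archetypes, nExperiments = 3L,
                               fieldsPerStrain = 3L, seed = 1L, ...) {
  if (length(archetypes) == 0) stop("archetypes must be a nonempty list")
  if (fieldsPerStrain < 1) stop("fieldsPerStrain must be >= 1")
  if (is(archetypes, "StrainArchetype")) archetypes <- list(archetypes)
  scenes <- list()
  for (e in seq_len(nExperiments)) {
    for (s in seq_along(archetypes)) {
      for (f in seq_len(fieldsPerStrain)) {
        sSeed <- deriveSeed(seed, e, s, f)
        scenes[[length(scenes) + 1L]] <- generateScene(
          archetypes[[s]], seed = sSeed,
          strainTag = archetypes[[s]]@name,
          experimentId = paste0("E", e), fieldId = paste0("F", f), ...)
      }
    }
  }
  scenes
}

#' Idealised prediction maps from ground truth
#'
#' Constructs the prediction maps a perfectly trained network would emit for
#' a scene: the spatial embedding of every cell pixel equals that cell's mean
#' pixel coordinate (so embeddings are exactly constant per cell), the seed
#' score is 1 inside cells and 0 outside, and the bandwidth is a constant.
#' Feeding the result to [clusterInstances()] recovers the ground-truth label
#' image exactly when cells are separated by more than a few bandwidths,
#' which makes the clustering stage testable without any training.
#'
#' @param scene a [Scene-class] with at least one cell.
#' @param bandwidth positive constant sigma, in embedding (normalised
#'   coordinate) units.
#' @return a [PredictionMaps-class].
#' @export
oraclePredictionMaps <- function(scene, bandwidth = 0.02) {
  lab <- scene@labelImage
  if (max(lab) < 1) stop("scene must contain at least one cell")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  H <- nrow(lab); W <- ncol(lab); S <- max(H, W)
  rowN <- (matrix(seq_len(H), H, W) - 0.5) / S
  colN <- (matrix(seq_len(W), H, W, byrow = TRUE) - 0.5) / S
  offR <- matrix(0, H, W); offC <- matrix(0, H, W)
  for (k in seq_len(max(lab))) {
    px <- which(lab == k)
    offR[px] <- mean(rowN[px]) - rowN[px]
    offC[px] <- mean(colN[px]) - colN[px]
  }
  new("PredictionMaps", seed = matrix(as.numeric(lab > 0), H, W),
      bandwidth = matrix(bandwidth, H, W),
      offsetRow = offR, offsetCol = offC)
}
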