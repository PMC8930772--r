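#' Iterative seed clustering of prediction maps into cell instances
#'
#' The inference algorithm of the embedding segmentation: among unassigned
#' pixels with seed score above `seedThreshold`, pick the pixel with the
#' highest seed score; every unassigned pixel whose embedding lies within the
#' seed pixel's Gaussian kernel (bandwidth = the seed pixel's own predicted
#' sigma) at membership above `membershipThreshold` is clustered into a new
#' instance. Repeat until no foreground pixel (seed score > `seedThreshold`)
#' remains unassigned. Termination is guaranteed because the seed pixel
#' always assigns itself (its kernel value is exactly 1). Ties in the seed
#' argmax break to the smallest (row, col).
#'
#' @param maps a [PredictionMaps-class].
#' @param seedThreshold foreground cutoff on the seed score (default 0.5).
#' @param membershipThreshold Gaussian-kernel membership cutoff
#'   (default 0.5).
#' @return list of raw instances; each has `id`, `pixels` (linear indices),
#'   `seedPixel` (row, col) and `seedScore`. Empty list when no pixel is
#'   foreground.
#' @export
clusterInstances <- function(maps, seedThreshold = 0.5,
                             membershipThreshold = 0.5) {
  stopifnot(is(maps, "PredictionMaps"))
  H <- nrow(maps@seed); W <- ncol(maps@seed)
  emb <- embeddings(maps)
  eR <- emb$row; eC <- emb$col
  s <- maps@seed; bw <- maps@bandwidth
  unassigned <- rep(TRUE, H * W)
  out <- list()
  repeat {
    cand <- which(unassigned & s > seedThreshold)
    if (length(cand) == 0) break
    best <- cand[s[cand] == max(s[cand])]
    if (length(best) > 1) {  # smallest (row, col) lexicographically
      br <- pixRow(best, H); bc <- pixCol(best, H)
      best <- best[order(br, bc)][1]
    }
    u <- which(unassigned)
    d2 <- (eR[u] - eR[best])^2 + (eC[u] - eC[best])^2
    member <- u[exp(-d2 / (2 * bw[best]^2)) > membershipThreshold]
    member <- union(best, member)
    unassigned[member] <- FALSE
    out[[length(out) + 1L]] <- list(
      id = length(out) + 1L, pixels = sort(member),
      seedPixel = c(pixRow(best, H), pixCol(best, H)),
      seedScore = s[best])
  }
  out
}

#' Filter raw instances and build hull ROIs
#'
#' Applies the two published filters -- instances whose size falls below the
#' pixel-area threshold (strictly fewer than `minAreaPx` pixels; a 300-px
#' instance is retained) and instances touching the image border -- then
#' computes each survivor's convex hull, rasterises it into the region used
#' for downstream droplet counting, and renders a hull label image.
#'
#' @param raw list of raw instances from [clusterInstances()] (disjoint
#'   pixel sets; overlapping input is an upstream contract violation and
#'   raises an error).
#' @param imageShape `c(rows, cols)`.
#' @param minAreaPx area threshold in pixels (default 300).
#' @return a [SegmentationResult-class].
#' @export
postprocess <- function(raw, imageShape, minAreaPx = 300L) {
  H <- as.integer(imageShape[1]); W <- as.integer(imageShape[2])
  allPix <- unlist(lapply(raw, `[[`, "pixels"))
  if (anyDuplicated(allPix)) {
    stop("raw instances overlap: upstream clustering contract violated")
  }
  kept <- list(); removed <- list()
  for (inst in raw) {
    px <- inst$pixels
    area <- length(px)
    r <- pixRow(px, H); c <- pixCol(px, H)
    onBorder <- any(r == 1L | r == H | c == 1L | c == W)
    if (area < minAreaPx) {
      removed[[length(removed) + 1L]] <-
        data.frame(id = inst$id, reason = "small", areaPx = area)
      next
    }
    if (onBorder) {
      removed[[length(removed) + 1L]] <-
        data.frame(id = inst$id, reason = "border", areaPx = area)
      next
    }
    hull <- hullPolygon(r, c)
    inst$areaPx <- area
    inst$touchesBorder <- FALSE
    inst$hull <- hull
    inst$hullPixels <- rasterizeConvex(hull, H, W)
    kept[[length(kept) + 1L]] <- inst
  }
  lab <- matrix(0L, H, W)
  for (inst in kept) {  # first id wins on the rare overlapping hull pixel
    free <- inst$hullPixels[lab[inst$hullPixels] == 0L]
    lab[free] <- inst$id
  }
  new("SegmentationResult", instances = kept,
      removed = if (length(removed)) do.call(rbind, removed) else
        data.frame(id = integer(), reason = character(), areaPx = integer()),
      labelImage = lab,
      parameters = list(minAreaPx = minAreaPx, imageShape = c(H, W)))
}

# convex hull vertices (row, col matrix, counter-clockwise per chull)
hullPolygon <- function(r, c) {
  pts <- cbind(row = r, col = c)
  if (nrow(pts) == 1) return(pts)
  h <- grDevices::chull(pts[, "col"], pts[, "row"])
  pts[h, , drop = FALSE]
}

# every integer pixel inside (or on) the convex polygon, by half-plane tests
rasterizeConvex <- function(hull, H, W) {
  n <- nrow(hull)
  if (n == 1) return((hull[1, "col"] - 1L) * H + hull[1, "row"])
  if (n > 2) {  # orient counter-clockwise in the (col, row) plane
    a2 <- sum(hull[, "col"] * hull[c(2:n, 1), "row"] -
              hull[c(2:n, 1), "col"] * hull[, "row"])
    if (a2 < 0) hull <- hull[n:1, , drop = FALSE]
  }
  r0 <- max(1L, floor(min(hull[, "row"]))); r1 <- min(H, ceiling(max(hull[, "row"])))
  c0 <- max(1L, floor(min(hull[, "col"]))); c1 <- min(W, ceiling(max(hull[, "col"])))
  rows <- r0:r1; colsv <- c0:c1
  R <- matrix(rows, length(rows), length(colsv))
  C <- matrix(colsv, length(rows), length(colsv), byrow = TRUE)
  inside <- matrix(TRUE, length(rows), length(colsv))
  tol <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # edge i -> j; interior is on one consistent side (chull is ordered)
    er <- hull[j, "row"] - hull[i, "row"]
    ec <- hull[j, "col"] - hull[i, "col"]
    if (er == 0 && ec == 0) next
    # CCW polygon in the (col, row) plane: interior has nonnegative cross
    cr <- ec * (R - hull[i, "row"]) - er * (C - hull[i, "col"])
    inside <- inside & (cr >= -tol)
  }
  idx <- as.integer((C[inside] - 1L) * H + R[inside])
  sort(idx)
}

#' Compare a segmentation against a ground-truth label image
#'
#' Greedy best-IoU matching between segmented hull regions and ground-truth
#' instances. The per-truth IoU table assigns 0 to missed cells, so
#' `meanIoU` is the mean over ground-truth cells. Counting rules: a
#' predicted instance is *merged* if it contains the majority (> 50%) of the
#' pixels of two or more truth cells; a truth cell is *split* if it contains
#' the majority of two or more predicted instances; *matched* pairs are
#' greedy IoU matches with IoU >= 0.5; remaining truth cells are *missed*.
#'
#' @param result a [SegmentationResult-class] (hull regions are compared) or
#'   a plain integer label matrix.
#' @param truth ground-truth integer label matrix.
#' @return list with `table` (per-truth-cell data.frame: `truth_id`,
#'   `pred_id`, `iou`), `meanIoU`, and `counts` (matched, merged, split,
#'   missed).
#' @export
matchToGroundTruth <- function(result, truth) {
  predLab <- if (is(result, "SegmentationResult")) {
    if (!identical(dim(result@labelImage), dim(truth))) {
      stop("segmentation and truth shapes differ")
    }
    result@labelImage
  } else result
  if (!identical(dim(predLab), dim(truth))) stop("shapes differ")
  nT <- max(truth); nP <- max(predLab)
  tPix <- lapply(seq_len(nT), function(k) which(truth == k))
  pPix <- lapply(seq_len(nP), function(k) which(predLab == k))
  ov <- matrix(0, nT, max(nP, 1))
  for (ti in seq_len(nT)) {
    if (!length(tPix[[ti]])) next
    pv <- predLab[tPix[[ti]]]
    tab <- table(pv[pv > 0])
    if (length(tab)) ov[ti, as.integer(names(tab))] <- as.integer(tab)
  }
  tArea <- lengths(tPix); pArea <- if (nP) lengths(pPix) else integer(0)
  iouM <- matrix(0, nT, max(nP, 1))
  for (ti in seq_len(nT)) {
    for (pi in seq_len(nP)) {
      if (ov[ti, pi] > 0) {
        iouM[ti, pi] <- ov[ti, pi] / (tArea[ti] + pArea[pi] - ov[ti, pi])
      }
    }
  }
  # greedy matching by descending IoU
  pairIou <- numeric(nT); pairPred <- rep(NA_integer_, nT)
  usedP <- rep(FALSE, max(nP, 1))
  if (nP > 0 && nT > 0) {
    ord <- order(iouM, decreasing = TRUE)
    for (o in ord) {
      if (iouM[o] <= 0) break
      ti <- ((o - 1) %% nT) + 1; pi <- ((o - 1) %/% nT) + 1
      if (is.na(pairPred[ti]) && !usedP[pi]) {
        pairPred[ti] <- pi; pairIou[ti] <- iouM[ti, pi]; usedP[pi] <- TRUE
      }
    }
  }
  matched <- sum(pairIou >= 0.5)
  merged <- if (nP) sum(colSums(ov > 0.5 * tArea) >= 2) else 0L
  split <- if (nP) {
    sum(vapply(seq_len(nT), function(ti)
      sum(ov[ti, ] > 0.5 * pArea & pArea > 0) >= 2, logical(1)))
  } else 0L
  missed <- sum(pairIou < 0.5)
  list(table = data.frame(truth_id = seq_len(nT), pred_id = pairPred,
                          iou = pairIou),
       meanIoU = if (nT) mean(pairIou) else NA_real_,
       counts = c(matched = matched, merged = merged, split = split,
                  missed = missed))
}
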