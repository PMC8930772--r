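# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: flood-fill labeling instead of the union-find in
# src/, definitional sums of squares instead of lm(), direct per-pixel
# formula evaluation instead of the vectorised soft-mask code.

# brute-force connected components by BFS flood fill
floodCount <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  sizes <- integer(0)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE; n <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; n <- n + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  list(count = length(sizes), sizes = sizes)
}

# definitional randomized-complete-block sums of squares
rcbdOracle <- function(values, strain, block) {
  g <- mean(values)
  sMeans <- tapply(values, strain, mean)
  bMeans <- tapply(values, block, mean)
  s <- length(sMeans); b <- length(bMeans)
  ssS <- b * sum((sMeans - g)^2)
  ssB <- s * sum((bMeans - g)^2)
  ssT <- sum((values - g)^2)
  ssR <- ssT - ssS - ssB
  Fv <- (ssS / (s - 1)) / (ssR / ((s - 1) * (b - 1)))
  list(ssStrain = ssS, ssBlock = ssB, ssResidual = ssR, ssTotal = ssT,
       F = Fv, p = pf(Fv, s - 1, (s - 1) * (b - 1), lower.tail = FALSE))
}

# per-pixel soft-mask evaluation straight from the formula
softMaskOracle <- function(maps, cellPixels) {
  H <- nrow(seedMap(maps)); W <- ncol(seedMap(maps))
  S <- max(H, W)
  eR <- matrix(NA_real_, H, W); eC <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    eR[r, c] <- (r - 0.5) / S + maps@offsetRow[r, c]
    eC[r, c] <- (c - 0.5) / S + maps@offsetCol[r, c]
  }
  eBar <- c(mean(eR[cellPixels]), mean(eC[cellPixels]))
  sBar <- mean(maps@bandwidth[cellPixels])
  phi <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    phi[r, c] <- exp(-((eR[r, c] - eBar[1])^2 + (eC[r, c] - eBar[2])^2) /
                       (2 * sBar^2))
  }
  phi
}

# random well-formed prediction maps on a small grid
randomMaps <- function(H, W, seed) {
  set.seed(seed)
  new("PredictionMaps",
      seed = matrix(runif(H * W), H, W),
      bandwidth = matrix(runif(H * W, 0.01, 0.1), H, W),
      offsetRow = matrix(rnorm(H * W, 0, 0.1), H, W),
      offsetCol = matrix(rnorm(H * W, 0, 0.1), H, W))
}

# a small scene for clustering / quantification tests: disjoint bright
# droplets, every droplet countable at every sweep threshold
brightArchetype <- function(meanDrops = 4) {
  strainArchetype("bright", dropletsPerCellMean = meanDrops,
                  radiusLogMean = log(0.2), radiusLogSd = 0.15,
                  intensityRange = c(22000, 30000), clusteringProb = 0)
}

smallScene <- function(seed = 1, nCells = 8, border = 0,
                       archetype = brightArchetype(), shape = c(128, 128),
                       radii = c(10, 13)) {
  generateScene(archetype, nCells = nCells, imageShape = shape,
                cellRadiusRange = radii, borderFraction = border,
                seed = seed, retryBudget = 500)
}
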