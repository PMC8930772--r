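test_that("scene generation is deterministic and honours the archetype", {
  sc1 <- smallScene(seed = 3)
  sc2 <- smallScene(seed = 3)
  expect_identical(brightfield(sc1), brightfield(sc2))
  expect_identical(fluorescence(sc1), fluorescence(sc2))
  expect_identical(droplets(sc1), droplets(sc2))
  expect_identical(labelImage(sc1), labelImage(sc2))

  # zero-mean archetype: empty droplet table, background-only fluorescence
  empty <- strainArchetype("none", 0, log(0.2), 0.1, c(8000, 20000))
  sc0 <- smallScene(seed = 4, archetype = empty)
  expect_equal(nrow(droplets(sc0)), 0)
  expect_lt(max(fluorescence(sc0)), 2000)
})

test_that("cells are disjoint, labelled 1..n, and each droplet lies inside its owner", {
  sc <- smallScene(seed = 5, border = 0.2)
  lab <- labelImage(sc)
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(as.integer(ids), seq_along(ids))
  dr <- droplets(sc)
  own <- lab[cbind(round(dr$row), round(dr$col))]
  expect_identical(as.integer(own), as.integer(dr$owner_cell))
  # ground-truth conservation: per-cell counts sum to the table length
  expect_identical(sum(table(dr$owner_cell)), nrow(dr))
})

test_that("fluorescence background stays below the counting floor", {
  for (seed in 1:3) {
    sc <- smallScene(seed = seed, archetype = brightArchetype(3))
    fl <- fluorescence(sc)
    dr <- droplets(sc)
    H <- nrow(fl); W <- ncol(fl)
    foot <- rep(FALSE, H * W)
    for (i in seq_len(nrow(dr))) {
      disk <- ldscope:::diskPixels(c(dr$row[i], dr$col[i]), dr$radius_px[i],
                                   H, W)
      foot[ldscope:::dilateIndices(disk, H, W, 1L)] <- TRUE  # blur support
    }
    expect_lt(max(fl[!foot]), 2000)
  }
})

test_that("archetype droplet means separate in the stated direction", {
  wtLike <- strainArchetype("wt-like", 8, log(0.15), 0.25, c(8000, 30000))
  nullLike <- strainArchetype("null-like", 2, log(0.5), 0.35,
                              c(10000, 40000))
  nCells <- 50
  counts <- function(a, seed) {
    sc <- generateScene(a, nCells = nCells, imageShape = c(384, 384),
                        cellRadiusRange = c(13, 17), borderFraction = 0,
                        seed = seed, retryBudget = 500)
    nrow(droplets(sc)) / nCells
  }
  mWt <- counts(wtLike, 11)
  mNull <- counts(nullLike, 12)
  # Poisson sampling bound: means 8 vs 2 over 50 cells are > 5 sigma apart
  expect_gt(mWt, mNull)
  expect_gt(mWt, 8 - 3 * sqrt(8 / nCells) - 1)  # allow placement omissions
  expect_lt(mNull, 2 + 3 * sqrt(2 / nCells))
})

test_that("supersized radii occur at the analytically expected frequency", {
  # area > 0.5 um^2 iff radius > sqrt(0.5/pi) um under the hard-disk model
  arch <- nullArchetype()
  rCut <- sqrt(0.5 / pi)
  pExp <- plnorm(rCut, arch@radiusLogMean, arch@radiusLogSd,
                 lower.tail = FALSE)
  sc <- generateScene(arch, nCells = 60, imageShape = c(512, 512),
                      cellRadiusRange = c(16, 20), borderFraction = 0,
                      seed = 21, retryBudget = 500)
  dr <- droplets(sc)
  n <- nrow(dr)
  pObs <- mean(dr$area_um2 > 0.5)
  # binomial 3-sigma band, plus slack for big droplets lost to placement
  expect_lt(abs(pObs - pExp), 3 * sqrt(pExp * (1 - pExp) / n) + 0.06)
})

test_that("impossible packings fail with a density error", {
  expect_error(
    generateScene(wtArchetype(), nCells = 50, imageShape = c(64, 64),
                  cellRadiusRange = c(10, 12), seed = 1, retryBudget = 20),
    "density")
  expect_error(generateScene(wtArchetype(), nCells = 0), "positive")
})

test_that("experiment generation forms a complete labelled design", {
  arch <- list(brightArchetype(2),
               strainArchetype("dim", 2, log(0.2), 0.15, c(8000, 15000)))
  scenes <- generateExperiment(arch, nExperiments = 3, fieldsPerStrain = 3,
                               seed = 9, nCells = 4, imageShape = c(72, 72),
                               cellRadiusRange = c(8, 10),
                               borderFraction = 0, retryBudget = 500)
  expect_length(scenes, 18)
  key <- vapply(scenes, function(s)
    paste(strainTag(s), s@experimentId, sep = "/"), character(1))
  expect_true(all(table(key) == 3))
  seeds <- vapply(scenes, function(s) s@seed, integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  expect_error(generateExperiment(list(), 3, 3, 1), "nonempty")
})

test_that("scenes round-trip through save and load unchanged", {
  sc <- smallScene(seed = 6, nCells = 4, shape = c(72, 72), radii = c(8, 10))
  d <- withr::local_tempdir()
  writeScene(sc, d)
  rt <- readScene(d)
  expect_identical(brightfield(rt), brightfield(sc))
  expect_identical(fluorescence(rt), fluorescence(sc))
  expect_identical(labelImage(rt), labelImage(sc))
  expect_equal(droplets(rt), droplets(sc), tolerance = 1e-12)
  expect_identical(strainTag(rt), strainTag(sc))
  expect_identical(rt@experimentId, sc@experimentId)
  expect_identical(rt@fieldId, sc@fieldId)
})

test_that("oracle prediction maps are constant per cell at the centroid", {
  sc <- smallScene(seed = 7, nCells = 2, shape = c(72, 72), radii = c(8, 10))
  maps <- oraclePredictionMaps(sc, bandwidth = 0.02)
  lab <- labelImage(sc)
  emb <- embeddings(maps)
  S <- max(dim(lab))
  for (k in 1:2) {
    px <- which(lab == k)
    r <- ldscope:::pixRow(px, nrow(lab)); c <- ldscope:::pixCol(px, nrow(lab))
    expect_equal(unique(round(emb$row[px], 12)),
                 round(mean((r - 0.5) / S), 12))
    expect_equal(unique(round(emb$col[px], 12)),
                 round(mean((c - 0.5) / S), 12))
  }
  # two cells: embedding separation equals centroid separation
  e1 <- c(emb$row[which(lab == 1)[1]], emb$col[which(lab == 1)[1]])
  e2 <- c(emb$row[which(lab == 2)[1]], emb$col[which(lab == 2)[1]])
  ctr <- function(k) {
    px <- which(lab == k)
    c(mean(ldscope:::pixRow(px, nrow(lab))),
      mean(ldscope:::pixCol(px, nrow(lab))))
  }
  expect_equal(sqrt(sum((e1 - e2)^2)), sqrt(sum((ctr(1) - ctr(2))^2)) / S,
               tolerance = 1e-10)
  expect_identical(seedMap(maps), matrix(as.numeric(lab > 0), nrow(lab)))
})
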