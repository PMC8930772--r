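test_that("particle counts match a brute-force flood fill on the fixtures", {
  spec <- thresholdSweepSpec()
  expect_identical(spec$thresholds, seq(20000, 2000, by = -2000))

  threeD <- fixtureThreeDisks()
  bridge <- fixtureBridge()
  for (thr in spec$thresholds) {
    expect_identical(
      countParticles(threeD, seq_along(threeD), thr)$count,
      floodCount(threeD >= thr, 8)$count)
    expect_identical(
      countParticles(bridge, seq_along(bridge), thr)$count,
      floodCount(bridge >= thr, 8)$count)
  }
  # three disjoint 25,000-count disks: 3 particles at every threshold
  expect_true(all(vapply(spec$thresholds, function(thr)
    countParticles(threeD, seq_along(threeD), thr)$count, integer(1)) == 3L))
  # bridge at 6,000 merges the two disks below the 8,000 threshold
  counts <- vapply(spec$thresholds, function(thr)
    countParticles(bridge, seq_along(bridge), thr)$count, integer(1))
  expect_identical(counts, c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L))
  sw <- sweepCell(bridge, seq_along(bridge))
  expect_identical(unname(sw$countsPerThreshold), counts)
  expect_identical(sw$ldCount, 2L)

  # background-only region: zero particles everywhere
  bg <- matrix(1500L, 20, 20)
  expect_true(all(vapply(spec$thresholds, function(thr)
    countParticles(bg, seq_along(bg), thr)$count, integer(1)) == 0L))
  expect_error(countParticles(bg, integer(0), 2000), "nonempty")
  expect_error(thresholdSweepSpec(2000, 20000), "start")
  expect_error(thresholdSweepSpec(20000, 2000, 1700), "step")
})

test_that("connectivity choice matches its flood-fill counterpart", {
  set.seed(99)
  for (i in 1:10) {
    img <- matrix(sample(c(0L, 25000L), 144, replace = TRUE,
                         prob = c(0.6, 0.4)), 12, 12)
    expect_identical(countParticles(img, seq_along(img), 10000,
                                    connectivity = 8)$count,
                     floodCount(img >= 10000, 8)$count)
    expect_identical(countParticles(img, seq_along(img), 10000,
                                    connectivity = 4)$count,
                     floodCount(img >= 10000, 4)$count)
  }
})

test_that("supersized scoring applies the strict area and threshold rules", {
  calib <- calibration(0.065)
  # radius 25 px at 30,000 counts: ~8.3 um^2, far above the 0.5 um^2 cut
  d25 <- fixtureDisk(25, 30000)
  s25 <- sweepCell(d25, seq_along(d25), calib = calib)
  expect_true(s25$hasSupersized)
  a25 <- countParticles(d25, seq_along(d25), 10000, calib = calib)$areasUm2
  expect_equal(a25, pi * 25^2 * 0.065^2, tolerance = 0.02)

  # radius 10 px: ~1.33 um^2, still supersized
  d10 <- fixtureDisk(10, 30000)
  expect_true(sweepCell(d10, seq_along(d10), calib = calib)$hasSupersized)

  # radius 5 px: ~0.33 um^2, not supersized
  d5 <- fixtureDisk(5, 30000)
  s5 <- sweepCell(d5, seq_along(d5), calib = calib)
  expect_false(s5$hasSupersized)
  expect_identical(s5$ldCount, 1L)

  # 9,000-count disk: counted in the sweep, invisible to the 10,000 pass
  dim10 <- fixtureDisk(10, 9000)
  sDim <- sweepCell(dim10, seq_along(dim10), calib = calib)
  expect_identical(sDim$ldCount, 1L)
  expect_false(sDim$hasSupersized)
  dim25 <- fixtureDisk(25, 9000)   # size is irrelevant below the threshold
  expect_false(sweepCell(dim25, seq_along(dim25),
                         calib = calib)$hasSupersized)
})

test_that("mask nesting and the maximum rule hold on random scenes", {
  for (seed in 1:4) {
    sc <- smallScene(seed = 40 + seed, nCells = 5, shape = c(96, 96),
                     radii = c(9, 12), archetype = wtArchetype())
    fl <- fluorescence(sc)
    spec <- thresholdSweepSpec()
    lab <- labelImage(sc)
    for (k in seq_len(max(lab))) {
      region <- which(lab == k)
      sw <- sweepCell(fl, region, spec, sceneCalibration(sc))
      expect_identical(sw$ldCount, max(sw$countsPerThreshold))
      expect_true(all(sw$ldCount >= sw$countsPerThreshold))
      # monotone mask nesting between consecutive thresholds
      for (i in seq_len(9)) {
        hi <- fl[region] >= spec$thresholds[i]
        lo <- fl[region] >= spec$thresholds[i + 1]
        expect_true(all(lo[hi]))
      }
    }
  }
})

test_that("disjoint bright droplets are recovered exactly from ground truth", {
  sc <- smallScene(seed = 55, nCells = 8, archetype = brightArchetype(4))
  fs <- summarizeField(sc)
  dr <- droplets(sc)
  truth <- table(factor(dr$owner_cell, levels = seq_len(max(labelImage(sc)))))
  expect_identical(as.integer(fs$cells$ld_count), as.integer(truth))
  expect_equal(fs$summary$mean_ld_per_cell, nrow(dr) / max(labelImage(sc)))
})

test_that("field summaries aggregate per-cell results correctly", {
  # 4 cells with known counts via a constructed image: {2, 2, 4, 0} -> mean 2
  img <- matrix(0L, 40, 40)
  mk <- function(r, c) img[r:(r + 1), c:(c + 1)] <<- 25000L
  mk(3, 3); mk(3, 12)                 # cell 1: 2 particles
  mk(14, 3); mk(14, 12)               # cell 2: 2 particles
  mk(24, 3); mk(24, 8); mk(24, 13); mk(24, 18)  # cell 3: 4
  regions <- list(`1` = as.integer(outer(1:10, (1:20 - 1L) * 40, "+")),
                  `2` = as.integer(outer(11:20, (1:20 - 1L) * 40, "+")),
                  `3` = as.integer(outer(21:30, (1:20 - 1L) * 40, "+")),
                  `4` = as.integer(outer(31:40, (1:20 - 1L) * 40, "+")))
  fs <- summarizeField(img, regions)
  expect_identical(fs$cells$ld_count, c(2L, 2L, 4L, 0L))
  expect_equal(fs$summary$mean_ld_per_cell, 2.0)
  expect_equal(fs$summary$pct_cells_supersized, 0)
  expect_error(summarizeField(img, list()), "no cells")
})

test_that("areas scale with the square of the pixel size", {
  d10 <- fixtureDisk(10, 30000)
  a1 <- countParticles(d10, seq_along(d10), 10000,
                       calib = calibration(0.065))$areasUm2
  a2 <- countParticles(d10, seq_along(d10), 10000,
                       calib = calibration(0.065 / 2))$areasUm2
  expect_equal(a2, a1 / 4, tolerance = 1e-12)
  # halving the pixel size can only demote supersized flags
  s1 <- sweepCell(d10, seq_along(d10), calib = calibration(0.065))
  s2 <- sweepCell(d10, seq_along(d10), calib = calibration(0.065 / 2))
  expect_true(s1$hasSupersized >= s2$hasSupersized)
})
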