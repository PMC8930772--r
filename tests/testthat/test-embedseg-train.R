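test_that("soft mask matches the closed-form kernel and a brute-force oracle", {
  # constant embeddings over the cell: phi = 1 on every cell pixel
  sc <- smallScene(seed = 7, nCells = 1, shape = c(48, 48), radii = c(8, 10))
  maps <- oraclePredictionMaps(sc, bandwidth = 0.05)
  px <- which(labelImage(sc) == 1)
  sm <- softMask(maps, px)
  expect_true(all(abs(sm$phi[px] - 1) < 1e-12))

  # half-maximum at distance sigma * sqrt(2 ln 2)
  m <- new("PredictionMaps", seed = matrix(1, 1, 3),
           bandwidth = matrix(0.1, 1, 3),
           offsetRow = matrix(0, 1, 3),
           offsetCol = matrix(c(0, 0.1 * sqrt(2 * log(2)) - 1 / 3, 0), 1, 3))
  # cell = pixel 1 only; pixel 2's embedding sits at the half-max radius
  sm2 <- softMask(m, 1L)
  expect_equal(sm2$phi[1, 2], 0.5, tolerance = 1e-12)

  # random maps on a 7x7 grid against per-pixel brute force
  for (seed in 1:3) {
    maps <- randomMaps(7, 7, seed)
    px <- sample(49, 11)
    sm <- softMask(maps, px)
    expect_equal(sm$phi, softMaskOracle(maps, px), tolerance = 1e-12)
  }
  expect_error(softMask(maps, integer(0)), "nonempty")
})

test_that("dice loss reproduces its defining arithmetic", {
  t1 <- matrix(0, 8, 8); t1[2:5, 2:5] <- 1
  expect_equal(diceLoss(t1, t1), 0, tolerance = 1e-6)
  t2 <- matrix(0, 8, 8); t2[7:8, 7:8] <- 1
  expect_equal(diceLoss(t1, t2), 1, tolerance = 1e-6)
  # phi = target on exactly half the target pixels: 1 - 2(n/2)/(n/2 + n) = 1/3
  phi <- matrix(0, 8, 8); phi[2:3, 2:5] <- 1
  expect_equal(diceLoss(phi, t1), 1 / 3, tolerance = 1e-6)
  expect_error(diceLoss(t1, matrix(0, 4, 4)), "mismatch")
  # bounds on random inputs
  set.seed(1)
  for (i in 1:20) {
    phi <- matrix(runif(64), 8, 8)
    tg <- matrix(rbinom(64, 1, 0.3), 8, 8)
    d <- diceLoss(phi, tg)
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("training loss is near zero on oracle maps and id-relabel invariant", {
  sc <- smallScene(seed = 8, nCells = 1, shape = c(32, 32), radii = c(7, 9))
  maps <- oraclePredictionMaps(sc, bandwidth = 0.02)
  tl <- trainingLoss(maps, labelImage(sc))
  # only kernel tails outside the cell contribute
  expect_lt(tl$instance, 0.05)
  expect_lt(tl$seed, 0.05)

  # relabeling instance ids leaves the loss unchanged
  sc2 <- smallScene(seed = 9, nCells = 3, shape = c(72, 72), radii = c(8, 10))
  maps2 <- randomMaps(72, 72, 4)
  lab <- labelImage(sc2)
  perm <- c(3L, 1L, 2L)
  labP <- lab; labP[lab > 0] <- perm[lab[lab > 0]]
  expect_equal(trainingLoss(maps2, lab)$total,
               trainingLoss(maps2, labP)$total, tolerance = 1e-12)

  # zero cells: instance term 0, seed term pulls the seed map to 0
  labEmpty <- matrix(0L, 72, 72)
  tl0 <- trainingLoss(maps2, labEmpty)
  expect_identical(tl0$instance, 0)
  expect_equal(tl0$seed, mean(seedMap(maps2)^2), tolerance = 1e-12)
})

test_that("the loss is invariant under a consistent flip of maps and labels", {
  sc <- smallScene(seed = 10, nCells = 3, shape = c(72, 72), radii = c(8, 10))
  lab <- labelImage(sc)
  maps <- randomMaps(72, 72, 5)
  H <- nrow(lab)
  flip <- function(m) m[H:1, , drop = FALSE]
  # flipping rows negates the row offsets (the embedding frame is an isometry)
  mapsF <- new("PredictionMaps", seed = flip(seedMap(maps)),
               bandwidth = flip(bandwidthMap(maps)),
               offsetRow = -flip(maps@offsetRow),
               offsetCol = flip(maps@offsetCol))
  expect_equal(trainingLoss(maps, lab)$total,
               trainingLoss(mapsF, flip(lab))$total, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences (detached seed target)", {
  spec <- networkSpec(depth = 2, baseChannels = 4)
  params <- initNetwork(spec, seed = 5)
  H <- W <- 12
  set.seed(42)
  x <- matrix(rnorm(H * W), ncol = 1)
  lab <- matrix(0L, H, W); lab[3:6, 3:7] <- 1L; lab[8:11, 6:10] <- 2L
  lossOf <- function(p) {
    fwd <- ldscope:::netForward(p, x, H, W)
    ldscope:::headLoss(fwd$Y, lab, H, W, seedWeight = 0,
                       wantGrad = FALSE)$loss
  }
  fwd <- ldscope:::netForward(params, x, H, W)
  hl <- ldscope:::headLoss(fwd$Y, lab, H, W, seedWeight = 0)
  g <- ldscope:::netBackward(params, fwd, hl$dY)
  eps <- 1e-6
  for (nm in c("enc_in_1", "enc_res_2", "dec_in_1", "dec_res_1", "head")) {
    for (pn in names(g[[nm]])) {
      pv <- params$units[[nm]][[pn]]
      for (i in sample(length(pv), min(3, length(pv)))) {
        p2 <- params; p2$units[[nm]][[pn]][i] <- pv[i] + eps
        p3 <- params; p3$units[[nm]][[pn]][i] <- pv[i] - eps
        num <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
        expect_equal(unname(g[[nm]][[pn]][i]), num, tolerance = 1e-4,
                     label = sprintf("grad %s$%s[%d]", nm, pn, i))
      }
    }
  }
})

test_that("short training runs are deterministic and reduce the loss", {
  scenes <- lapply(1:4, function(i)
    smallScene(seed = 30 + i, nCells = 4, shape = c(80, 80),
               radii = c(8, 10)))
  spec <- networkSpec(depth = 2, baseChannels = 8)
  cfg <- trainConfig(cropSize = 64, steps = 60, batchSize = 2,
                     augment = FALSE, seed = 3, valEvery = 30)
  net1 <- trainNetwork(spec, scenes, cfg)
  net2 <- trainNetwork(spec, scenes, cfg)
  expect_identical(net1$trace$total, net2$trace$total)

  # smoothed loss decreases over 200 steps on small crops
  cfg2 <- trainConfig(cropSize = 64, steps = 200, batchSize = 2,
                      augment = TRUE, seed = 4, valEvery = 50)
  net3 <- trainNetwork(spec, scenes, cfg2)
  first <- mean(net3$trace$total[1:20])
  last <- mean(net3$trace$total[181:200])
  expect_lt(last, first)

  # validation bookkeeping: no held-out scene id in any training batch
  valIds <- net3$valIds
  used <- unlist(strsplit(net3$trace$scenes, ";"))
  expect_false(any(as.integer(used) %in% valIds))
  expect_true(all(net3$trainIds %in% seq_along(scenes)))
})
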