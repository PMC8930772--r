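#' Grow an instance soft mask from prediction maps
#'
#' For a cell's pixel set, computes the mean embedding `e_k` and the mean
#' bandwidth `sigma_k` over those pixels, then the Gaussian-kernel soft mask
#' `phi_k(i) = exp(-||e_i - e_k||^2 / (2 sigma_k^2))` over the whole image.
#' `phi` is 1 wherever the embedding equals the cell mean.
#'
#' @param maps a [PredictionMaps-class].
#' @param cellPixels nonempty integer vector of linear pixel indices.
#' @return list of class `InstanceSoftMask`: `meanEmbedding` (row, col in
#'   normalised coordinates), `meanBandwidth`, `phi` (matrix).
#' @export
softMask <- function(maps, cellPixels) {
  if (length(cellPixels) == 0) stop("cell pixel set must be nonempty")
  emb <- embeddings(maps)
  eBar <- c(mean(emb$row[cellPixels]), mean(emb$col[cellPixels]))
  sBar <- mean(maps@bandwidth[cellPixels])
  d2 <- (emb$row - eBar[1])^2 + (emb$col - eBar[2])^2
  structure(list(meanEmbedding = eBar, meanBandwidth = sBar,
                 phi = exp(-d2 / (2 * sBar^2))),
            class = "InstanceSoftMask")
}

#' Dice loss between a soft mask and a binary target
#'
#' `1 - 2 sum(phi * t) / (sum(phi) + sum(t) + eps)`: 0 for perfect binary
#' agreement, approaching 1 for disjoint supports. Chosen for instance
#' training because it is insensitive to the foreground/background class
#' imbalance of crowded microscopy fields.
#'
#' @param phi soft mask matrix in `(0, 1]`.
#' @param target binary matrix of the same shape.
#' @param eps stabiliser.
#' @return nonnegative scalar.
#' @export
diceLoss <- function(phi, target, eps = 1e-6) {
  if (!identical(dim(phi), dim(target))) stop("shape mismatch")
  1 - 2 * sum(phi * target) / (sum(phi) + sum(target) + eps)
}

#' Full training loss of prediction maps against a ground-truth labelling
#'
#' The instance term grows a soft mask for every ground-truth cell and
#' averages the Dice losses against the cells' binary masks. The seed term
#' regresses the seed map to the (gradient-detached) soft-mask value on each
#' cell's pixels and to 0 on background, so at convergence the seed score
#' predicts how well a pixel would serve as a cluster seed.
#'
#' @param maps a [PredictionMaps-class].
#' @param labelImage integer ground-truth label matrix (0 background).
#' @param seedWeight weight of the seed term.
#' @return list with `total`, `instance`, `seed` and `perCell` (named Dice
#'   losses).
#' @export
trainingLoss <- function(maps, labelImage, seedWeight = 1) {
  if (!identical(dim(maps@seed), dim(labelImage))) stop("shape mismatch")
  ids <- sort(unique(labelImage[labelImage > 0]))
  phiTarget <- matrix(0, nrow(labelImage), ncol(labelImage))
  perCell <- numeric(0)
  for (k in ids) {
    px <- which(labelImage == k)
    sm <- softMask(maps, px)
    perCell[as.character(k)] <- diceLoss(sm$phi, matrix(
      as.numeric(labelImage == k), nrow(labelImage)))
    phiTarget[px] <- sm$phi[px]
  }
  instance <- if (length(ids)) mean(perCell) else 0
  seedTerm <- seedWeight * mean((maps@seed - phiTarget)^2)
  list(total = instance + seedTerm, instance = instance, seed = seedTerm,
       perCell = perCell)
}

# loss and gradient with respect to the raw head output (HW x 4):
# columns are seed logit, raw bandwidth, row offset, col offset.
headLoss <- function(Y, lab, H, W, bandwidthScale = 0.1, seedWeight = 1,
                     eps = 1e-6, wantGrad = TRUE) {
  N <- H * W
  S <- max(H, W)
  rowN <- (rep.int(seq_len(H), W) - 0.5) / S
  colN <- (rep(seq_len(W), each = H) - 0.5) / S
  s <- sigmoid(Y[, 1])
  sigma <- softplus(Y[, 2]) * bandwidthScale
  eR <- rowN + Y[, 3]
  eC <- colN + Y[, 4]
  ids <- sort(unique(lab[lab > 0]))
  nC <- length(ids)
  dER <- numeric(N); dEC <- numeric(N); dSigma <- numeric(N)
  phiTarget <- numeric(N)
  instance <- 0
  for (k in ids) {
    px <- which(lab == k)
    Tn <- length(px)
    eRm <- mean(eR[px]); eCm <- mean(eC[px]); sg <- mean(sigma[px])
    dR <- eR - eRm; dC <- eC - eCm
    d2 <- dR^2 + dC^2
    phi <- exp(-d2 / (2 * sg^2))
    A <- sum(phi[px]); B <- sum(phi)
    denom <- B + Tn + eps
    instance <- instance + (1 - 2 * A / denom)
    phiTarget[px] <- phi[px]
    if (wantGrad) {
      g <- rep.int(2 * A / denom^2, N)
      g[px] <- g[px] - 2 / denom
      g <- g / nC
      common <- g * phi
      dER <- dER - common * dR / sg^2
      dEC <- dEC - common * dC / sg^2
      sR <- sum(common * dR) / sg^2
      sC <- sum(common * dC) / sg^2
      dER[px] <- dER[px] + sR / Tn
      dEC[px] <- dEC[px] + sC / Tn
      sS <- sum(common * d2) / sg^3
      dSigma[px] <- dSigma[px] + sS / Tn
    }
  }
  instance <- if (nC) instance / nC else 0
  seedTerm <- seedWeight * mean((s - phiTarget)^2)
  loss <- instance + seedTerm
  if (!wantGrad) {
    return(list(loss = loss, instance = instance, seed = seedTerm))
  }
  dS <- seedWeight * 2 * (s - phiTarget) / N
  dY <- cbind(dS * s * (1 - s),
              dSigma * sigmoid(Y[, 2]) * bandwidthScale,
              dER, dEC)
  list(loss = loss, instance = instance, seed = seedTerm, dY = dY)
}

# ---- Adam ----

adamInit <- function(params) {
  st <- lapply(params$units, function(u)
    lapply(u, function(p) list(m = p * 0, v = p * 0)))
  list(state = st, t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      st <- opt$state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      opt$state[[nm]][[pn]] <- st
      params$units[[nm]][[pn]] <- params$units[[nm]][[pn]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}

# ---- training ----

# the 8 dihedral transforms of a matrix (k = 0..7)
dihedral <- function(m, k) {
  if (k >= 4) m <- t(m)
  k <- k %% 4
  if (k == 1) m <- m[nrow(m):1, , drop = FALSE]
  if (k == 2) m <- m[, ncol(m):1, drop = FALSE]
  if (k == 3) m <- m[nrow(m):1, ncol(m):1, drop = FALSE]
  m
}

normalizeImage <- function(img) {
  s <- stats::sd(img)
  (img - mean(img)) / if (s > 0) s else 1
}

#' Train the embedding segmentation network
#'
#' Optimises the soft-mask Dice + seed-regression loss with Adam on random
#' (optionally flipped/rotated) crops of the training scenes. Validation
#' loss is evaluated every `valEvery` steps on held-out scenes and the
#' best-on-validation parameters are returned. With augmentation off and a
#' fixed seed, two runs produce identical loss traces.
#'
#' @param spec a [networkSpec()].
#' @param scenes list of [Scene-class] objects (training pool).
#' @param config a [trainConfig()].
#' @param valScenes optional explicit validation scenes; by default the
#'   last `validationFraction` of `scenes` is held out (train/validation
#'   split protocol; e.g. 18 annotated fields split 14/4).
#' @return list of class `ldNet`: `params` (best on validation),
#'   `finalParams`, `spec`, `config`, `trace` (per-step losses and the
#'   scene ids of each batch), `valTrace`, `bestStep`, `trainIds`,
#'   `valIds`.
#' @export
trainNetwork <- function(spec, scenes, config = trainConfig(),
                         valScenes = NULL) {
  if (length(scenes) == 0) stop("training set must be nonempty")
  if (is.null(valScenes)) {
    nVal <- max(1L, min(length(scenes) - 1L,
                        round(config$validationFraction * length(scenes))))
    valIds <- seq(length(scenes) - nVal + 1L, length(scenes))
    valScenes <- scenes[valIds]
    trainIds <- setdiff(seq_along(scenes), valIds)
    scenes <- scenes[trainIds]
  } else {
    trainIds <- seq_along(scenes)
    valIds <- length(scenes) + seq_along(valScenes)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- initNetwork(spec, seed = deriveSeed(config$seed, "init"))
  opt <- adamInit(params)
  cs <- config$cropSize
  imgs <- lapply(scenes, function(s) normalizeImage(s@brightfield))
  labs <- lapply(scenes, function(s) s@labelImage)
  valImgs <- lapply(valScenes, function(s) normalizeImage(s@brightfield))
  valLabs <- lapply(valScenes, function(s) s@labelImage)
  trace <- vector("list", config$steps)
  valTrace <- list()
  best <- list(loss = Inf, params = params, step = 0L)
  for (step in seq_len(config$steps)) {
    gacc <- NULL
    tot <- inst <- sd_ <- 0
    usedScenes <- integer(config$batchSize)
    for (bi in seq_len(config$batchSize)) {
      si <- sample.int(length(scenes), 1L)
      usedScenes[bi] <- trainIds[si]
      img <- imgs[[si]]; lab <- labs[[si]]
      H0 <- nrow(img); W0 <- ncol(img)
      if (H0 < cs || W0 < cs) {
        stop("cropSize exceeds scene size: ", cs, " > ", min(H0, W0))
      }
      r0 <- if (H0 > cs) sample.int(H0 - cs + 1L, 1L) else 1L
      c0 <- if (W0 > cs) sample.int(W0 - cs + 1L, 1L) else 1L
      ic <- img[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
      lc <- lab[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
      if (config$augment) {
        k <- sample.int(8L, 1L) - 1L
        ic <- dihedral(ic, k); lc <- dihedral(lc, k)
      }
      fwd <- netForward(params, matrix(as.numeric(ic), ncol = 1), cs, cs)
      hl <- headLoss(fwd$Y, lc, cs, cs, config$bandwidthScale,
                     config$seedLossWeight)
      if (!is.finite(hl$loss)) {
        stop(sprintf(
          "training diverged (non-finite loss) at step %d; reduce the learning rate or check the inputs",
          step))
      }
      g <- netBackward(params, fwd, hl$dY)
      gacc <- if (is.null(gacc)) g else accumGrads(gacc, g)
      tot <- tot + hl$loss; inst <- inst + hl$instance; sd_ <- sd_ + hl$seed
    }
    gacc <- scaleGrads(gacc, 1 / config$batchSize)
    upd <- adamStep(params, gacc, opt, config$learningRate)
    params <- upd$params; opt <- upd$opt
    trace[[step]] <- data.frame(
      step = step, total = tot / config$batchSize,
      instance = inst / config$batchSize, seed = sd_ / config$batchSize,
      scenes = paste(usedScenes, collapse = ";"))
    if (step %% config$valEvery == 0 || step == config$steps) {
      vl <- mean(vapply(seq_along(valImgs), function(i) {
        v <- netForward(params,
                        matrix(as.numeric(valImgs[[i]]), ncol = 1),
                        nrow(valImgs[[i]]), ncol(valImgs[[i]]))
        headLoss(v$Y, valLabs[[i]], nrow(valImgs[[i]]), ncol(valImgs[[i]]),
                 config$bandwidthScale, config$seedLossWeight,
                 wantGrad = FALSE)$loss
      }, numeric(1)))
      valTrace[[length(valTrace) + 1L]] <-
        data.frame(step = step, valLoss = vl)
      if (vl < best$loss) best <- list(loss = vl, params = params,
                                       step = step)
    }
  }
  structure(list(params = best$params, finalParams = params, spec = spec,
                 config = config, trace = do.call(rbind, trace),
                 valTrace = do.call(rbind, valTrace),
                 bestStep = best$step, bestValLoss = best$loss,
                 trainIds = trainIds, valIds = valIds),
            class = "ldNet")
}

accumGrads <- function(a, b) {
  for (nm in names(b)) {
    for (pn in names(b[[nm]])) a[[nm]][[pn]] <- a[[nm]][[pn]] + b[[nm]][[pn]]
  }
  a
}

scaleGrads <- function(g, f) {
  for (nm in names(g)) {
    for (pn in names(g[[nm]])) g[[nm]][[pn]] <- g[[nm]][[pn]] * f
  }
  g
}

#' @export
print.ldNet <- function(x, ...) {
  cat(sprintf(
    "ldNet: depth %d, base %d channels; %d steps trained, best validation loss %.4f at step %d\n",
    x$spec$depth, x$spec$baseChannels, nrow(x$trace), x$bestValLoss,
    x$bestStep))
  invisible(x)
}

#' Predict the per-pixel maps for an image
#'
#' Standardises the image, pads it (edge replication) to a multiple of the
#' network's pooling factor, runs the forward pass and returns the maps on
#' the original grid. Normalisation statistics are computed per image, so
#' prediction is deterministic and needs no stored running averages.
#'
#' @param net an `ldNet` from [trainNetwork()], or an `ldNetParams`.
#' @param image brightfield matrix (raw counts or standardised).
#' @param bandwidthScale bandwidth scale; taken from the training config
#'   when `net` is an `ldNet`.
#' @return a [PredictionMaps-class].
#' @export
predictMaps <- function(net, image, bandwidthScale = NULL) {
  params <- if (inherits(net, "ldNet")) net$params else net
  if (is.null(bandwidthScale)) {
    bandwidthScale <- if (inherits(net, "ldNet")) {
      net$config$bandwidthScale
    } else 0.1
  }
  H <- nrow(image); W <- ncol(image)
  f <- 2^(params$spec$depth - 1)
  Hp <- ceiling(H / f) * f; Wp <- ceiling(W / f) * f
  img <- normalizeImage(image)
  if (Hp > H) img <- rbind(img, img[rep(H, Hp - H), , drop = FALSE])
  if (Wp > W) img <- cbind(img, img[, rep(W, Wp - W), drop = FALSE])
  fwd <- netForward(params, matrix(as.numeric(img), ncol = 1), Hp, Wp)
  toMat <- function(v) matrix(v, Hp, Wp)[seq_len(H), seq_len(W)]
  # offsets were learned in the padded coordinate frame; the embedding
  # normalisation uses the padded larger dimension
  new("PredictionMaps",
      seed = toMat(sigmoid(fwd$Y[, 1])),
      bandwidth = toMat(softplus(fwd$Y[, 2]) * bandwidthScale),
      offsetRow = toMat(fwd$Y[, 3]),
      offsetCol = toMat(fwd$Y[, 4]))
}

#' Segment an image end to end
#'
#' [predictMaps()] then [clusterInstances()] then [postprocess()].
#'
#' @param net trained `ldNet`.
#' @param image brightfield matrix (or a [Scene-class]).
#' @param minAreaPx,seedThreshold,membershipThreshold filter and clustering
#'   parameters.
#' @return a [SegmentationResult-class].
#' @export
segmentImage <- function(net, image, minAreaPx = 300L, seedThreshold = 0.5,
                         membershipThreshold = 0.5) {
  if (is(image, "Scene")) image <- image@brightfield
  maps <- predictMaps(net, image)
  raw <- clusterInstances(maps, seedThreshold, membershipThreshold)
  postprocess(raw, dim(image), minAreaPx)
}

#' Save or load a network checkpoint
#'
#' The checkpoint bundles the parameters with the architecture and training
#' configuration snapshots.
#'
#' @param net an `ldNet`.
#' @param path file path (.rds).
#' @return `readCheckpoint` returns the `ldNet`.
#' @export
writeCheckpoint <- function(net, path) {
  saveRDS(net[c("params", "finalParams", "spec", "config", "bestStep",
                "bestValLoss", "trainIds", "valIds")], path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  x <- readRDS(path)
  class(x) <- "ldNet"
  x
}

#' Write the per-step training log as CSV
#'
#' @param net an `ldNet`.
#' @param path CSV path.
#' @export
writeTrainLog <- function(net, path) {
  utils::write.csv(net$trace, path, row.names = FALSE)
  invisible(path)
}
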